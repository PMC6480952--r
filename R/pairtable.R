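#' Pair tables: the canonical secondary-structure form
#'
#' A pair table is a 1-based integer vector \code{p} of length \code{n} with
#' \code{p[i] = j} if residue \code{i} pairs residue \code{j} and
#' \code{p[i] = 0} if \code{i} is unpaired.  It is involutive:
#' \code{p[p[i]] == i} for every paired \code{i}.  Backbone interruptions
#' (between chains of a co- or multi-fold structure) are stored in the
#' \code{breaks} attribute as the sorted positions after which the backbone
#' is interrupted, e.g. \code{breaks = 4} means chains \code{1..4} and
#' \code{5..n}.
#'
#' @param pairs integer vector, \code{pairs[i]} = partner of \code{i} or 0.
#' @param breaks integer vector of after-positions of backbone breaks.
#' @return an object of class \code{"pair_table"}.
#' @export
#' @examples
#' pt <- pair_table(c(6L, 5L, 0L, 0L, 2L, 1L))
#' parse_dotbracket("((..))")
pair_table <- function(pairs, breaks = integer()) {
  pairs <- as.integer(pairs)
  breaks <- sort(unique(as.integer(breaks)))
  pt <- structure(pairs, breaks = breaks, class = "pair_table")
  validate_pair_table(pt)
  pt
}

validate_pair_table <- function(pt) {
  n <- length(pt)
  p <- unclass(pt)
  attributes(p) <- NULL
  if (any(is.na(p))) stop("pair table contains NA")
  if (any(p < 0L | p > n)) stop("pair table partner out of range 1..n")
  paired <- which(p > 0L)
  if (any(p[paired] == paired)) stop("residue paired with itself")
  if (any(p[p[paired]] != paired)) stop("pair table is not an involution")
  br <- attr(pt, "breaks")
  if (length(br) && (any(br < 1L) || any(br >= n)))
    stop("chain break positions must lie in 1..(n-1)")
  invisible(pt)
}

#' @export
print.pair_table <- function(x, ...) {
  cat("pair_table of length", length(x), "\n")
  cat(write_dotbracket(x), "\n")
  invisible(x)
}

# Bracket pages in fixed output order.  Openers beyond the four ASCII pairs
# are the uppercase letters, closed by the matching lowercase letter.
.db_openers <- c("(", "[", "{", "<", LETTERS)
.db_closers <- c(")", "]", "}", ">", letters)

#' Parse a dot-bracket string into a pair table
#'
#' Supports the extended bracket alphabet \code{() [] {} <>} plus letter
#' pages \code{A..Z} (closed by \code{a..z}), \code{'.'} and \code{'-'} for
#' unpaired positions, and \code{'&'} as a chain separator for co- and
#' multi-fold structures.  \code{'&'} does not occupy a sequence position;
#' it is recorded as a backbone break.
#'
#' @param db dot-bracket string.
#' @return a [pair_table()].
#' @export
#' @examples
#' parse_dotbracket("((..))")
#' parse_dotbracket("((..&..))")     # two chains, break after position 4
#' parse_dotbracket("((([[[)))]]]")  # crossing pairs are retained
parse_dotbracket <- function(db) {
  stopifnot(is.character(db), length(db) == 1L)
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  pairs <- integer(0)
  breaks <- integer(0)
  stacks <- vector("list", length(.db_openers))
  pos <- 0L
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (ch == "&") {
      if (pos == 0L) stop("parse error at character ", k, ": '&' before any residue")
      breaks <- c(breaks, pos)
      next
    }
    pos <- pos + 1L
    pairs[pos] <- 0L
    if (ch == "." || ch == "-") next
    io <- match(ch, .db_openers)
    if (!is.na(io)) {
      stacks[[io]] <- c(stacks[[io]], pos)
      next
    }
    ic <- match(ch, .db_closers)
    if (!is.na(ic)) {
      st <- stacks[[ic]]
      if (!length(st)) stop("parse error at position ", pos,
                            ": unbalanced closing bracket '", ch, "'")
      j <- st[length(st)]
      stacks[[ic]] <- st[-length(st)]
      pairs[pos] <- j
      pairs[j] <- pos
      next
    }
    stop("parse error at position ", pos, ": unknown character '", ch, "'")
  }
  open_left <- which(vapply(stacks, length, 1L) > 0L)
  if (length(open_left))
    stop("parse error: unbalanced opening bracket '", .db_openers[open_left[1]],
         "' at position ", stacks[[open_left[1]]][1])
  pair_table(pairs, breaks = breaks)
}

#' Write a pair table as a dot-bracket string
#'
#' Crossing pairs are emitted on additional bracket pages, assigned greedily
#' in the fixed page order \code{() [] {} <> Aa..Zz}: each pair goes to the
#' first page on which it does not cross a pair already on that page.
#'
#' @param pt a [pair_table()].
#' @return dot-bracket string with \code{'&'} at chain breaks.
#' @export
write_dotbracket <- function(pt) {
  validate_pair_table(pt)
  n <- length(pt)
  out <- rep(".", n)
  opens <- which(unclass(pt) > seq_len(n))
  # page assignment: greedy, first page without a crossing partner
  pages <- list()
  for (i in opens) {
    j <- pt[[i]]
    placed <- FALSE
    for (pg in seq_along(pages)) {
      x <- pages[[pg]]
      crossing <- any((x[, 1] < i & i < x[, 2] & x[, 2] < j) |
                      (i < x[, 1] & x[, 1] < j & j < x[, 2]))
      if (!crossing) {
        pages[[pg]] <- rbind(x, c(i, j))
        out[i] <- .db_openers[pg]; out[j] <- .db_closers[pg]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      pg <- length(pages) + 1L
      if (pg > length(.db_openers)) stop("structure needs more bracket pages than available")
      pages[[pg]] <- matrix(c(i, j), 1)
      out[i] <- .db_openers[pg]; out[j] <- .db_closers[pg]
    }
  }
  br <- attr(pt, "breaks")
  if (length(br)) {
    pieces <- character(0)
    bounds <- c(0L, br, n)
    for (k in seq_len(length(bounds) - 1L))
      pieces <- c(pieces, paste(out[(bounds[k] + 1L):bounds[k + 1L]], collapse = ""))
    paste(pieces, collapse = "&")
  } else {
    paste(out, collapse = "")
  }
}

# TRUE where pair (i1,j1) crosses (i2,j2); arguments are equal-length vectors.
pairs_cross <- function(i1, j1, i2, j2) {
  (i1 < i2 & i2 < j1 & j1 < j2) | (i2 < i1 & i1 < j2 & j2 < j1)
}

# Matrix of pairs (i < j) in 5' order.
pt_pairs <- function(pt) {
  i <- which(unclass(pt) > seq_along(pt))
  cbind(i = i, j = as.integer(pt[i]))
}

#' Read and write bpseq files
#'
#' The bpseq format has one line per residue: \code{index base partner},
#' 1-based, with partner 0 for unpaired residues.  Comment lines starting
#' with \code{#} are ignored on input.
#'
#' @param path file path.
#' @return \code{read_bpseq}: a list with \code{pt} (a [pair_table()]) and
#'   \code{seq} (sequence string).
#' @export
read_bpseq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[[:space:]]+")
  bad <- which(vapply(fields, length, 1L) != 3L)
  if (length(bad)) stop("bpseq parse error on line ", bad[1])
  idx <- as.integer(vapply(fields, `[`, "", 1L))
  base <- vapply(fields, `[`, "", 2L)
  partner <- as.integer(vapply(fields, `[`, "", 3L))
  if (any(is.na(idx)) || any(is.na(partner))) stop("bpseq: non-numeric index or partner")
  o <- order(idx)
  idx <- idx[o]; base <- base[o]; partner <- partner[o]
  if (!identical(idx, seq_along(idx))) stop("bpseq: indices are not 1..n")
  list(pt = pair_table(partner), seq = paste(base, collapse = ""))
}

#' @rdname read_bpseq
#' @param pt a [pair_table()].
#' @param seq optional sequence string (defaults to all N).
#' @export
write_bpseq <- function(pt, path, seq = NULL) {
  validate_pair_table(pt)
  n <- length(pt)
  if (is.null(seq)) seq <- paste(rep("N", n), collapse = "")
  base <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(base) != n) stop("sequence length does not match pair table")
  writeLines(sprintf("%d %s %d", seq_len(n), base, as.integer(pt)), path)
  invisible(path)
}

#' Read and write connectivity-table (ct) files
#'
#' Six columns per residue: index, base, 5' neighbour index (0 at chain
#' starts), 3' neighbour index (0 at chain ends), partner (0 if unpaired),
#' and the reference number.  The header line carries the length.  Chain
#' breaks are reconstructed from zeroed neighbour columns.
#'
#' @param path file path.
#' @return \code{read_ct}: list with \code{pt} and \code{seq}.
#' @export
read_ct <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("ct: empty file")
  hdr <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  n <- suppressWarnings(as.integer(hdr[1]))
  if (is.na(n)) stop("ct: header does not start with the sequence length")
  if (length(lines) < n + 1L) stop("ct: fewer residue lines than header length")
  fields <- strsplit(trimws(lines[2:(n + 1L)]), "[[:space:]]+")
  get <- function(k) vapply(fields, `[`, "", k)
  idx <- as.integer(get(1)); base <- get(2)
  nxt <- as.integer(get(4)); partner <- as.integer(get(5))
  if (!identical(idx, seq_len(n))) stop("ct: indices are not 1..n")
  breaks <- setdiff(which(nxt == 0L), n)
  list(pt = pair_table(partner, breaks = breaks), seq = paste(base, collapse = ""))
}

#' @rdname read_ct
#' @param pt a [pair_table()].
#' @param seq optional sequence string.
#' @param name structure name for the header.
#' @export
write_ct <- function(pt, path, seq = NULL, name = "rna") {
  validate_pair_table(pt)
  n <- length(pt)
  if (is.null(seq)) seq <- paste(rep("N", n), collapse = "")
  base <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(base) != n) stop("sequence length does not match pair table")
  br <- attr(pt, "breaks")
  prev <- seq_len(n) - 1L
  nxt <- seq_len(n) + 1L
  nxt[n] <- 0L
  if (length(br)) {
    nxt[br] <- 0L
    prev[br + 1L] <- 0L
  }
  out <- c(sprintf("%d %s", n, name),
           sprintf("%d %s %d %d %d %d", seq_len(n), base, prev, nxt,
                   as.integer(pt), seq_len(n)))
  writeLines(out, path)
  invisible(path)
}

#' Read dot-bracket / fasta-style secondary structure files
#'
#' Accepts a bare dot-bracket line, or a fasta-like record with \code{>}
#' header, optional sequence line and a structure line.
#'
#' @param path file path.
#' @return list with \code{pt}, \code{seq} (possibly \code{NULL}) and
#'   \code{name}.
#' @export
read_dotbracket_file <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  name <- "rna"; seq <- NULL; db <- NULL
  for (ln in lines) {
    if (startsWith(ln, ">")) { name <- sub("^>\\s*", "", ln); next }
    if (grepl("^[ACGUTNacgutn&]+$", ln) && is.null(seq) && !grepl("[().]", ln)) {
      seq <- gsub("&", "", toupper(ln), fixed = TRUE); next
    }
    db <- if (is.null(db)) ln else paste0(db, ln)
  }
  if (is.null(db)) stop("no dot-bracket line found in ", path)
  list(pt = parse_dotbracket(db), seq = seq, name = name)
}
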