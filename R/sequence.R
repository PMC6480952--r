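#' Residue identifiers
#'
#' Experimental structures number residues by an external reference: a chain
#' id, an integer that may be negative (residues upstream of the functional
#' RNA) or start above 1 (fragments of larger molecules), and an optional
#' insertion-code letter that keeps downstream numbering stable when
#' residues are inserted.  A residue id is encoded as the string
#' \code{"<chain>:<number><icode>"}, e.g. \code{"A:14"} or \code{"A:14B"}.
#'
#' Ordering is lexicographic on (chain, number, insertion code), with a
#' blank insertion code sorting before any letter.
#'
#' @param chain chain identifier (non-empty string).
#' @param number integer residue number (may be negative or > 1).
#' @param icode insertion code: a single letter or \code{""}.
#' @return residue-id string.
#' @export
#' @examples
#' residue_id("A", 14)
#' residue_id("A", 14, "B")
#' parse_residue_id("A:-2")
residue_id <- function(chain, number, icode = "") {
  chain <- as.character(chain); icode <- as.character(icode)
  icode[is.na(icode) | icode == " "] <- ""
  if (any(!nzchar(chain))) stop("residue id: chain must be non-empty")
  if (any(nchar(icode) > 1L)) stop("residue id: insertion code must be one character")
  sprintf("%s:%d%s", chain, as.integer(number), icode)
}

#' @rdname residue_id
#' @param id residue-id string(s).
#' @return \code{parse_residue_id}: data frame with columns \code{chain},
#'   \code{number}, \code{icode}.
#' @export
parse_residue_id <- function(id) {
  m <- regmatches(id, regexec("^(.+):(-?[0-9]+)([A-Za-z]?)$", id))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed residue id: ", id[bad][1])
  data.frame(chain = vapply(m, `[`, "", 2L),
             number = as.integer(vapply(m, `[`, "", 3L)),
             icode = vapply(m, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

#' @rdname residue_id
#' @export
order_residue_ids <- function(id) {
  p <- parse_residue_id(id)
  order(p$chain, p$number, p$icode, method = "radix")
}

#' RNA sequences with dual indexing and missing-residue bookkeeping
#'
#' An \code{rna_sequence} stores, in file order, the one-letter code of
#' every residue known to the experiment, its [residue_id()], whether
#' coordinates are present, and (for modified residues) the original
#' three-letter code.  Two numbering schemes coexist: plain integers are
#' strictly 1-based positions into the \emph{present} residues, while
#' residue-id strings address any residue (present or missing) by its
#' reference identifier.
#'
#' @param codes character vector of one-letter codes in \code{A,C,G,U,N}.
#' @param ids residue-id strings (unique), same length as \code{codes};
#'   defaults to chain "A", numbers 1..n.
#' @param present logical vector: does the residue have coordinates?
#' @param mods character vector of original 3-letter codes, \code{NA} where
#'   the residue is unmodified.
#' @param breaks backbone-break positions (1-based, after-index, counted in
#'   the present-only numbering).
#' @return object of class \code{"rna_sequence"}.
#' @export
#' @examples
#' s <- rna_sequence(c("G", "A", "C"),
#'                   ids = residue_id("A", 13:15))
#' resolve_index(s, 2)
#' resolve_index(s, "A:15")
rna_sequence <- function(codes, ids = NULL, present = NULL, mods = NULL,
                         breaks = integer()) {
  codes <- toupper(as.character(codes))
  n <- length(codes)
  if (n && !all(codes %in% c("A", "C", "G", "U", "N")))
    stop("sequence codes must be one of A, C, G, U, N")
  if (is.null(ids)) ids <- if (n) residue_id("A", seq_len(n)) else character()
  if (anyDuplicated(ids)) stop("residue ids must be unique")
  if (is.null(present)) present <- rep(TRUE, n)
  if (is.null(mods)) mods <- rep(NA_character_, n)
  stopifnot(length(ids) == n, length(present) == n, length(mods) == n)
  structure(list(codes = codes, ids = as.character(ids),
                 present = as.logical(present), mods = as.character(mods),
                 breaks = sort(unique(as.integer(breaks)))),
            class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat("rna_sequence:", sum(x$present), "present /", length(x$codes),
      "total residues\n")
  cat(seq_string(x), "\n")
  invisible(x)
}

#' @export
length.rna_sequence <- function(x) sum(x$present)

#' Present-only and with-missing sequence views
#'
#' \code{seq_string} returns the present-only sequence (the string that
#' 1-based integer indices address); \code{missing_residue_view} returns the
#' full-length sequence including residues without coordinates.  The
#' present-only string is always a subsequence of the with-missing view.
#'
#' @param seq an [rna_sequence()].
#' @return a sequence string.
#' @export
seq_string <- function(seq) paste(seq$codes[seq$present], collapse = "")

#' @rdname seq_string
#' @export
missing_residue_view <- function(seq) paste(seq$codes, collapse = "")

#' Resolve an integer position or residue id to a residue record
#'
#' Integer indices are strictly 1-based positions into the present residues;
#' 0 and negative integers are errors (negative \emph{reference} numbers
#' live inside residue ids only).  Residue-id strings resolve any residue,
#' present or missing.
#'
#' @param seq an [rna_sequence()].
#' @param index a single integer or a residue-id string.
#' @return list with \code{code}, \code{id}, \code{present}, \code{mod} and
#'   \code{position} (present-only position, \code{NA} for missing
#'   residues).
#' @export
resolve_index <- function(seq, index) {
  stopifnot(inherits(seq, "rna_sequence"), length(index) == 1L)
  if (is.numeric(index)) {
    i <- as.integer(index)
    if (i != index) stop("non-integer index")
    npres <- sum(seq$present)
    if (i < 1L || i > npres)
      stop("integer index out of range: ", i, " (valid: 1..", npres, ")")
    k <- which(seq$present)[i]
  } else if (is.character(index)) {
    k <- match(index, seq$ids)
    if (is.na(k)) stop("unknown residue id: ", index)
  } else {
    stop("index must be an integer position or a residue-id string")
  }
  pos <- if (seq$present[k]) match(k, which(seq$present)) else NA_integer_
  list(code = seq$codes[k], id = seq$ids[k], present = seq$present[k],
       mod = seq$mods[k], position = pos)
}

#' Normalize a residue's three-letter code to its unmodified parent
#'
#' Standard codes (\code{A,C,G,U}) return themselves with no modification
#' annotation.  Modified residues found in the bundled table return the
#' parent one-letter code plus the original code as annotation.  Unknown
#' codes raise an error unless \code{permissive = TRUE}, in which case they
#' map to \code{"N"} with a warning (silent coercion would hide data
#' problems).
#'
#' @param code3 residue code from a structure file (1-3 characters).
#' @param table named character vector mapping 3-letter codes to parent
#'   letters; defaults to the bundled table (see [modification_table()]).
#' @param permissive map unknown codes to \code{"N"} instead of failing?
#' @return list with \code{code} (one letter) and \code{mod} (original
#'   code, or \code{NA} if unmodified).
#' @export
#' @examples
#' normalize_residue("G")
#' normalize_residue("5MC")   # 5-methylcytidine -> C
normalize_residue <- function(code3, table = modification_table(),
                              permissive = FALSE) {
  stopifnot(is.character(code3), length(code3) == 1L, nzchar(code3))
  code3 <- toupper(trimws(code3))
  if (code3 %in% c("A", "C", "G", "U"))
    return(list(code = code3, mod = NA_character_))
  parent <- if (code3 %in% names(table)) unname(table[[code3]])
            else NA_character_
  if (!is.na(parent)) {
    if (!parent %in% c("A", "C", "G", "U"))
      stop("modification table maps '", code3, "' to non-standard parent '",
           parent, "'")
    return(list(code = parent, mod = code3))
  }
  if (permissive) {
    warning("unknown residue code '", code3, "' mapped to N")
    return(list(code = "N", mod = code3))
  }
  stop("unknown residue code '", code3,
       "'; extend the modification table or use permissive = TRUE")
}
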