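#' Bulge graphs: RNA structures as graphs of secondary-structure elements
#'
#' A bulge graph partitions the residues 1..n of a structure into named
#' elements and connects elements that are adjacent along the backbone (or
#' share a closing-pair boundary).  Element kinds are encoded in the name
#' prefix:
#' \describe{
#'   \item{s}{stem: a maximal run of consecutive stacked pairs
#'     \code{(i,j), (i+1,j-1), ...}; a single isolated pair is a valid
#'     1-bp stem.}
#'   \item{h}{hairpin loop (possibly empty for a zero-length loop).}
#'   \item{i}{interior loop or bulge; \emph{both} strands of an internal
#'     loop form one element.}
#'   \item{m}{multiloop segment: a single-stranded stretch, possibly of
#'     zero length, connecting two stems.  Zero-length segments are kept as
#'     empty elements so that stacking across them remains expressible.}
#'   \item{f, t}{unpaired 5' and 3' chain ends.}
#' }
#' Elements are numbered within each kind by the position of their first
#' residue (empty elements by the backbone boundary they sit on).
#'
#' Crossing (pseudoknotted) base pairs are retained: their helices are
#' ordinary stems and the single-stranded stretches around them become
#' multiloop segments flagged as pseudoknotted.
#'
#' @param x a [pair_table()] or a dot-bracket string.
#' @param min_stem_bp minimum number of consecutive pairs for a helix to
#'   count as a stem; pairs in shorter helices are treated as unpaired.
#'   Default 1 keeps isolated pairs.
#' @param remove_pk drop crossing pairs (see [remove_pseudoknots()]) before
#'   decomposing?
#' @return object of class \code{"bulge_graph"}: a list with \code{n},
#'   \code{pt}, \code{elements} (named list of residue-position vectors),
#'   \code{edges} (named list of adjacent element names), \code{stems}
#'   (per-stem pair matrices, outermost pair first), \code{junctions} (see
#'   [junctions()]) and \code{pk_elements} (names of multiloop segments
#'   bordering crossing helices).
#' @export
#' @examples
#' bg <- bulge_graph("((..((...))..))")
#' bg$elements
#' junctions(bulge_graph("(((..(((...)))..(((...)))..(((...)))..)))"))
bulge_graph <- function(x, min_stem_bp = 1L, remove_pk = FALSE) {
  pt <- if (inherits(x, "pair_table")) x else parse_dotbracket(x)
  if (remove_pk) pt <- remove_pseudoknots(pt)
  n <- length(pt)
  breaks <- attr(pt, "breaks")

  stems <- find_stems(pt, min_stem_bp = min_stem_bp)
  # working copy with sub-threshold helix pairs removed
  p <- as.integer(pt)
  keep <- rep(FALSE, n)
  for (st in stems) keep[c(st[, 1], st[, 2])] <- TRUE
  p[p > 0L & !keep] <- 0L
  pt_eff <- pair_table(p, breaks = breaks)

  stem_of <- rep(NA_integer_, n)
  for (si in seq_along(stems)) stem_of[c(stems[[si]][, 1], stems[[si]][, 2])] <- si
  crossing <- stem_crossing_flags(stems)

  ## ---- enumerate gaps -------------------------------------------------
  paired <- p > 0L
  is_break <- rep(FALSE, max(n, 1L)); if (length(breaks)) is_break[breaks] <- TRUE
  gaps <- list()
  i <- 1L
  while (i <= n) {
    if (!paired[i]) {
      j <- i
      while (j < n && !paired[j + 1L] && !is_break[j]) j <- j + 1L
      gaps[[length(gaps) + 1L]] <- list(a = i, b = j, key = i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (n > 1L) for (k in seq_len(n - 1L)) {
    if (paired[k] && paired[k + 1L] && !is_break[k] &&
        (p[k + 1L] != p[k] - 1L || p[k] == k + 1L)) {
      gaps[[length(gaps) + 1L]] <- list(a = k + 1L, b = k, key = k + 0.5)
    }
  }
  if (length(gaps)) gaps <- gaps[order(vapply(gaps, `[[`, 0, "key"))]

  ## ---- classify gaps --------------------------------------------------
  consumed <- rep(FALSE, length(gaps))
  elems <- list()   # each: list(kind, members, key, flanks = c(p, q), pk)
  find_gap <- function(key_want) {
    for (g in seq_along(gaps))
      if (!consumed[g] && abs(gaps[[g]]$key - key_want) < 1e-9) return(g)
    NA_integer_
  }
  for (g in seq_along(gaps)) {
    if (consumed[g]) next
    gp <- gaps[[g]]
    members <- if (gp$a <= gp$b) gp$a:gp$b else integer()
    pl <- gp$a - 1L
    if (pl < 1L || is_break[pl]) pl <- NA_integer_
    ql <- gp$b + 1L
    if (ql > n || (gp$b >= 1L && is_break[gp$b])) ql <- NA_integer_
    pk_flag <- FALSE
    if (is.na(pl) && is.na(ql)) {
      kind <- "f"   # an entirely unpaired chain
    } else if (is.na(pl)) {
      kind <- "f"
    } else if (is.na(ql)) {
      kind <- "t"
    } else if (p[pl] == ql) {
      kind <- "h"
    } else if (p[pl] > pl && p[ql] > ql && p[ql] < p[pl] &&
               all(!paired[seq2(p[ql] + 1L, p[pl] - 1L)]) &&
               !any(is_break[seq2(p[ql], p[pl] - 1L)])) {
      # interior loop: the complementary strand gap between the partners is
      # unpaired; merge the two strands into one element
      kind <- "i"
      B <- p[ql]; A <- p[pl]
      members <- c(members, seq2(B + 1L, A - 1L))
      key2 <- if (B + 1L <= A - 1L) as.numeric(B + 1L) else B + 0.5
      g2 <- find_gap(key2)
      if (!is.na(g2)) consumed[g2] <- TRUE
    } else {
      kind <- "m"
      pk_flag <- (!is.na(pl) && isTRUE(crossing[stem_of[pl]])) ||
                 (!is.na(ql) && isTRUE(crossing[stem_of[ql]]))
    }
    consumed[g] <- TRUE
    elems[[length(elems) + 1L]] <-
      list(kind = kind, members = sort(members), key = gp$key,
           flanks = c(pl, ql), pk = pk_flag)
  }

  ## ---- name elements --------------------------------------------------
  elements <- list(); edges <- list(); flanks <- list()
  pk_elements <- character()
  stem_names <- character(length(stems))
  if (length(stems)) {
    ord <- order(vapply(stems, function(s) s[1, 1], 0L))
    for (r in seq_along(ord)) stem_names[ord[r]] <- paste0("s", r - 1L)
    for (si in seq_along(stems))
      elements[[stem_names[si]]] <- sort(c(stems[[si]][, 1], stems[[si]][, 2]))
  }
  for (kd in c("h", "i", "m", "f", "t")) {
    sel <- which(vapply(elems, `[[`, "", "kind") == kd)
    if (!length(sel)) next
    sel <- sel[order(vapply(elems[sel], `[[`, 0, "key"))]
    for (r in seq_along(sel)) {
      nm <- paste0(kd, r - 1L)
      e <- elems[[sel[r]]]
      elements[[nm]] <- e$members
      flanks[[nm]] <- e$flanks
      if (e$pk) pk_elements <- c(pk_elements, nm)
    }
  }
  # edges: every loop element connects to the stems of its flanks
  for (nm in names(flanks)) {
    fl <- flanks[[nm]]
    nb <- unique(stem_names[stats::na.omit(stem_of[fl[!is.na(fl)]])])
    edges[[nm]] <- nb
    for (s in nb) edges[[s]] <- unique(c(edges[[s]] %||% character(), nm))
  }
  for (s in stem_names) if (is.null(edges[[s]])) edges[[s]] <- character()

  bg <- structure(list(
    n = n, pt = pt_eff, elements = elements, edges = edges,
    stems = stats::setNames(stems, stem_names),
    stem_of = ifelse(is.na(stem_of), NA_character_, stem_names[stem_of]),
    flanks = flanks, pk_elements = pk_elements,
    crossing_stems = stem_names[which(crossing)],
    breaks = breaks
  ), class = "bulge_graph")
  bg$junctions <- find_junctions(bg)
  bg
}

# integer sequence that is empty when from > to (avoids 5:4 pitfalls)
seq2 <- function(from, to) if (from > to) integer() else from:to

#' @export
print.bulge_graph <- function(x, ...) {
  cat("bulge_graph:", x$n, "residues,", length(x$stems), "stems,",
      length(x$junctions), "junctions\n")
  kinds <- substr(names(x$elements), 1, 1)
  cat(paste(sprintf("%s=%d", c("s", "h", "i", "m", "f", "t"),
                    vapply(c("s", "h", "i", "m", "f", "t"),
                           function(k) sum(kinds == k), 0L)), collapse = " "), "\n")
  invisible(x)
}

# Stems as matrices of pairs (i, j), outermost first.  Strand runs never
# span a chain break.
find_stems <- function(pt, min_stem_bp = 1L) {
  n <- length(pt)
  p <- as.integer(pt)
  breaks <- attr(pt, "breaks")
  is_break <- rep(FALSE, max(n, 1L)); if (length(breaks)) is_break[breaks] <- TRUE
  used <- rep(FALSE, n)
  stems <- list()
  for (i in seq_len(n)) {
    j <- p[i]
    if (j <= i || used[i]) next
    rows <- c(i, j)
    k <- 1L
    while (i + k < j - k &&
           !is_break[i + k - 1L] && !is_break[j - k] &&
           p[i + k] == j - k) {
      rows <- rbind(rows, c(i + k, j - k))
      k <- k + 1L
    }
    m <- matrix(rows, ncol = 2)
    used[c(m[, 1], m[, 2])] <- TRUE
    if (nrow(m) >= min_stem_bp) stems[[length(stems) + 1L]] <- m
  }
  stems
}

stem_crossing_flags <- function(stems) {
  k <- length(stems)
  out <- rep(FALSE, k)
  if (k < 2L) return(out)
  span <- t(vapply(stems, function(s) c(s[1, 1], s[1, 2]), c(0L, 0L)))
  for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
    if (pairs_cross(span[a, 1], span[a, 2], span[b, 1], span[b, 2])) {
      out[a] <- TRUE; out[b] <- TRUE
    }
  }
  out
}

# Multiloop cycles.  For every stem whose inner loop contains >= 2 direct
# child stems and no strand of a crossing helix, record the cycle
# [S, m, T1, m, T2, ..., Tk, m] of bounding stems and connecting segments.
# The exterior loop is never a junction.
find_junctions <- function(bg) {
  stems <- bg$stems
  if (length(stems) < 3L) return(list())
  # lookup: element by its (p, q) flank pair
  flank_key <- vapply(bg$flanks, function(f) paste(f, collapse = ","), "")
  elem_by_flanks <- stats::setNames(names(bg$flanks), flank_key)
  span <- t(vapply(stems, function(s) c(s[1, 1], s[1, 2]), c(0L, 0L)))
  crossing <- names(stems) %in% bg$crossing_stems
  p <- as.integer(bg$pt)
  out <- list()
  for (si in seq_along(stems)) {
    S <- stems[[si]]
    x <- S[nrow(S), 1]; y <- S[nrow(S), 2]   # inner pair
    if (x + 1L > y - 1L) next
    inside <- which(span[, 1] > x & span[, 2] < y)
    if (length(inside) < 2L) next
    direct <- inside[vapply(inside, function(t1) {
      !any(span[inside, 1] < span[t1, 1] & span[inside, 2] > span[t1, 2])
    }, TRUE)]
    if (length(direct) < 2L) next
    # clean face: every residue between x and y is unpaired or inside a
    # direct child's span
    face <- seq2(x + 1L, y - 1L)
    covered <- rep(FALSE, bg$n)
    for (t1 in direct) covered[span[t1, 1]:span[t1, 2]] <- TRUE
    if (any(p[face] > 0L & !covered[face])) next   # pierced by a pseudoknot
    if (any(bg$breaks %in% setdiff(face, which(covered)))) next
    direct <- direct[order(span[direct, 1])]
    stems_cycle <- c(names(stems)[si], names(stems)[direct])
    bounds_l <- c(x, span[direct, 2])
    bounds_r <- c(span[direct, 1], y)
    segs <- character(length(direct) + 1L)
    ok <- TRUE
    for (s2 in seq_along(segs)) {
      key <- paste(c(bounds_l[s2], bounds_r[s2]), collapse = ",")
      el <- if (key %in% names(elem_by_flanks)) elem_by_flanks[[key]]
            else NA_character_
      if (is.na(el) || substr(el, 1, 1) != "m") { ok <- FALSE; break }
      segs[s2] <- el
    }
    if (!ok) next
    out[[length(out) + 1L]] <- list(stems = stems_cycle, segments = segs)
  }
  out
}

#' Multiloop junctions of a bulge graph
#'
#' A junction is the closed cycle of multiloop segments (m elements,
#' possibly empty) around one multiloop, together with its bounding stems in
#' cycle order: \code{segments[i]} connects \code{stems[i]} and
#' \code{stems[i + 1]} (cyclically).  Every junction has at least three
#' bounding stems; two-stem cycles are interior loops by construction, and
#' the exterior loop is excluded.  Multiloops pierced by crossing helices
#' are not reported; decompose with \code{remove_pk = TRUE} to analyse them.
#'
#' @param bg a [bulge_graph()].
#' @return list of junctions, each a list with \code{stems} and
#'   \code{segments}.
#' @export
junctions <- function(bg) {
  stopifnot(inherits(bg, "bulge_graph"))
  bg$junctions
}

#' Remove pseudoknots from a pair table
#'
#' Returns a crossing-free pair table that retains the maximum possible
#' number of pairs (optimizing pairs, not helices).  Ties between equally
#' large crossing-free subsets are broken toward the subset whose first
#' retained pair is 5'-most.
#'
#' @param pt a [pair_table()].
#' @return a crossing-free [pair_table()] with the same length and breaks.
#' @export
#' @examples
#' write_dotbracket(remove_pseudoknots(parse_dotbracket("((([[)))]]")))
remove_pseudoknots <- function(pt) {
  validate_pair_table(pt)
  n <- length(pt)
  p <- as.integer(pt)
  if (n == 0L) return(pt)
  # interval DP on the number of retainable nested pairs
  M <- matrix(0L, n + 1L, n + 1L)        # M[i, j+1] over interval i..j
  take <- matrix(FALSE, n, n)
  for (len in 2:max(n, 2L)) {
    if (len > n) break
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      best <- M[i + 1L, j + 1L]
      k <- p[i]
      if (k > i && k <= j) {
        cand <- 1L + M[i + 1L, k] + (if (k < j) M[k + 1L, j + 1L] else 0L)
        if (cand >= best) {           # >= : prefer keeping the 5'-most pair
          best <- cand
          take[i, j] <- TRUE
        }
      }
      M[i, j + 1L] <- best
    }
  }
  keep <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack)) {
    iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    if (i >= j) next
    if (take[i, j]) {
      k <- p[i]
      keep <- c(keep, i)
      if (i + 1L <= k - 1L) stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
      if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
    } else {
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
    }
  }
  out <- integer(n)
  out[keep] <- p[keep]
  out[p[keep]] <- keep
  pair_table(out, breaks = attr(pt, "breaks"))
}

#' Condensed shape of a secondary structure
#'
#' Reduces a structure to a bracket shape in which every rod (a maximal
#' chain of stems connected through interior loops) is a single bracket
#' pair; unpaired elements are dropped and nesting order is preserved.
#' Crossing pairs are removed (see [remove_pseudoknots()]) before shape
#' reduction.
#'
#' @param bg a [bulge_graph()], [pair_table()] or dot-bracket string.
#' @return shape string such as \code{"[[][][]]"}.
#' @export
#' @examples
#' condense("((..((...))..))")                              # "[]"
#' condense("(((..(((...)))..(((...)))..(((...)))..)))")    # "[[][][]]"
condense <- function(bg) {
  pt <- if (inherits(bg, "bulge_graph")) bg$pt
        else if (inherits(bg, "pair_table")) bg
        else parse_dotbracket(bg)
  pt <- remove_pseudoknots(pt)
  stems <- find_stems(pt)
  if (!length(stems)) return("")
  span <- t(vapply(stems, function(s) c(s[1, 1], s[1, 2]), c(0L, 0L)))
  direct_children <- function(idx) {
    if (is.na(idx)) {
      inside <- seq_len(nrow(span))
    } else {
      inside <- which(span[, 1] > span[idx, 1] & span[, 2] < span[idx, 2])
    }
    inside[vapply(inside, function(t1)
      !any(span[inside, 1] < span[t1, 1] & span[inside, 2] > span[t1, 2]), TRUE)]
  }
  shape_of <- function(idx) {
    ch <- direct_children(idx)
    while (length(ch) == 1L) {        # rod: descend through interior loops
      idx <- ch
      ch <- direct_children(idx)
    }
    paste0("[", paste(vapply(ch[order(span[ch, 1])], shape_of, ""),
                      collapse = ""), "]")
  }
  top <- direct_children(NA)
  paste(vapply(top[order(span[top, 1])], shape_of, ""), collapse = "")
}

#' Recover the pair table of a bulge graph
#'
#' @param bg a [bulge_graph()].
#' @return the [pair_table()] the graph was decomposed from (pairs of
#'   helices below the stem-length threshold are unpaired here).
#' @export
to_pairtable <- function(bg) {
  stopifnot(inherits(bg, "bulge_graph"))
  bg$pt
}

# kind of an element name ("s0" -> "s")
element_kind <- function(name) substr(name, 1, 1)
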