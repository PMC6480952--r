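#' Shadow of a secondary structure
#'
#' The shadow keeps only crossing (pseudoknotted) base pairs and collapses
#' every maximal crossing helix to a single chord, yielding a chord diagram
#' on the backbone(s).  Two pairs belong to the same chord when they are
#' nested into each other with no other retained pair endpoint between them
#' on either strand (so a helix interrupted by small internal loops still
#' collapses to one chord).  Nested (non-crossing) structure disappears
#' completely: the shadow of a nested structure is the empty diagram.
#'
#' @param x a [pair_table()], dot-bracket string, or chord diagram (for
#'   which the shadow is the diagram itself: shadowing is idempotent).
#' @return object of class \code{"chord_diagram"}: list with
#'   \code{chords} (k x 2 matrix of endpoint indices in 1..2k along the
#'   backbone), \code{backbone} (backbone index of each endpoint),
#'   \code{positions} (original residue position of each endpoint) and
#'   \code{word} (pattern string such as \code{"ABAB"}).
#' @export
#' @examples
#' shadow("((([[[)))]]]")$word        # "ABAB": H-type
#' shadow("(((...)))")$word           # "": nested structures vanish
shadow <- function(x) {
  if (inherits(x, "chord_diagram")) return(x)
  pt <- if (inherits(x, "pair_table")) x else parse_dotbracket(x)
  prs <- pt_pairs(pt)
  n <- length(pt)
  if (!nrow(prs)) return(empty_chord_diagram())
  # keep crossing pairs only
  k <- nrow(prs)
  crossing <- rep(FALSE, k)
  if (k > 1L) for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
    if (pairs_cross(prs[a, 1], prs[a, 2], prs[b, 1], prs[b, 2])) {
      crossing[a] <- TRUE; crossing[b] <- TRUE
    }
  }
  prs <- prs[crossing, , drop = FALSE]
  if (!nrow(prs)) return(empty_chord_diagram())
  # collapse helices: merge directly nested pairs with no other endpoint in
  # between on either strand
  prs <- prs[order(prs[, 1]), , drop = FALSE]
  ends <- sort(c(prs[, 1], prs[, 2]))
  grp <- seq_len(nrow(prs))
  find <- function(a) { while (grp[a] != a) a <- grp[a]; a }
  for (a in seq_len(nrow(prs))) for (b in seq_len(nrow(prs))) {
    if (a == b) next
    ia <- prs[a, 1]; ja <- prs[a, 2]; ib <- prs[b, 1]; jb <- prs[b, 2]
    if (ia < ib && jb < ja &&
        !any(ends > ia & ends < ib) && !any(ends > jb & ends < ja)) {
      grp[find(b)] <- find(a)
    }
  }
  root <- vapply(seq_len(nrow(prs)), find, 0L)
  groups <- split(seq_len(nrow(prs)), root)
  reps <- t(vapply(groups, function(idx) {
    c(min(prs[idx, 1]), max(prs[idx, 2]))   # outermost pair of the helix
  }, c(0L, 0L)))
  ord <- order(reps[, 1])
  reps <- reps[ord, , drop = FALSE]
  members <- lapply(groups[ord], function(idx) prs[idx, , drop = FALSE])
  # endpoint indexing along the backbone
  pos <- sort(c(reps[, 1], reps[, 2]))
  chords <- cbind(match(reps[, 1], pos), match(reps[, 2], pos))
  breaks <- attr(pt, "breaks")
  backbone_of_pos <- findInterval(pos - 0.5, c(0, breaks)) # 1-based chain idx
  structure(list(chords = chords, backbone = backbone_of_pos,
                 positions = pos, word = chord_word(chords),
                 members = unname(members)),
            class = "chord_diagram")
}

empty_chord_diagram <- function() {
  structure(list(chords = matrix(integer(), 0, 2), backbone = integer(),
                 positions = integer(), word = "", members = list()),
            class = "chord_diagram")
}

#' @export
print.chord_diagram <- function(x, ...) {
  cat("chord_diagram:", nrow(x$chords), "chords",
      if (nzchar(x$word)) paste0("(", x$word, ")") else "(empty)", "\n")
  invisible(x)
}

# Pattern word: endpoints in backbone order, chords lettered by first
# occurrence ("ABAB", "ABACBC", ...).
chord_word <- function(chords) {
  if (!nrow(chords)) return("")
  ne <- 2L * nrow(chords)
  lab <- integer(ne)
  for (c1 in seq_len(nrow(chords))) lab[chords[c1, ]] <- c1
  first <- unique(lab)
  paste(LETTERS[match(lab, first)], collapse = "")
}

# Build a chord diagram directly from an endpoint word such as "ABAB"
# (each letter exactly twice).  Used by tests and enumeration.
chord_diagram_from_word <- function(word) {
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  letters_u <- unique(ch)
  stopifnot(all(table(ch) == 2))
  chords <- t(vapply(letters_u, function(L) which(ch == L), c(0L, 0L)))
  structure(list(chords = chords, backbone = rep(1L, length(ch)),
                 positions = seq_along(ch), word = chord_word(chords)),
            class = "chord_diagram")
}

#' Genus of a chord diagram
#'
#' The genus of the fatgraph obtained by thickening the backbone(s) and
#' attaching each chord as a ribbon.  For a connected diagram with
#' \code{b} backbones, \code{n} chords and \code{r} boundary cycles the
#' genus is \code{g = (2 - b + n - r) / 2}; for one backbone this is the
#' familiar \code{(1 + n - r) / 2}.  Boundary cycles are counted as the
#' cycles of the permutation \code{sigma . alpha}, where \code{alpha} swaps
#' chord endpoints and \code{sigma} advances cyclically along each
#' backbone.  Disconnected diagrams contribute the sum of their component
#' genera.  Nested structures have genus 0; the H-type pseudoknot and the
#' kissing hairpin have genus 1.
#'
#' By default the backbones of a multi-chain diagram are concatenated in
#' chain order into a single circle before the walk, which is how
#' pseudoknot classes are defined for interacting chains (an
#' intermolecular kissing complex then has genus 1, like its
#' single-chain counterpart).  Set \code{concatenate = FALSE} to treat
#' each backbone as its own fatgraph vertex instead.
#'
#' @param cd a \code{"chord_diagram"} (see [shadow()]), or anything
#'   [shadow()] accepts.
#' @param concatenate join multiple backbones into one circle first?
#' @return integer genus (>= 0).
#' @export
#' @examples
#' genus(shadow("((([[[)))]]]"))  # 1 (H-type)
#' genus(shadow("(((...)))"))     # 0
genus <- function(cd, concatenate = TRUE) {
  cd <- shadow(cd)
  if (concatenate) cd$backbone <- rep(1L, length(cd$backbone))
  nch <- nrow(cd$chords)
  if (!nch) return(0L)
  ne <- 2L * nch
  if (anyDuplicated(as.integer(cd$chords)) ||
      !setequal(as.integer(cd$chords), seq_len(ne)))
    stop("malformed chord diagram: endpoints must use 1..2n exactly once")
  alpha <- integer(ne)
  alpha[cd$chords[, 1]] <- cd$chords[, 2]
  alpha[cd$chords[, 2]] <- cd$chords[, 1]
  sigma <- integer(ne)
  for (b in unique(cd$backbone)) {
    idx <- which(cd$backbone == b)
    sigma[idx] <- idx[c(seq_along(idx)[-1], 1L)]
  }
  # connected components over chords + backbones
  g_ig <- igraph::make_graph(edges = character(0), directed = FALSE)
  verts <- c(paste0("e", seq_len(ne)))
  g_ig <- igraph::add_vertices(g_ig, length(verts), name = verts)
  edges <- c(rbind(paste0("e", seq_len(ne)), paste0("e", alpha)),
             rbind(paste0("e", seq_len(ne)), paste0("e", sigma)))
  g_ig <- igraph::add_edges(g_ig, edges)
  comp <- igraph::components(g_ig)$membership
  total <- 0L
  perm <- sigma[alpha]                     # next endpoint on the boundary
  for (cm in unique(comp)) {
    idx <- which(comp == cm)
    n_c <- sum(cd$chords[, 1] %in% idx)
    b_c <- length(unique(cd$backbone[idx]))
    # boundary cycles within the component
    seen <- rep(FALSE, ne)
    r_c <- 0L
    for (s in idx) {
      if (seen[s]) next
      r_c <- r_c + 1L
      e <- s
      repeat {
        seen[e] <- TRUE
        e <- perm[e]
        if (e == s) break
      }
    }
    g_c <- (2L - b_c + n_c - r_c) / 2
    if (g_c != round(g_c) || g_c < 0) stop("internal error: non-integer genus")
    total <- total + as.integer(g_c)
  }
  total
}

# canonical form of a word under backbone reversal (relabel by first
# occurrence after reversing)
reverse_word <- function(word) {
  ch <- rev(strsplit(word, "", fixed = TRUE)[[1]])
  first <- unique(ch)
  paste(LETTERS[match(ch, first)], collapse = "")
}

.pk_classes <- c(ABAB = "H", ABACBC = "K", ABCABC = "L", ABCADBCD = "M")

#' Classify a pseudoknot shadow
#'
#' On the shadow level exactly four classes of crossing diagrams have
#' genus 1: the H-type pseudoknot (\code{ABAB}), the kissing hairpin
#' (\code{ABACBC}) and two rarer patterns labelled L (\code{ABCABC}) and M
#' (\code{ABCADBCD}).  Matching is up to reversal of the backbone.  Shadows
#' of higher genus are labelled \code{"higher-genus"}; genus-1 diagrams
#' that extend one of the four cores by further chords are labelled
#' \code{"genus-1-other"}.
#'
#' @param cd chord diagram or anything [shadow()] accepts; must contain at
#'   least one crossing (genus >= 1).
#' @return one of \code{"H"}, \code{"K"}, \code{"L"}, \code{"M"},
#'   \code{"genus-1-other"}, \code{"higher-genus"}.
#' @export
#' @examples
#' classify_pseudoknot("((([[[)))]]]")    # "H"
#' classify_pseudoknot("((.[[.)).((.]].))")
classify_pseudoknot <- function(cd) {
  cd <- shadow(cd)
  g <- genus(cd)
  if (g == 0L) stop("not a pseudoknot: diagram has genus 0")
  if (g > 1L) return("higher-genus")
  w <- cd$word
  cls <- unname(.pk_classes[w])
  if (is.na(cls)) cls <- unname(.pk_classes[reverse_word(w)])
  if (is.na(cls)) cls <- "genus-1-other"
  cls
}
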