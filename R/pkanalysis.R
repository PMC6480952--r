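#' Pseudoknot analysis of a structure, with 3D angles where available
#'
#' Identifies the pseudoknots of a structure (connected groups of crossing
#' helices in the shadow), classifies each by genus and crossing pattern,
#' and -- when coordinates are available -- measures the characteristic
#' stem angles: a single inter-stem angle for H-type pseudoknots, and the
#' three angles alpha (stem 1 vs kissing stem), beta (stem 2 vs kissing
#' stem) and gamma (stem 1 vs stem 2) for kissing hairpins.  Kissing
#' records are further assigned to one of three structural families by
#' [kissing_family()].
#'
#' Angle conventions: each regular stem's vector points away from the side
#' of its helix that encloses the partner helix's strand (away from the
#' loop interface); the kissing-stem vector points from its axis end
#' nearer stem 1's interface to the other end, so a coaxial
#' stem1-kissing-stem stack gives alpha near 180 degrees and a stack at
#' the \emph{other} kissing-stem end gives beta near 0 (the complementary
#' angle near 180).  Stem 1 is the 5'-most regular stem; for an
#' intermolecular kissing interaction (two chains) this assignment is
#' arbitrary but deterministic.
#'
#' @param cg a [coarse_grain()] object built with \code{remove_pk = FALSE}
#'   (or a bare [pair_table()] / dot-bracket string for a 2D-only
#'   analysis).
#' @return data frame with one row per pseudoknot: structure_id, class
#'   (H, K, L, M, genus-1-other, higher-genus), genus, stems
#'   (comma-separated), intermolecular, angle_deg (H only), alpha, beta,
#'   gamma, family (kissing only).
#' @export
#' @examples
#' pseudoknot_records("((([[[)))]]]")
pseudoknot_records <- function(cg) {
  if (inherits(cg, "cg_rna")) {
    pt <- cg$bg$pt
    has3d <- length(cg$coords) > 0L
  } else {
    pt <- if (inherits(cg, "pair_table")) cg else parse_dotbracket(cg)
    cg <- NULL
    has3d <- FALSE
  }
  sh <- shadow(pt)
  empty <- data.frame(structure_id = character(), class = character(),
                      genus = integer(), stems = character(),
                      intermolecular = logical(), angle_deg = numeric(),
                      alpha = numeric(), beta = numeric(), gamma = numeric(),
                      family = integer(), stringsAsFactors = FALSE)
  nch <- nrow(sh$chords)
  if (!nch) return(empty)
  # connected components under the crossing relation
  adj <- matrix(FALSE, nch, nch)
  for (a in seq_len(nch)) for (b in seq_len(nch)) {
    if (a < b && pairs_cross(sh$chords[a, 1], sh$chords[a, 2],
                             sh$chords[b, 1], sh$chords[b, 2])) {
      adj[a, b] <- TRUE; adj[b, a] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  out <- empty
  for (cm in sort(unique(memb))) {
    idx <- which(memb == cm)
    sub <- sub_diagram(sh, idx)
    gen <- genus(sub)
    cls <- classify_pseudoknot(sub)
    stems_i <- if (!is.null(cg))
      vapply(idx, function(k) chord_stem(cg$bg, sh$members[[k]]), "")
    else rep(NA_character_, length(idx))
    inter <- length(unique(sh$backbone[as.integer(sh$chords[idx, ])])) > 1L
    row <- data.frame(structure_id = if (!is.null(cg)) cg$name else "rna",
                      class = cls, genus = gen,
                      stems = paste(stems_i, collapse = ","),
                      intermolecular = inter, angle_deg = NA_real_,
                      alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
                      family = NA_integer_, stringsAsFactors = FALSE)
    if (has3d && !anyNA(stems_i)) {
      ang <- tryCatch(pk_angles(cg, sub, stems_i),
                      error = function(e) NULL)
      if (!is.null(ang)) {
        if (cls == "H") row$angle_deg <- ang[["angle"]]
        if (cls == "K") {
          row$alpha <- ang[["alpha"]]; row$beta <- ang[["beta"]]
          row$gamma <- ang[["gamma"]]
          row$family <- kissing_family(row$alpha, row$beta, row$gamma)
        }
      }
    }
    out <- rbind(out, row)
  }
  out
}

# restrict a chord diagram to a chord subset, re-indexing endpoints
sub_diagram <- function(sh, idx) {
  eps <- sort(as.integer(sh$chords[idx, ]))
  chords <- cbind(match(sh$chords[idx, 1], eps), match(sh$chords[idx, 2], eps))
  structure(list(chords = chords, backbone = sh$backbone[eps],
                 positions = sh$positions[eps], word = chord_word(chords),
                 members = sh$members[idx]),
            class = "chord_diagram")
}

# representative bulge-graph stem of a collapsed helix: the stem holding
# the most of its pairs (ties broken 5'-most)
chord_stem <- function(bg, member_pairs) {
  stems <- bg$stem_of[member_pairs[, 1]]
  stems <- stems[!is.na(stems)]
  if (!length(stems)) return(NA_character_)
  tab <- table(stems)
  best <- names(tab)[tab == max(tab)]
  if (length(best) > 1L) {
    first <- vapply(best, function(s) bg$stems[[s]][1, 1], 0L)
    best <- best[which.min(first)]
  }
  best
}

# which axis side of `stem` faces the backbone region enclosing the other
# chord: "end" (inner) when the partner's strand lies between the stem's
# own strands, else "start"
pk_interface_side <- function(bg, stem, other_positions) {
  sp <- bg$stems[[stem]]
  inner_lo <- sp[nrow(sp), 1]; inner_hi <- sp[nrow(sp), 2]
  if (any(other_positions > inner_lo & other_positions < inner_hi)) "end"
  else "start"
}

pk_stem_vector <- function(cg, stem, other_positions) {
  side <- pk_interface_side(cg$bg, stem, other_positions)
  xy <- cg$coords[[stem]]
  if (side == "end") as.numeric(xy[1, ] - xy[2, ])
  else as.numeric(xy[2, ] - xy[1, ])
}

pk_interface_point <- function(cg, stem, other_positions) {
  side <- pk_interface_side(cg$bg, stem, other_positions)
  cg$coords[[stem]][if (side == "end") 2L else 1L, ]
}

#' Stem angles of a classified pseudoknot
#'
#' Low-level angle measurement used by [pseudoknot_records()]; see that
#' help page for the direction conventions.
#'
#' @param cg a [coarse_grain()] object with pseudoknots retained.
#' @param sub chord diagram of one pseudoknot (H or K pattern).
#' @param stems_i representative stem names, one per chord, in chord
#'   order.
#' @return named numeric vector: \code{angle} for H-type; \code{alpha},
#'   \code{beta}, \code{gamma} for kissing hairpins.
#' @export
pk_angles <- function(cg, sub, stems_i) {
  cls <- classify_pseudoknot(sub)
  # original residue positions of each chord's strands
  strands <- lapply(sub$members, function(m) sort(unique(as.integer(m))))
  if (cls == "H") {
    # interface = the mutually nearest pair of axis ends; both vectors
    # point away from it, so a coaxial stack measures 180 degrees
    xy1 <- cg$coords[[stems_i[1]]]; xy2 <- cg$coords[[stems_i[2]]]
    d <- outer(1:2, 1:2, Vectorize(function(a, b)
      vec_norm(xy1[a, ] - xy2[b, ])))
    near <- which(d == min(d), arr.ind = TRUE)[1, ]
    v1 <- as.numeric(xy1[3L - near[1], ] - xy1[near[1], ])
    v2 <- as.numeric(xy2[3L - near[2], ] - xy2[near[2], ])
    return(c(angle = inter_stem_angle(v1, v2)))
  }
  if (cls != "K") stop("angles are defined for H and K pseudoknots only")
  # kissing chord = the one crossing both others
  nch <- 3L
  ncross <- vapply(seq_len(nch), function(a) sum(vapply(seq_len(nch),
    function(b) a != b && pairs_cross(sub$chords[a, 1], sub$chords[a, 2],
                                      sub$chords[b, 1], sub$chords[b, 2]),
    TRUE)), 0L)
  kiss <- which(ncross == 2L)
  reg <- setdiff(seq_len(nch), kiss)
  # stem 1 = 5'-most regular chord
  reg <- reg[order(sub$positions[sub$chords[reg, 1]])]
  sK <- stems_i[kiss]; s1 <- stems_i[reg[1]]; s2 <- stems_i[reg[2]]
  v1 <- pk_stem_vector(cg, s1, strands[[kiss]])
  v2 <- pk_stem_vector(cg, s2, strands[[kiss]])
  p1 <- pk_interface_point(cg, s1, strands[[kiss]])
  xyK <- cg$coords[[sK]]
  dK <- c(vec_norm(xyK[1, ] - p1), vec_norm(xyK[2, ] - p1))
  vK <- if (dK[1] <= dK[2]) as.numeric(xyK[2, ] - xyK[1, ])
        else as.numeric(xyK[1, ] - xyK[2, ])
  c(alpha = inter_stem_angle(v1, vK),
    beta = inter_stem_angle(v2, vK),
    gamma = inter_stem_angle(v1, v2))
}

#' Structural family of a kissing hairpin
#'
#' Families follow the geometry of the three stems:
#' \describe{
#'   \item{1}{the two regular stems run almost parallel (gamma below
#'     \code{gamma1_max}) with both kissing-stem angles above
#'     \code{ab1_min}; typical of riboswitch aptamers where the second
#'     regular stem stacks onto the kissing stem.}
#'   \item{2}{the regular stems are roughly perpendicular (gamma within
#'     \code{gamma2_range}) and the kissing stem lies along the arc
#'     between them.}
#'   \item{3}{all three stems form one continuous coaxial line: one
#'     kissing-stem angle near 180 degrees and the other near 0 (its
#'     complement near 180); seen in intermolecular kissing dimers.}
#' }
#' Combinations outside all three windows return NA (unclassified).
#'
#' @param alpha,beta,gamma angles in degrees.
#' @param gamma1_max family-1 threshold on gamma (default 32).
#' @param ab1_min family-1 threshold on min(alpha, beta) (default 130).
#' @param gamma2_range family-2 window on gamma (default 60..120).
#' @param coax_min,coax_max family-3 thresholds: one of alpha/beta above
#'   \code{coax_min} (default 160) and the other below \code{coax_max}
#'   (default 20).
#' @return 1, 2, 3 or NA.
#' @export
kissing_family <- function(alpha, beta, gamma, gamma1_max = 32,
                           ab1_min = 130, gamma2_range = c(60, 120),
                           coax_min = 160, coax_max = 20) {
  if (anyNA(c(alpha, beta, gamma))) stop("kissing family needs all angles")
  if ((alpha > coax_min && beta < coax_max) ||
      (alpha < coax_max && beta > coax_min)) return(3L)
  if (gamma < gamma1_max && min(alpha, beta) > ab1_min) return(1L)
  if (gamma >= gamma2_range[1] && gamma <= gamma2_range[2]) return(2L)
  NA_integer_
}
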