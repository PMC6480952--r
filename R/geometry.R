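#' Stem vector relative to a multiloop segment
#'
#' The stem vector points \emph{away} from the given multiloop segment
#' along the helix axis: \code{end - start} when the start side faces the
#' segment, \code{start - end} otherwise.  Its norm is the axis length.
#' With both stem vectors of an adjacent pair pointing away from their
#' connecting segment, an angle of 180 degrees between them is the
#' coaxial-stack geometry.
#'
#' @param cg a [coarse_grain()] object.
#' @param stem stem name.
#' @param ml adjacent element name (usually an m segment).
#' @return numeric length-3 vector.
#' @export
stem_vector <- function(cg, stem, ml) {
  sides <- get_sides(cg, stem, ml)
  xy <- cg$coords[[stem]]
  if (is.null(xy)) stop("stem ", stem, " has no coordinates")
  as.numeric(xy[sides[2], ] - xy[sides[1], ])
}

#' Angle between two stems
#'
#' \code{acos} of the normalized dot product, in degrees within
#' \code{[0, 180]}; symmetric in its arguments.  180 degrees means
#' anti-aligned stem vectors.
#'
#' @param v_i,v_h stem vectors (nonzero).
#' @return angle in degrees.
#' @export
inter_stem_angle <- function(v_i, v_h) vec_angle(v_i, v_h)

# minimum distance between the rays c1 + l*v1 and c2 + l*v2 (l >= 0),
# handling the line-line, point-line and point-point cases exactly
ray_distance <- function(c1, v1, c2, v2) {
  if (vec_norm(v1) < 1e-12 || vec_norm(v2) < 1e-12)
    stop("zero-length axis in ray distance")
  d1 <- vec_unit(v1); d2 <- vec_unit(v2)
  w <- c2 - c1
  point_ray <- function(p, c0, d0) {
    t0 <- max(0, sum((p - c0) * d0))
    vec_norm(p - (c0 + t0 * d0))
  }
  cand <- c(point_ray(c1, c2, d2), point_ray(c2, c1, d1))
  b <- sum(d1 * d2)
  denom <- 1 - b^2
  if (denom > 1e-12) {
    # unconstrained closest points of the two lines
    e <- sum(w * d1); f <- sum(w * d2)
    l1 <- (e - b * f) / denom
    l2 <- (b * e - f) / denom
    if (l1 >= 0 && l2 >= 0)
      cand <- c(cand, vec_norm((c1 + l1 * d1) - (c2 + l2 * d2)))
  }
  min(cand)
}

#' Offset between two stems across a multiloop segment
#'
#' The minimum Euclidean distance between the two rays that start at the
#' stems' multiloop-side axis endpoints and extend along the stem vectors
#' (i.e. away from the segment).  Zero for perfectly coaxial anti-aligned
#' stems whose axes lie on one line.
#'
#' @param cg a [coarse_grain()] object.
#' @param stem1,stem2 stem names adjacent to \code{ml}.
#' @param ml connecting element name.
#' @return offset in Angstrom (>= 0).
#' @export
inter_stem_offset <- function(cg, stem1, stem2, ml) {
  s1 <- get_sides(cg, stem1, ml); s2 <- get_sides(cg, stem2, ml)
  c1 <- cg$coords[[stem1]][s1[1], ]
  c2 <- cg$coords[[stem2]][s2[1], ]
  ray_distance(c1, stem_vector(cg, stem1, ml), c2, stem_vector(cg, stem2, ml))
}

# residue ids of the terminal pair of `stem` on the side facing `elem`
ml_side_pair_ids <- function(bg, ids, stem, elem) {
  sp <- bg$stems[[stem]]
  side <- bg_side(bg, stem, elem)
  pr <- if (side == "start") sp[1, ] else sp[nrow(sp), ]
  ids[as.integer(pr)]
}

#' Relaxed coaxial-stacking call from a stack annotation
#'
#' Two helices connected by a multiloop segment count as stacking when at
#' least one nucleotide of the first helix's segment-side terminal pair
#' lies in a continuous stack together with at least one nucleotide of the
#' second helix's segment-side terminal pair.  Any number of intermediate
#' stacked nucleotides between the stems is allowed (they need not be
#' backbone-connected), and bulged-out nucleotides absent from the stack
#' do not break the call.  This is deliberately more relaxed than
#' atom-level stacking definitions.
#'
#' @param cg a [coarse_grain()] object (coordinates are not needed; a
#'   bare graph plus \code{ids} works too).
#' @param stem1,stem2 stem names adjacent to \code{ml}.
#' @param ml connecting element name.
#' @param stacks stack annotation: list of residue-id vectors; defaults to
#'   the annotation stored in \code{cg}.  Missing annotation is an error,
#'   distinct from a FALSE call.
#' @return logical.
#' @export
helices_are_stacking <- function(cg, stem1, stem2, ml, stacks = NULL) {
  if (is.null(stacks)) stacks <- cg$stacks
  if (is.null(stacks))
    stop("no stack annotation available; pass `stacks` or load one")
  bg <- if (inherits(cg, "cg_rna")) cg$bg else cg
  ids <- cg$ids
  p1 <- ml_side_pair_ids(bg, ids, stem1, ml)
  p2 <- ml_side_pair_ids(bg, ids, stem2, ml)
  for (st in stacks) {
    if (any(p1 %in% st) && any(p2 %in% st)) return(TRUE)
  }
  FALSE
}

#' Angles, offsets and stacking calls for all junction segments
#'
#' For every multiloop segment of every junction, computes the inter-stem
#' angle between the two bounding stems' vectors (pointing away from the
#' segment), their ray offset, the separation vector between the
#' segment-side axis endpoints, and (when a stack annotation is
#' available) the relaxed stacking call.  Output rows are ordered by
#' junction and then by segment; failures in one record are reported as
#' NA fields with a warning while the remaining records are produced.
#'
#' @param cg a [coarse_grain()] object.
#' @param stacks optional stack annotation (defaults to \code{cg$stacks};
#'   if none, the stacking column is NA).
#' @return data frame with columns structure_id, junction_id, ml, stem1,
#'   stem2, angle_deg, offset_ang, sep_x, sep_y, sep_z, stacking_dssr.
#' @export
describe_junctions <- function(cg, stacks = NULL) {
  stopifnot(inherits(cg, "cg_rna"))
  if (is.null(stacks)) stacks <- cg$stacks
  out <- data.frame(structure_id = character(), junction_id = character(),
                    ml = character(), stem1 = character(),
                    stem2 = character(), angle_deg = numeric(),
                    offset_ang = numeric(), sep_x = numeric(),
                    sep_y = numeric(), sep_z = numeric(),
                    stacking_dssr = logical(), stringsAsFactors = FALSE)
  jns <- junctions(cg$bg)
  for (ji in seq_along(jns)) {
    jn <- jns[[ji]]
    k <- length(jn$segments)
    for (si in seq_len(k)) {
      ml <- jn$segments[si]
      stem1 <- jn$stems[si]
      stem2 <- jn$stems[if (si == k) 1L else si + 1L]
      row <- data.frame(structure_id = cg$name,
                        junction_id = paste0("j", ji - 1L),
                        ml = ml, stem1 = stem1, stem2 = stem2,
                        angle_deg = NA_real_, offset_ang = NA_real_,
                        sep_x = NA_real_, sep_y = NA_real_, sep_z = NA_real_,
                        stacking_dssr = NA, stringsAsFactors = FALSE)
      geo <- tryCatch({
        v1 <- stem_vector(cg, stem1, ml)
        v2 <- stem_vector(cg, stem2, ml)
        c1 <- cg$coords[[stem1]][get_sides(cg, stem1, ml)[1], ]
        c2 <- cg$coords[[stem2]][get_sides(cg, stem2, ml)[1], ]
        sep <- c2 - c1
        list(angle = inter_stem_angle(v1, v2),
             offset = inter_stem_offset(cg, stem1, stem2, ml), sep = sep)
      }, error = function(e) {
        warning("junction record ", ml, ": ", conditionMessage(e))
        NULL
      })
      if (!is.null(geo)) {
        row$angle_deg <- geo$angle
        row$offset_ang <- geo$offset
        row$sep_x <- geo$sep[1]; row$sep_y <- geo$sep[2]; row$sep_z <- geo$sep[3]
      }
      if (!is.null(stacks)) {
        row$stacking_dssr <- tryCatch(
          helices_are_stacking(cg, stem1, stem2, ml, stacks = stacks),
          error = function(e) NA)
      }
      out <- rbind(out, row)
    }
  }
  out
}

#' Write a junction or pseudoknot table as TSV
#'
#' Tab-separated with a header line; NA values are written as \code{"."}.
#'
#' @param df data frame.
#' @param path output file (or \code{""} for stdout).
#' @return the path, invisibly.
#' @export
write_tsv_dot <- function(df, path) {
  df2 <- df
  for (k in seq_along(df2)) {
    v <- df2[[k]]
    v <- as.character(v)
    v[is.na(v)] <- "."
    df2[[k]] <- v
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
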