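#' Coarse-grained RNA: cylinder axes for stems, endpoints for loops
#'
#' A \code{cg_rna} couples a [bulge_graph()] with 3D information: every
#' element gets start and end coordinates, and every stem additionally two
#' unit twist vectors orthogonal to its axis that mark the orientation of
#' the terminal base pairs.  Stems are fitted from the C1' atoms of their
#' base pairs (see [fit_stem_axis()]); loop and single-strand endpoints
#' are derived from the adjacent stem axes (see [assign_loop_coords()]).
#'
#' @param bg a [bulge_graph()].
#' @param model an [load_structure()] atom model.
#' @param ids residue-id strings of the graph's n present residues, in
#'   backbone order.
#' @param name structure name used in reports.
#' @param interacting optional residue ids near protein/ligand atoms (see
#'   [interacting_residues()]).
#' @param stacks optional stack annotation (list of residue-id vectors,
#'   see [read_dssr_json()]).
#' @return object of class \code{"cg_rna"}: list with \code{bg},
#'   \code{coords} (element name -> 2x3 matrix, rows start/end),
#'   \code{twists} (stem name -> 2x3), \code{ids}, \code{model},
#'   \code{interacting}, \code{stacks}, \code{name}.
#' @export
coarse_grain <- function(bg, model, ids, name = "rna",
                         interacting = character(), stacks = NULL) {
  stopifnot(inherits(bg, "bulge_graph"), length(ids) == bg$n)
  coords <- list(); twists <- list()
  for (s in names(bg$stems)) {
    fit <- fit_stem_axis(bg$stems[[s]], model, ids)
    coords[[s]] <- rbind(start = fit$start, end = fit$end)
    twists[[s]] <- rbind(start = fit$twist_start, end = fit$twist_end)
  }
  cg <- structure(list(bg = bg, coords = coords, twists = twists,
                       ids = as.character(ids), model = model,
                       interacting = interacting, stacks = stacks,
                       name = name),
                  class = "cg_rna")
  loops <- setdiff(names(bg$elements), names(bg$stems))
  for (el in loops) cg$coords[[el]] <- assign_loop_coords(cg, el)
  cg
}

#' @export
print.cg_rna <- function(x, ...) {
  cat("cg_rna '", x$name, "': ", x$bg$n, " residues, ",
      length(x$bg$stems), " stems fitted\n", sep = "")
  invisible(x)
}

c1_coord <- function(model, id) {
  a <- model$atoms
  k <- which(a$id == id & a$elety == "C1'")
  if (!length(k)) return(NULL)
  as.numeric(a[k[1], c("x", "y", "z")])
}

#' Fit a cylinder axis and twist vectors to a stem
#'
#' The per-pair center is the midpoint of the two C1' atoms; the axis is
#' the total-least-squares line through the pair centers (first principal
#' direction of the centered center cloud), with the line through the two
#' centers for 2-bp stems and the least-squares base-plane normal for the
#' degenerate 1-bp stem.  Axis endpoints are the orthogonal projections of
#' the terminal pair centers onto the fitted line; the start endpoint
#' belongs to the pair containing the stem's 5'-most residue.  The twist
#' vector at each end is the unit component, orthogonal to the axis, of
#' the vector from the axis endpoint to the terminal pair's strand-1 C1'
#' atom -- a deterministic proxy for the groove orientation of the
#' terminal pair.  Pairs whose C1' atoms lack coordinates are dropped from
#' the fit; a stem with no complete pair is an error.
#'
#' @param stem_pairs matrix of paired positions (outermost pair first), as
#'   stored in \code{bg$stems}.
#' @param model atom model.
#' @param ids residue ids by position.
#' @return list with \code{start}, \code{end}, \code{twist_start},
#'   \code{twist_end}.
#' @export
fit_stem_axis <- function(stem_pairs, model, ids) {
  n <- nrow(stem_pairs)
  centers <- matrix(NA_real_, n, 3)
  c1s1 <- matrix(NA_real_, n, 3)   # strand-1 C1' per pair
  keep <- rep(FALSE, n)
  for (k in seq_len(n)) {
    p1 <- c1_coord(model, ids[stem_pairs[k, 1]])
    p2 <- c1_coord(model, ids[stem_pairs[k, 2]])
    if (is.null(p1) || is.null(p2)) next
    centers[k, ] <- (p1 + p2) / 2
    c1s1[k, ] <- p1
    keep[k] <- TRUE
  }
  if (!any(keep))
    stop("cannot fit stem axis: no pair with C1' coordinates among residues ",
         paste(ids[as.integer(stem_pairs)], collapse = ", "))
  centers <- centers[keep, , drop = FALSE]
  c1s1 <- c1s1[keep, , drop = FALSE]
  m <- nrow(centers)
  if (m == 1L) {
    # degenerate 1-bp stem: axis direction = base-plane normal
    both <- rbind(residue_atom_xyz(model$atoms, ids[stem_pairs[1, 1]]),
                  residue_atom_xyz(model$atoms, ids[stem_pairs[1, 2]]))
    ctr <- colMeans(both)
    sv <- svd(sweep(both, 2, ctr))
    dir <- sv$v[, 3]
    # orient deterministically and rigid-equivariantly from the pair frame
    ref <- vec_cross(c1s1[1, ] - centers[1, ], both[2, ] - centers[1, ])
    if (sum(dir * ref) < 0) dir <- -dir
    half <- 1.405 * dir
    start <- centers[1, ] - half
    end <- centers[1, ] + half
  } else {
    ctr <- colMeans(centers)
    dir <- if (m == 2L) vec_unit(centers[2, ] - centers[1, ])
           else svd(sweep(centers, 2, ctr))$v[, 1]
    t_ <- as.numeric(sweep(centers, 2, ctr) %*% dir)
    if (t_[1] > t_[m]) { dir <- -dir; t_ <- -t_ }
    start <- ctr + t_[1] * dir
    end <- ctr + t_[m] * dir
  }
  perp_unit <- function(v, d) {
    w <- v - sum(v * d) * d
    if (vec_norm(w) < 1e-9) return(c(NA_real_, NA_real_, NA_real_))
    vec_unit(w)
  }
  dirn <- vec_unit(end - start)
  list(start = as.numeric(start), end = as.numeric(end),
       twist_start = perp_unit(c1s1[1, ] - start, dirn),
       twist_end = perp_unit(c1s1[m, ] - end, dirn))
}

# side of `stem` that faces `elem`, from backbone connectivity alone:
# "start" is the outer-pair side (containing the stem's 5'-most residue),
# "end" the inner-pair side.
bg_side <- function(bg, stem, elem) {
  if (!(elem %in% (bg$edges[[stem]] %||% character())))
    stop("element ", elem, " is not adjacent to ", stem)
  sp <- bg$stems[[stem]]
  outer <- c(sp[1, 1], sp[1, 2])
  inner <- c(sp[nrow(sp), 1], sp[nrow(sp), 2])
  fl <- bg$flanks[[elem]]
  fl <- fl[!is.na(fl)]
  fl <- fl[!is.na(bg$stem_of[fl]) & bg$stem_of[fl] == stem]
  if (!length(fl)) stop("element ", elem, " has no flank in stem ", stem)
  if (any(fl %in% inner)) "end" else if (any(fl %in% outer)) "start"
  else stop("internal error: flank is not a terminal pair residue")
}

#' Stem sides facing and opposing an adjacent element
#'
#' Returns the indices into the stem's coordinate matrix (1 = start,
#' 2 = end) of the axis endpoint closer to and farther from the given
#' adjacent element.  "Closer" is decided by backbone connectivity (which
#' terminal pair the element touches), not by Euclidean distance.
#'
#' @param cg a [coarse_grain()] object (or a bare [bulge_graph()]).
#' @param stem stem name.
#' @param elem adjacent element name.
#' @return integer vector \code{c(closer, farther)}.
#' @export
get_sides <- function(cg, stem, elem) {
  bg <- if (inherits(cg, "cg_rna")) cg$bg else cg
  side <- bg_side(bg, stem, elem)
  if (side == "start") c(1L, 2L) else c(2L, 1L)
}

#' @rdname coarse_grain
#' @param cg a \code{cg_rna} whose stems are already fitted.
#' @param elem loop element name (h, i, m, f or t).
#' @return \code{assign_loop_coords}: a 2x3 start/end matrix.
#' @export
assign_loop_coords <- function(cg, elem) {
  bg <- cg$bg
  kind <- element_kind(elem)
  stems_adj <- intersect(bg$edges[[elem]] %||% character(), names(bg$stems))
  for (s in stems_adj) if (is.null(cg$coords[[s]]))
    stop("adjacent stem ", s, " has no coordinates")
  stem_face <- function(s) {
    cg$coords[[s]][get_sides(cg, s, elem)[1], ]
  }
  if (kind %in% c("m", "i") && length(stems_adj) >= 2L) {
    fl <- bg$flanks[[elem]]
    s_p <- bg$stem_of[fl[1]]; s_q <- bg$stem_of[fl[2]]
    return(rbind(start = stem_face(s_p), end = stem_face(s_q)))
  }
  if (length(stems_adj) >= 1L) {
    a <- stem_face(stems_adj[1])
    members <- bg$elements[[elem]]
    if (kind %in% c("h", "f", "t") && length(members)) {
      pts <- lapply(cg$ids[members], function(id) c1_coord(cg$model, id))
      pts <- do.call(rbind, pts[!vapply(pts, is.null, TRUE)])
      if (!is.null(pts) && nrow(pts)) {
        d <- sqrt(rowSums(sweep(pts, 2, a)^2))
        return(rbind(start = a, end = pts[which.max(d), ]))
      }
    }
    return(rbind(start = a, end = a))
  }
  # isolated unpaired chain: span its own C1' atoms
  members <- bg$elements[[elem]]
  pts <- lapply(cg$ids[members], function(id) c1_coord(cg$model, id))
  pts <- do.call(rbind, pts[!vapply(pts, is.null, TRUE)])
  if (is.null(pts) || !nrow(pts))
    return(rbind(start = c(NA_real_, NA_real_, NA_real_),
                 end = c(NA_real_, NA_real_, NA_real_)))
  rbind(start = pts[1, ], end = pts[nrow(pts), ])
}

# ---- coarse-grain text format -------------------------------------------

.cg_format_version <- 1L

#' Write and read the coarse-grain text format
#'
#' A versioned plain-text serialization of a \code{cg_rna}: name, length,
#' dot-bracket (with \code{&} at chain breaks), present-only sequence,
#' residue ids, per-element coordinate lines and per-stem twist lines.
#' The round trip \code{read_cg(write_cg(cg))} is lossless for the graph,
#' coordinates, twists, sequence and interacting set.  Files whose twist
#' vectors are not unit length and orthogonal to the stem axis are
#' rejected.
#'
#' @param cg a [coarse_grain()] object.
#' @param path file path.
#' @param seq optional present-only sequence string to store.
#' @return \code{write_cg}: the path, invisibly; \code{read_cg}: a
#'   \code{cg_rna} (without an atom model).
#' @export
write_cg <- function(cg, path, seq = NULL) {
  stopifnot(inherits(cg, "cg_rna"))
  num <- function(x) sprintf("%.6f", x)
  lines <- c(paste("# rnasse-cg", .cg_format_version),
             paste("name", cg$name),
             paste("length", cg$bg$n),
             paste("dotbracket", write_dotbracket(cg$bg$pt)))
  if (!is.null(seq)) lines <- c(lines, paste("seq", seq))
  if (length(cg$ids)) lines <- c(lines, paste("ids", paste(cg$ids, collapse = " ")))
  for (el in names(cg$coords)) {
    xy <- cg$coords[[el]]
    if (any(is.na(xy))) next
    lines <- c(lines, paste("coord", el, paste(num(t(xy)), collapse = " ")))
  }
  for (el in names(cg$twists)) {
    tw <- cg$twists[[el]]
    if (any(is.na(tw))) next
    lines <- c(lines, paste("twist", el, paste(num(t(tw)), collapse = " ")))
  }
  if (length(cg$interacting))
    lines <- c(lines, paste("interacting", paste(cg$interacting, collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cg
#' @export
read_cg <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# rnasse-cg 1$", lines[1]))
    stop("not a version-", .cg_format_version, " coarse-grain file: ", path)
  kv <- strsplit(lines[-1], " ", fixed = TRUE)
  field <- vapply(kv, `[`, "", 1L)
  val1 <- function(key) {
    k <- which(field == key)
    if (!length(k)) return(NULL)
    paste(kv[[k[1]]][-1], collapse = " ")
  }
  name <- val1("name") %||% "rna"
  db <- val1("dotbracket")
  if (is.null(db)) stop("coarse-grain file lacks a dotbracket line")
  bg <- bulge_graph(parse_dotbracket(db))
  n_stated <- as.integer(val1("length"))
  if (!is.na(n_stated) && n_stated != bg$n)
    stop("length line disagrees with dotbracket")
  ids <- strsplit(val1("ids") %||% "", " ")[[1]]
  if (!length(ids) || !nzchar(ids[1])) ids <- residue_id("A", seq_len(bg$n))
  cg <- structure(list(bg = bg, coords = list(), twists = list(),
                       ids = ids, model = NULL,
                       interacting = strsplit(val1("interacting") %||% "",
                                              " ")[[1]],
                       stacks = NULL, name = name),
                  class = "cg_rna")
  cg$interacting <- cg$interacting[nzchar(cg$interacting)]
  for (k in which(field == "coord")) {
    el <- kv[[k]][2]
    v <- as.numeric(kv[[k]][3:8])
    if (length(v) != 6 || any(is.na(v))) stop("bad coord line for ", el)
    cg$coords[[el]] <- rbind(start = v[1:3], end = v[4:6])
  }
  for (k in which(field == "twist")) {
    el <- kv[[k]][2]
    v <- as.numeric(kv[[k]][3:8])
    if (length(v) != 6 || any(is.na(v))) stop("bad twist line for ", el)
    tw <- rbind(start = v[1:3], end = v[4:6])
    ax <- cg$coords[[el]]
    if (is.null(ax)) stop("twist line for ", el, " without coord line")
    dirn <- ax[2, ] - ax[1, ]
    for (r in 1:2) {
      if (abs(vec_norm(tw[r, ]) - 1) > 1e-3)
        stop("twist vector of ", el, " is not unit length")
      if (vec_norm(dirn) > 1e-9 &&
          abs(sum(tw[r, ] * vec_unit(dirn))) > 1e-3)
        stop("twist vector of ", el, " is not orthogonal to the stem axis")
    }
    cg$twists[[el]] <- tw
  }
  sq <- val1("seq")
  if (!is.null(sq)) cg$seq <- sq
  cg
}

#' Load an RNA structure file into coarse-grained objects
#'
#' The high-level entry point: loads a PDB/mmCIF file, obtains canonical
#' base pairs (from the built-in heuristic or an external DSSR-style JSON
#' annotation), splits the chains into base-pair-connected components and
#' returns one fitted \code{cg_rna} per component.  For secondary-structure
#' files (dot-bracket, bpseq, ct) a single coordinate-less object is
#' returned.
#'
#' @param path structure file.
#' @param format \code{"auto"} or one of pdb, mmcif, dotbracket, bpseq, ct.
#' @param annotation \code{"builtin"} or \code{"dssr-json"}.
#' @param dssr_path JSON path when \code{annotation = "dssr-json"}.
#' @param dotbracket optional dot-bracket override for the base pairing of
#'   a 3D file (handy for fixtures and curated annotations); applied to
#'   the present residues of all RNA chains, \code{&}-separated.
#' @param remove_pk drop crossing pairs before decomposing?  Keep them
#'   (\code{FALSE}) when analysing pseudoknots.
#' @param min_stem_bp minimum helix length, see [bulge_graph()].
#' @param permissive passed to [load_structure()].
#' @return list of \code{cg_rna} objects.
#' @export
load_rna <- function(path, format = c("auto", "pdb", "mmcif", "dotbracket",
                                      "bpseq", "ct"),
                     annotation = c("builtin", "dssr-json"),
                     dssr_path = NULL, dotbracket = NULL, remove_pk = TRUE,
                     min_stem_bp = 1L, permissive = FALSE) {
  format <- match.arg(format)
  annotation <- match.arg(annotation)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "mmcif",
                     mmcif = "mmcif", bpseq = "bpseq", ct = "ct",
                     "dotbracket")
  }
  name <- sub("\\.[^.]*$", "", basename(path))
  if (format %in% c("dotbracket", "bpseq", "ct")) {
    parsed <- switch(format,
                     dotbracket = read_dotbracket_file(path),
                     bpseq = read_bpseq(path),
                     ct = read_ct(path))
    pt <- if (remove_pk) remove_pseudoknots(parsed$pt) else parsed$pt
    bg <- bulge_graph(pt, min_stem_bp = min_stem_bp)
    cg <- structure(list(bg = bg, coords = list(), twists = list(),
                         ids = residue_id("A", seq_len(bg$n)), model = NULL,
                         interacting = character(), stacks = NULL,
                         name = name, seq = parsed$seq),
                    class = "cg_rna")
    return(list(cg))
  }
  model <- load_structure(path, format = format, permissive = permissive)
  stacks <- NULL
  if (annotation == "dssr-json") {
    if (is.null(dssr_path)) stop("annotation = 'dssr-json' needs dssr_path")
    ann <- read_dssr_json(dssr_path)
    bp <- ann$pairs
    stacks <- ann$stacks
  } else {
    bp <- detect_basepairs(model)
  }
  inter <- interacting_residues(model)
  out <- list()
  if (!is.null(dotbracket)) {
    # pairing given externally: one object holding all RNA chains
    ids <- unlist(lapply(model$sequences, function(s) s$ids[s$present]),
                  use.names = FALSE)
    lens <- vapply(model$sequences, function(s) sum(s$present), 0L)
    breaks <- utils::head(cumsum(lens), -1L)
    pt <- parse_dotbracket(dotbracket)
    if (length(pt) != length(ids))
      stop("dotbracket length ", length(pt), " does not match the ",
           length(ids), " present RNA residues")
    attr(pt, "breaks") <- sort(unique(c(attr(pt, "breaks"), as.integer(breaks))))
    if (remove_pk) pt <- remove_pseudoknots(pt)
    bg <- bulge_graph(pt, min_stem_bp = min_stem_bp)
    return(list(coarse_grain(bg, model, ids, name = name,
                             interacting = inter, stacks = stacks)))
  }
  comps <- connected_components(model$rna_chains, bp)
  # keep deterministic component order: by first chain's file order
  ord <- order(vapply(comps, function(ch) match(ch[1], model$rna_chains), 0L))
  comps <- comps[ord]
  for (ci in seq_along(comps)) {
    chains <- comps[[ci]]
    chains <- chains[order(match(chains, model$rna_chains))]
    ids <- unlist(lapply(model$sequences[chains],
                         function(s) s$ids[s$present]), use.names = FALSE)
    lens <- vapply(model$sequences[chains], function(s) sum(s$present), 0L)
    breaks <- utils::head(cumsum(lens), -1L)
    pos <- stats::setNames(seq_along(ids), ids)
    pairs_v <- integer(length(ids))
    if (nrow(bp)) for (k in seq_len(nrow(bp))) {
      i <- pos[bp$id1[k]]; j <- pos[bp$id2[k]]
      if (is.na(i) || is.na(j)) next
      pairs_v[i] <- j; pairs_v[j] <- i
    }
    pt <- pair_table(pairs_v, breaks = breaks)
    if (remove_pk) pt <- remove_pseudoknots(pt)
    bg <- bulge_graph(pt, min_stem_bp = min_stem_bp)
    cname <- if (length(comps) > 1L) paste0(name, "_", ci) else name
    out[[length(out) + 1L]] <-
      coarse_grain(bg, model, ids, name = cname,
                   interacting = intersect(inter, ids), stacks = stacks)
  }
  out
}
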