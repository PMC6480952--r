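#' Load a PDB or mmCIF structure into an atom model
#'
#' Reads atomic coordinates (first model only), identifies RNA chains by
#' residue composition, normalizes modified residues to their parent
#' letter, and extracts residues that are declared in the header but have
#' no coordinates (REMARK 465 in PDB, the
#' \code{pdbx_unobs_or_zero_occ_residues} category in mmCIF), which become
#' \code{present = FALSE} entries of the per-chain sequences.
#'
#' A chain counts as RNA when more than half of its residues normalize to
#' A/C/G/U and carry a ribose C1' atom.  Non-RNA chains are retained for
#' the protein/ligand interaction search; a cleaned RNA-only view is
#' available via \code{model$atoms[model$atoms$is_rna, ]}.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or
#'   \code{"mmcif"}.
#' @param permissive map unknown residue codes to N instead of failing?
#' @param mod_table modification table, see [modification_table()].
#' @return object of class \code{"atom_model"}: list with \code{atoms}
#'   (data frame: chain, resno, icode, resname, elety, elesy, x, y, z,
#'   id, is_rna), \code{residues} (one row per residue incl. missing
#'   ones), \code{sequences} (named list of [rna_sequence()] per RNA
#'   chain) and \code{rna_chains}.
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           permissive = FALSE,
                           mod_table = modification_table()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  raw <- tryCatch(
    suppressWarnings(
      if (format == "pdb") bio3d::read.pdb(path, multi = FALSE)
      else bio3d::read.cif(path)),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e)))
  at <- raw$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (!nrow(at)) stop("no atoms in ", path)
  # remove quoting that mmCIF uses around names like "C1'" (only when the
  # same quote character wraps both ends -- a bare trailing prime stays)
  strip_q <- function(x) sub("^\"(.*)\"$", "\\1", sub("^'(.*)'$", "\\1", x))
  atoms <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resname = toupper(strip_q(as.character(at$resid))),
    elety = strip_q(as.character(at$elety)),
    elesy = toupper(ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                           substr(strip_q(as.character(at$elety)), 1, 1),
                           as.character(at$elesy))),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- "A"
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in ", path)

  missing_res <- if (format == "pdb") parse_remark465(path)
                 else parse_cif_unobs(path)
  build_atom_model(atoms, missing_res, source = path,
                   permissive = permissive, mod_table = mod_table)
}

# assemble an atom_model from an atom data frame (chain, resno, icode,
# resname, elety, elesy, x, y, z) and a missing-residue table
build_atom_model <- function(atoms, missing_res = NULL, source = "memory",
                             permissive = FALSE,
                             mod_table = modification_table()) {
  if (is.null(atoms$elesy)) atoms$elesy <- toupper(substr(atoms$elety, 1, 1))
  if (is.null(missing_res))
    missing_res <- data.frame(resname = character(), chain = character(),
                              resno = integer(), icode = character(),
                              stringsAsFactors = FALSE)
  atoms$id <- residue_id(atoms$chain, atoms$resno, atoms$icode)

  # residue table in file order
  ridx <- !duplicated(atoms$id)
  residues <- atoms[ridx, c("chain", "resno", "icode", "resname", "id")]
  residues$present <- TRUE
  if (nrow(missing_res)) {
    missing_res$id <- residue_id(missing_res$chain, missing_res$resno,
                                 missing_res$icode)
    missing_res <- missing_res[!missing_res$id %in% residues$id, , drop = FALSE]
    if (nrow(missing_res)) {
      add <- data.frame(chain = missing_res$chain, resno = missing_res$resno,
                        icode = missing_res$icode,
                        resname = toupper(missing_res$resname),
                        id = missing_res$id, present = FALSE,
                        stringsAsFactors = FALSE)
      residues <- rbind(residues, add)
    }
  }
  # normalize residue codes
  norm <- lapply(residues$resname, function(r3)
    tryCatch(normalize_residue(r3, table = mod_table,
                               permissive = permissive),
             error = function(e) NULL))
  residues$code <- vapply(norm, function(x) if (is.null(x)) NA_character_
                          else x$code, "")
  residues$mod <- vapply(norm, function(x) if (is.null(x)) NA_character_
                         else x$mod, "")
  has_c1 <- residues$id %in% atoms$id[atoms$elety == "C1'"]
  residues$riboseish <- has_c1 | !residues$present

  # chain classification
  rna_chains <- character()
  for (ch in unique(residues$chain)) {
    rr <- residues[residues$chain == ch, ]
    frac <- mean(!is.na(rr$code) & rr$code %in% c("A", "C", "G", "U") &
                 rr$riboseish)
    if (frac > 0.5) rna_chains <- c(rna_chains, ch)
  }
  if (!length(rna_chains))
    message("no RNA chains identified in ", basename(source))
  residues$is_rna <- residues$chain %in% rna_chains
  atoms$is_rna <- atoms$chain %in% rna_chains

  sequences <- list()
  for (ch in rna_chains) {
    rr <- residues[residues$chain == ch, , drop = FALSE]
    # keep file order for present residues; missing ones are sorted in by
    # reference number
    ord <- order(rr$resno, rr$icode, method = "radix")
    rr <- rr[ord, , drop = FALSE]
    code <- rr$code
    code[is.na(code)] <- "N"
    sequences[[ch]] <- rna_sequence(code, ids = rr$id, present = rr$present,
                                    mods = rr$mod)
  }
  structure(list(atoms = atoms, residues = residues, sequences = sequences,
                 rna_chains = rna_chains, source = source),
            class = "atom_model")
}

#' @export
print.atom_model <- function(x, ...) {
  cat("atom_model:", nrow(x$atoms), "atoms,",
      length(unique(x$residues$chain)), "chains (RNA:",
      paste(x$rna_chains, collapse = ","), ")\n")
  invisible(x)
}

parse_remark465 <- function(path) {
  lines <- grep("^REMARK 465", readLines(path, warn = FALSE), value = TRUE)
  out <- data.frame(resname = character(), chain = character(),
                    resno = integer(), icode = character(),
                    stringsAsFactors = FALSE)
  for (ln in lines) {
    tok <- strsplit(trimws(sub("^REMARK 465", "", ln)), "[[:space:]]+")[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok) < 3) next
    m <- regmatches(tok[3], regexec("^(-?[0-9]+)([A-Za-z]?)$", tok[3]))[[1]]
    if (length(m) != 3 || nchar(tok[2]) != 1) next
    out <- rbind(out, data.frame(resname = tok[1], chain = tok[2],
                                 resno = as.integer(m[2]), icode = m[3],
                                 stringsAsFactors = FALSE))
  }
  out
}

parse_cif_unobs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- data.frame(resname = character(), chain = character(),
                    resno = integer(), icode = character(),
                    stringsAsFactors = FALSE)
  start <- grep("_pdbx_unobs_or_zero_occ_residues\\.", lines)
  if (!length(start)) return(out)
  cols <- character(); k <- min(start)
  while (k <= length(lines) &&
         grepl("^_pdbx_unobs_or_zero_occ_residues\\.", lines[k])) {
    cols <- c(cols, sub("^_pdbx_unobs_or_zero_occ_residues\\.", "",
                        trimws(lines[k])))
    k <- k + 1L
  }
  while (k <= length(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln) || startsWith(ln, "#") || startsWith(ln, "_") ||
        startsWith(ln, "loop_")) break
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tok) >= length(cols)) {
      val <- stats::setNames(tok[seq_along(cols)], cols)
      ic <- val[["PDB_ins_code"]] %||% "?"
      out <- rbind(out, data.frame(
        resname = val[["auth_comp_id"]],
        chain = val[["auth_asym_id"]],
        resno = as.integer(val[["auth_seq_id"]]),
        icode = if (ic %in% c("?", ".")) "" else ic,
        stringsAsFactors = FALSE))
    }
    k <- k + 1L
  }
  out
}

# --- canonical base-pair heuristic ---------------------------------------

.ring_atoms <- list(
  purine = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  pyrimidine = c("N1", "C2", "N3", "C4", "C5", "C6"))

# hydrogen-bond atom pairs of the Watson-Crick / wobble edge, given as
# (atom on first base, atom on second base) for the named ordered pair
.hbond_sets <- list(
  AU = list(c("N1", "N3"), c("N6", "O4")),
  GC = list(c("N1", "N3"), c("N2", "O2"), c("O6", "N4")),
  GU = list(c("O6", "N3"), c("N1", "O2")))

residue_atom_xyz <- function(atoms, id) {
  a <- atoms[atoms$id == id, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$elety
  m
}

base_plane <- function(xyz, code) {
  ring <- .ring_atoms[[if (code %in% c("A", "G")) "purine" else "pyrimidine"]]
  pts <- xyz[rownames(xyz) %in% ring, , drop = FALSE]
  if (nrow(pts) < 3) return(NULL)
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  list(center = ctr, normal = sv$v[, 3])
}

#' Detect canonical base pairs from coordinates
#'
#' A geometric fallback heuristic for canonical Watson-Crick (A-U, G-C)
#' and G-U wobble pairs, based on distances along the hydrogen bonds and
#' the coplanarity of the bases: every listed donor-acceptor contact of
#' the pair type must lie within \code{hbond_range}, at least
#' \code{min_contacts} such contacts are required, the base-plane normals
#' may differ by at most \code{max_plane_angle} degrees and the mean
#' inter-plane distance by at most \code{max_plane_dist} Angstrom (which
#' rejects stacked neighbours).  Residues lacking the ring or edge atoms
#' are skipped, so the heuristic can fail for exotic modified residues —
#' use an external annotation (see [read_dssr_json()]) when available.
#' Conflicting candidates are resolved greedily by the smallest mean
#' deviation of the hydrogen-bond lengths from 2.9 Angstrom, which keeps
#' every residue in at most one pair, deterministically.
#'
#' @param model an [load_structure()] result.
#' @param hbond_range allowed donor-acceptor distance window (Angstrom).
#' @param min_contacts minimum number of in-window contacts.
#' @param max_plane_angle maximal angle between base planes (degrees).
#' @param max_plane_dist maximal mean inter-plane distance (Angstrom).
#' @param max_c1_dist candidate-pruning C1'-C1' distance (Angstrom).
#' @return data frame with columns \code{id1}, \code{id2}, \code{kind}
#'   (\code{"WC"} or \code{"GU"}).
#' @export
detect_basepairs <- function(model, hbond_range = c(2.4, 3.5),
                             min_contacts = 2L, max_plane_angle = 30,
                             max_plane_dist = 2.5, max_c1_dist = 12) {
  stopifnot(inherits(model, "atom_model"))
  res <- model$residues
  res <- res[res$is_rna & res$present & !is.na(res$code) &
             res$code %in% c("A", "C", "G", "U"), , drop = FALSE]
  if (nrow(res) < 2) return(data.frame(id1 = character(), id2 = character(),
                                       kind = character()))
  atoms <- model$atoms
  c1 <- atoms[atoms$elety == "C1'" & atoms$id %in% res$id, , drop = FALSE]
  c1 <- c1[!duplicated(c1$id), ]
  res <- res[res$id %in% c1$id, , drop = FALSE]
  c1 <- c1[match(res$id, c1$id), ]
  xyz1 <- as.matrix(c1[, c("x", "y", "z")])
  cand <- which(as.matrix(stats::dist(xyz1)) < max_c1_dist, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  hits <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    ci <- res$code[i]; cj <- res$code[j]
    key <- paste0(ci, cj); swap <- FALSE
    if (!key %in% names(.hbond_sets)) {
      key <- paste0(cj, ci); swap <- TRUE
      if (!key %in% names(.hbond_sets)) next
    }
    a1 <- residue_atom_xyz(atoms, res$id[if (swap) j else i])
    a2 <- residue_atom_xyz(atoms, res$id[if (swap) i else j])
    dists <- vapply(.hbond_sets[[key]], function(hb) {
      if (!(hb[1] %in% rownames(a1)) || !(hb[2] %in% rownames(a2)))
        return(NA_real_)
      vec_norm(a1[hb[1], ] - a2[hb[2], ])
    }, 0)
    ok <- !is.na(dists) & dists >= hbond_range[1] & dists <= hbond_range[2]
    if (any(is.na(dists)) || sum(ok) < min_contacts || !all(ok[!is.na(dists)]))
      next
    p1 <- base_plane(a1, if (swap) cj else ci)
    p2 <- base_plane(a2, if (swap) ci else cj)
    if (is.null(p1) || is.null(p2)) next
    ang <- vec_angle(p1$normal, p2$normal)
    ang <- min(ang, 180 - ang)
    if (ang > max_plane_angle) next
    pdist <- mean(c(abs(sum((p2$center - p1$center) * p1$normal)),
                    abs(sum((p1$center - p2$center) * p2$normal))))
    if (pdist > max_plane_dist) next
    hits[[length(hits) + 1L]] <- list(
      i = i, j = j, kind = if (key == "GU") "GU" else "WC",
      score = mean(abs(dists - 2.9)))
  }
  if (!length(hits)) return(data.frame(id1 = character(), id2 = character(),
                                       kind = character()))
  hits <- hits[order(vapply(hits, `[[`, 0, "score"))]
  used <- rep(FALSE, nrow(res))
  out <- data.frame(id1 = character(), id2 = character(), kind = character(),
                    stringsAsFactors = FALSE)
  for (h in hits) {
    if (used[h$i] || used[h$j]) next
    used[h$i] <- TRUE; used[h$j] <- TRUE
    out <- rbind(out, data.frame(id1 = res$id[h$i], id2 = res$id[h$j],
                                 kind = h$kind, stringsAsFactors = FALSE))
  }
  out
}

#' Residues interacting with protein or ligand atoms
#'
#' An RNA residue is reported when any of its atoms lies within
#' \code{cutoff} Angstrom of a carbon or nitrogen atom of a non-RNA
#' residue.  Knowing these residues helps avoid biases when collecting
#' statistics over bare RNA.  Two implementations are provided: a grid
#' (cell-list) neighbour search and a brute-force double loop; they return
#' identical sets.
#'
#' @param model an [load_structure()] result.
#' @param cutoff distance threshold in Angstrom (default 6.0).
#' @param method \code{"grid"} or \code{"brute"}.
#' @return character vector of residue-id strings (sorted).
#' @export
interacting_residues <- function(model, cutoff = 6.0,
                                 method = c("grid", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "atom_model"))
  atoms <- model$atoms
  rna <- atoms[atoms$is_rna, , drop = FALSE]
  other <- atoms[!atoms$is_rna & atoms$elesy %in% c("C", "N"), , drop = FALSE]
  if (!nrow(rna) || !nrow(other)) return(character())
  A <- as.matrix(rna[, c("x", "y", "z")])
  B <- as.matrix(other[, c("x", "y", "z")])
  hit <- rep(FALSE, nrow(A))
  if (method == "brute") {
    for (k in seq_len(nrow(B))) {
      d2 <- (A[, 1] - B[k, 1])^2 + (A[, 2] - B[k, 2])^2 + (A[, 3] - B[k, 3])^2
      hit <- hit | d2 <= cutoff^2
    }
  } else {
    cell <- function(M) {
      key <- floor(sweep(M, 2, c(0, 0, 0)) / cutoff)
      paste(key[, 1], key[, 2], key[, 3])
    }
    keyA <- cell(A)
    binsA <- split(seq_len(nrow(A)), keyA)
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    for (k in seq_len(nrow(B))) {
      base <- floor(B[k, ] / cutoff)
      for (o in seq_len(nrow(offs))) {
        key <- paste(base[1] + offs[o, 1], base[2] + offs[o, 2],
                     base[3] + offs[o, 3])
        idx <- binsA[[key]]
        if (is.null(idx)) next
        d2 <- (A[idx, 1] - B[k, 1])^2 + (A[idx, 2] - B[k, 2])^2 +
              (A[idx, 3] - B[k, 3])^2
        hit[idx[d2 <= cutoff^2]] <- TRUE
      }
    }
  }
  sort(unique(rna$id[hit]))
}

#' Group chains into base-pair-connected components
#'
#' Chains linked by at least one inter-chain base pair are loaded into the
#' same coarse-grain object; unconnected chains form separate components.
#' The grouping is exactly the connected components of the chain-level
#' pairing graph and is invariant under chain relabelling.
#'
#' @param chains character vector of chain ids.
#' @param pairs data frame with residue-id columns \code{id1}, \code{id2}
#'   (see [detect_basepairs()]).
#' @return list of character vectors of chain ids.
#' @export
connected_components <- function(chains, pairs) {
  chains <- unique(as.character(chains))
  if (!length(chains)) return(list())
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(chains)
  if (nrow(pairs)) {
    c1 <- parse_residue_id(pairs$id1)$chain
    c2 <- parse_residue_id(pairs$id2)$chain
    keep <- c1 %in% chains & c2 %in% chains & c1 != c2
    if (any(keep))
      g <- igraph::add_edges(g, rbind(c1[keep], c2[keep]))
  }
  memb <- igraph::components(g)$membership
  unname(split(chains, memb[chains]))
}

# DSSR nucleotide id: [model:]chain.NAMEnumber[^icode], e.g. "A.C14^B"
dssr_id_to_residue <- function(nt) {
  m <- regmatches(nt,
    regexec("^(?:[0-9]+:)?([^.]+)\\.([A-Za-z0-9]*?)(-?[0-9]+)(?:\\^(.))?$", nt))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) stop("cannot parse DSSR nucleotide id: '", nt[bad][1], "'")
  data.frame(chain = vapply(m, `[`, "", 2L),
             name = vapply(m, `[`, "", 3L),
             number = as.integer(vapply(m, `[`, "", 4L)),
             icode = vapply(m, `[`, "", 5L),
             id = residue_id(vapply(m, `[`, "", 2L),
                             as.integer(vapply(m, `[`, "", 4L)),
                             vapply(m, `[`, "", 5L)),
             stringsAsFactors = FALSE)
}

#' Read base pairs and stacks from a DSSR-style JSON annotation
#'
#' Consumes the JSON artifact written by an external annotation tool: the
#' \code{pairs} array (fields \code{nt1}, \code{nt2}, \code{name}) and the
#' \code{stacks} array (comma-separated nucleotide ids in
#' \code{nts_long}, or an \code{nts} list).  The annotation tool itself is
#' never invoked by this package.
#'
#' @param path JSON file.
#' @param keep_all keep non-canonical pairs too?  By default only
#'   Watson-Crick and wobble pairs are returned.
#' @return list with \code{pairs} (data frame id1, id2, kind) and
#'   \code{stacks} (list of residue-id vectors; each residue appears at
#'   most once per stack).
#' @export
read_dssr_json <- function(path, keep_all = FALSE) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed JSON in '", path, "': ",
                                           conditionMessage(e)))
  pairs <- data.frame(id1 = character(), id2 = character(),
                      kind = character(), stringsAsFactors = FALSE)
  for (p in obj$pairs %||% list()) {
    nm <- p$name %||% "?"
    canonical <- grepl("^WC$|Wobble|^GU$", nm, ignore.case = TRUE)
    if (!canonical && !keep_all) next
    r1 <- dssr_id_to_residue(p$nt1); r2 <- dssr_id_to_residue(p$nt2)
    pairs <- rbind(pairs, data.frame(
      id1 = r1$id, id2 = r2$id,
      kind = if (grepl("Wobble|^GU$", nm, ignore.case = TRUE)) "GU"
             else if (canonical) "WC" else nm,
      stringsAsFactors = FALSE))
  }
  stacks <- lapply(obj$stacks %||% list(), function(s) {
    nts <- if (!is.null(s$nts_long))
      strsplit(s$nts_long, ",", fixed = TRUE)[[1]]
    else unlist(s$nts)
    ids <- dssr_id_to_residue(trimws(nts))$id
    if (anyDuplicated(ids)) stop("residue repeated within a stack")
    ids
  })
  list(pairs = pairs, stacks = stacks)
}
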