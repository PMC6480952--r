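# Brute-force oracles and small generators shared by the tests.  These are
# deliberately independent of the package's own algorithms: subset
# enumeration instead of dynamic programming, explicit boundary tracing
# instead of permutation cycles.

# all perfect matchings of a point set, as lists of 2-column matrices
all_matchings <- function(pts) {
  if (!length(pts)) return(list(matrix(integer(), 0, 2)))
  a <- pts[1]
  out <- list()
  for (k in seq_along(pts)[-1]) {
    for (m in all_matchings(pts[-c(1, k)]))
      out[[length(out) + 1L]] <- rbind(c(a, pts[k]), m)
  }
  out
}

cross_mat <- function(prs) {
  k <- nrow(prs)
  out <- matrix(FALSE, k, k)
  if (k < 2) return(out)
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    i1 <- prs[a, 1]; j1 <- prs[a, 2]; i2 <- prs[b, 1]; j2 <- prs[b, 2]
    if ((i1 < i2 && i2 < j1 && j1 < j2) || (i2 < i1 && i1 < j2 && j2 < j1))
      out[a, b] <- out[b, a] <- TRUE
  }
  out
}

# maximum number of mutually non-crossing pairs, by subset enumeration
oracle_max_noncrossing <- function(prs) {
  k <- nrow(prs)
  if (k == 0) return(0L)
  cm <- cross_mat(prs)
  best <- 0L
  for (mask in 0:(2^k - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    if (length(sel) <= best) next
    if (!any(cm[sel, sel])) best <- length(sel)
  }
  best
}

# boundary components of a chord diagram (backbones concatenated into one
# circle), by tracing the outline of the thickened diagram: every endpoint
# gets a left and a right side point; circle arcs join R(e) to L(next(e)),
# untwisted ribbons join L(e)-R(partner) and R(e)-L(partner).  Each side
# point then has degree 2 and the boundary components are the cycles.
oracle_boundary_components <- function(cd) {
  ne <- 2L * nrow(cd$chords)
  if (!ne) return(0L)
  alpha <- integer(ne)
  alpha[cd$chords[, 1]] <- cd$chords[, 2]
  alpha[cd$chords[, 2]] <- cd$chords[, 1]
  L <- function(e) 2L * e - 1L
  R <- function(e) 2L * e
  nbr <- vector("list", 2L * ne)
  link <- function(a, b) {
    nbr[[a]] <<- c(nbr[[a]], b)
    nbr[[b]] <<- c(nbr[[b]], a)
  }
  for (e in seq_len(ne)) {
    nxt <- if (e == ne) 1L else e + 1L
    link(R(e), L(nxt))                 # circle arc
  }
  for (e in seq_len(ne)) if (e < alpha[e]) {
    link(L(e), R(alpha[e]))            # the two ribbon sides
    link(R(e), L(alpha[e]))
  }
  seen <- rep(FALSE, 2L * ne)
  comps <- 0L
  for (s in seq_len(2L * ne)) {
    if (seen[s]) next
    comps <- comps + 1L
    prev <- 0L; cur <- s
    repeat {
      seen[cur] <- TRUE
      nx <- setdiff(nbr[[cur]], prev)[1]
      if (is.na(nx)) nx <- nbr[[cur]][1]   # two-point multigraph cycles
      prev <- cur; cur <- nx
      if (cur == s) break
    }
  }
  comps
}

oracle_genus <- function(cd) {
  n <- nrow(cd$chords)
  if (!n) return(0L)
  r <- oracle_boundary_components(cd)
  g <- (1 + n - r) / 2
  stopifnot(g == round(g), g >= 0)
  as.integer(g)
}

cd_from_matching <- function(m) {
  chords <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  chords <- chords[order(chords[, 1]), , drop = FALSE]
  structure(list(chords = chords, backbone = rep(1L, 2L * nrow(chords)),
                 positions = seq_len(2L * nrow(chords)),
                 word = rnasse:::chord_word(chords),
                 members = lapply(seq_len(nrow(chords)), function(k)
                   chords[k, , drop = FALSE])),
            class = "chord_diagram")
}

# random partial matching over n positions; crossings allowed
random_pair_table <- function(n, p_pair = 0.35, breaks = integer()) {
  pairs <- integer(n)
  free <- seq_len(n)
  for (attempt in seq_len(n)) {
    if (length(free) < 2 || stats::runif(1) > p_pair) next
    ij <- sort(sample(free, 2))
    if (ij[2] - ij[1] < 2) next
    pairs[ij[1]] <- ij[2]; pairs[ij[2]] <- ij[1]
    free <- setdiff(free, ij)
  }
  pair_table(pairs, breaks = breaks)
}

# build a cg_rna from a single ideal hairpin helix (stem + loop)
hairpin_cg <- function(n_bp = 10, R = diag(3), t = c(0, 0, 0), rise = 2.81) {
  h <- make_ideal_helix(n_bp, R = R, t = t, rise = rise,
                        resno1 = seq_len(n_bp),
                        resno2 = (2 * n_bp + 4 + 1) - seq_len(n_bp))
  far <- rnasse:::transform_points(
    rbind(c(8, 0, (n_bp - 1) * rise + 6), c(0, 8, (n_bp - 1) * rise + 8),
          c(-8, 0, (n_bp - 1) * rise + 6), c(0, -8, (n_bp - 1) * rise + 4)),
    R, t)
  loop <- rnasse:::loop_residues("A", n_bp + 1:4, far)
  fix <- list(atoms = rbind(h$atoms, loop),
              dotbracket = paste0(strrep("(", n_bp), "....",
                                  strrep(")", n_bp)))
  list(cg = load_fixture(fix), truth = h)
}

# build a cg_rna from fixture atoms entirely in memory (no PDB rounding)
cg_from_atoms <- function(fix, remove_pk = TRUE) {
  model <- rnasse:::build_atom_model(fix$atoms)
  ids <- unlist(lapply(model$sequences[model$rna_chains],
                       function(s) s$ids[s$present]), use.names = FALSE)
  pt <- parse_dotbracket(fix$dotbracket)
  if (remove_pk) pt <- remove_pseudoknots(pt)
  stopifnot(length(pt) == length(ids))
  bg <- bulge_graph(pt)
  coarse_grain(bg, model, ids, name = "fixture")
}

# write fixture atoms to a temp PDB and load it, with optional dotbracket
load_fixture <- function(fix, remove_pk = TRUE, ...) {
  pf <- tempfile(fileext = ".pdb")
  write_fixture_pdb(fix$atoms, pf,
                    missing = if (!is.null(fix$missing)) fix$missing)
  on.exit(unlink(pf))
  load_rna(pf, dotbracket = fix$dotbracket, remove_pk = remove_pk, ...)[[1]]
}
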