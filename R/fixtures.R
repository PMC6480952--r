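#' Synthetic structure fixtures
#'
#' Generators for ideal A-form-like helices, composite junction and
#' pseudoknot geometries and toy PDB/mmCIF files, so that every analysis in
#' the package can be exercised without downloading experimental
#' structures.  Helices use a minimal atom set (C1' plus the base ring and
#' Watson-Crick-edge atoms) with per-pair centers placed exactly on the
#' local helix axis, spaced by \code{rise} and rotated by \code{twist} per
#' step; physically realistic backbone geometry is not a goal.
#'
#' @name fixtures
NULL

# Default fiber-model parameters of an A-form helix.
.aform_rise <- 2.81    # Angstrom per base pair
.aform_twist <- 32.7   # degrees per base pair

# --- planar base-pair templates ------------------------------------------
# Coordinates in the pair frame: z = 0 plane, the C1'-C1' axis along x with
# the pair center (C1' midpoint) at the origin.  Watson-Crick-edge
# donor/acceptor distances across the pair are 2.5-3.1 Angstrom, inside the
# detection window of detect_basepairs().

.purine_s1 <- function(base) {
  at <- rbind(
    `C1'` = c(-5.20, 0.00),
    N9 = c(-3.85, -0.15), C8 = c(-4.05, 1.25), N7 = c(-2.90, 1.80),
    C5 = c(-1.95, 0.80), C6 = c(-0.55, 0.80), N1 = c(0.05, -0.40),
    C2 = c(-0.60, -1.55), N3 = c(-1.95, -1.60), C4 = c(-2.55, -0.45))
  if (base == "A") at <- rbind(at, N6 = c(0.15, 1.90))
  if (base == "G") at <- rbind(at, O6 = c(0.15, 1.90), N2 = c(0.10, -2.60))
  at
}

.pyrimidine_s2 <- function(base, wobble_shift = c(0, 0)) {
  at <- rbind(
    `C1'` = c(5.20, 0.00),
    N1 = c(3.85, 0.15), C2 = c(3.05, -0.75), N3 = c(2.95, -0.40),
    C4 = c(3.35, 0.95), C5 = c(4.45, 1.60), C6 = c(4.60, 0.90))
  if (base == "C") at <- rbind(at, O2 = c(2.55, -2.00), N4 = c(3.00, 2.00))
  if (base == "U") at <- rbind(at, O2 = c(2.55, -2.00), O4 = c(3.00, 2.10))
  base_rows <- rownames(at) != "C1'"
  at[base_rows, ] <- sweep(at[base_rows, , drop = FALSE], 2, wobble_shift, "+")
  at
}

# Atom template for one base pair: returns list(s1 = matrix, s2 = matrix)
# of (x, y) coordinates, strand 1 attached at negative x.  The G-U wobble
# shifts the U sideways so that the O6-N3 / N1-O2 contacts form.
pair_template <- function(b1, b2) {
  key <- paste0(b1, b2)
  flip <- FALSE
  if (key %in% c("UA", "CG", "UG")) {
    key <- paste0(b2, b1); tmp <- b1; b1 <- b2; b2 <- tmp
    flip <- TRUE
  }
  tpl <- switch(key,
    AU = list(s1 = .purine_s1("A"), s2 = .pyrimidine_s2("U")),
    GC = list(s1 = .purine_s1("G"), s2 = .pyrimidine_s2("C")),
    GU = list(s1 = .purine_s1("G"),
              s2 = .pyrimidine_s2("U", wobble_shift = c(0.15, 1.60))),
    stop("no base-pair template for ", b1, "-", b2))
  if (flip) {
    # rotate 180 degrees about z: purine moves to strand 2
    tpl <- list(s1 = -tpl$s2, s2 = -tpl$s1)
  }
  tpl
}

wc_complement <- function(b) c(A = "U", U = "A", G = "C", C = "G")[[b]]

empty_atoms <- function() {
  data.frame(chain = character(), resno = integer(), icode = character(),
             resname = character(), elety = character(),
             x = numeric(), y = numeric(), z = numeric(),
             stringsAsFactors = FALSE)
}

atom_rows <- function(chain, resno, resname, xyz, icode = "") {
  data.frame(chain = chain, resno = resno, icode = icode, resname = resname,
             elety = rownames(xyz), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate an ideal helix
#'
#' Builds the minimal-atom duplex of \code{n_bp} stacked base pairs.  The
#' per-pair C1' midpoints lie exactly on the local z axis at
#' \code{z = (k - 1) * rise}, so the helix axis of the untransformed
#' fixture is the z segment from the first to the last pair center; the
#' whole helix is then mapped by the rigid motion \code{(R, t)}.
#'
#' @param n_bp number of base pairs (>= 1).
#' @param seq1 strand-1 sequence (5' to 3', length \code{n_bp}); default
#'   alternating GC.
#' @param seq2 strand-2 sequence aligned to \code{seq1} by pair (i.e.
#'   \code{seq2[k]} pairs \code{seq1[k]}); default Watson-Crick complement.
#' @param rise,twist helical rise (Angstrom) and twist (degrees) per step.
#' @param R,t rigid motion applied to the construction.
#' @param chain1,chain2 chain ids of the two strands.
#' @param resno1,resno2 residue numbers for strand 1 and strand 2, by pair
#'   index (strand 2 numbers normally decrease: its 5' end pairs strand
#'   1's 3' end).
#' @return list with \code{atoms} (data frame), \code{axis_start},
#'   \code{axis_end} (true axis endpoints after the rigid motion, start at
#'   the first pair) and \code{pairs} (matrix of paired residue-id
#'   strings).
#' @export
#' @examples
#' h <- make_ideal_helix(10)
#' h$axis_end - h$axis_start   # (n-1)*rise along z
make_ideal_helix <- function(n_bp, seq1 = NULL, seq2 = NULL,
                             rise = .aform_rise, twist = .aform_twist,
                             R = diag(3), t = c(0, 0, 0),
                             chain1 = "A", chain2 = chain1,
                             resno1 = seq_len(n_bp),
                             resno2 = 2L * n_bp + 1L - seq_len(n_bp)) {
  stopifnot(n_bp >= 1, rise > 0)
  if (is.null(seq1))
    seq1 <- rep(c("G", "C"), length.out = n_bp)
  else
    seq1 <- strsplit(paste(seq1, collapse = ""), "", fixed = TRUE)[[1]]
  stopifnot(length(seq1) == n_bp)
  if (is.null(seq2)) seq2 <- vapply(seq1, wc_complement, "")
  else seq2 <- strsplit(paste(seq2, collapse = ""), "", fixed = TRUE)[[1]]
  stopifnot(length(seq2) == n_bp, length(resno1) == n_bp, length(resno2) == n_bp)
  atoms <- empty_atoms()
  for (k in seq_len(n_bp)) {
    tpl <- pair_template(seq1[k], seq2[k])
    ang <- (k - 1) * twist * pi / 180
    rot <- rotation_about(c(0, 0, 1), ang)
    z <- (k - 1) * rise
    place <- function(xy) {
      xyz <- cbind(xy, 0)
      xyz <- transform_points(xyz, rot, c(0, 0, z))
      transform_points(xyz, R, t)
    }
    a1 <- place(tpl$s1); rownames(a1) <- rownames(tpl$s1)
    a2 <- place(tpl$s2); rownames(a2) <- rownames(tpl$s2)
    atoms <- rbind(atoms,
                   atom_rows(chain1, resno1[k], seq1[k], a1),
                   atom_rows(chain2, resno2[k], seq2[k], a2))
  }
  axis <- transform_points(rbind(c(0, 0, 0), c(0, 0, (n_bp - 1) * rise)), R, t)
  pairs <- cbind(residue_id(chain1, resno1), residue_id(chain2, resno2))
  list(atoms = atoms, axis_start = axis[1, ], axis_end = axis[2, ],
       pairs = pairs)
}

# a single-atom (C1') residue used for loops and linkers
loop_residues <- function(chain, resnos, points, base = "A", icode = NULL) {
  if (is.null(icode)) icode <- rep("", length(resnos))
  out <- empty_atoms()
  for (k in seq_along(resnos)) {
    xyz <- matrix(points[k, ], 1, 3); rownames(xyz) <- "C1'"
    out <- rbind(out, atom_rows(chain, resnos[k], base, xyz, icode = icode[k]))
  }
  out
}

# points interpolated between a and b, pushed slightly sideways
arc_points <- function(a, b, k, bump = 3) {
  if (k == 0) return(matrix(numeric(), 0, 3))
  d <- b - a
  perp <- vec_cross(d, c(0, 0, 1))
  if (vec_norm(perp) < 1e-6) perp <- vec_cross(d, c(0, 1, 0))
  perp <- vec_unit(perp) * bump
  t_ <- seq_len(k) / (k + 1)
  out <- t(vapply(t_, function(s) a + s * d + sin(pi * s) * perp, numeric(3)))
  matrix(out, ncol = 3)
}

#' Three-way-junction fixture with a controlled stem pair
#'
#' Assembles three ideal helices and their connecting loops into a
#' single-chain toy structure whose multiloop segment \code{m0} connects
#' two stems at an exactly known inter-stem angle and ray offset: the
#' closing stem s0 ends at the origin with its stem vector along -z, and
#' s1 starts at \code{(0, offset, 0)} with its stem vector at
#' \code{theta} degrees to s0's.  Because the anchor separation is
#' perpendicular to both stem vectors, the true ray offset equals
#' \code{offset} for every \code{theta}.
#'
#' @param theta inter-stem angle for the (s0, s1) pair, degrees.
#' @param offset ray offset for the (s0, s1) pair, Angstrom.
#' @param n_bp base pairs per helix.
#' @param bulged_nt add an extra bulged-out loop nucleotide in m0?
#' @param modified_residue rename one hairpin-loop residue to 5MC?
#' @param missing_residue drop one m1 loop residue's coordinates (declared
#'   missing in the file header)?
#' @param insertion_code give one m2 loop residue an insertion code?
#' @param protein_chain add a decoy protein chain with one residue within
#'   6 Angstrom of the RNA?
#' @param rise,twist helix parameters.
#' @return list with \code{atoms}, \code{dotbracket} (for the present
#'   residues), \code{truth} (data frame with the constructed angle/offset
#'   of segment m0), \code{missing} (data frame of declared missing
#'   residues), \code{stack_residues} (the m0-facing closing-pair residue
#'   ids of s0 and s1, handy for stack annotations) and
#'   \code{interacting_truth} (residue id expected from the 6-Angstrom
#'   protein search, or NULL).
#' @export
make_junction_fixture <- function(theta, offset, n_bp = 10L,
                                  bulged_nt = FALSE,
                                  modified_residue = FALSE,
                                  missing_residue = FALSE,
                                  insertion_code = FALSE,
                                  protein_chain = FALSE,
                                  rise = .aform_rise, twist = .aform_twist) {
  L <- (n_bp - 1) * rise
  th <- theta * pi / 180
  v1 <- c(0, 0, -1)                       # s0 stem vector (away from m0)
  v2 <- c(sin(th), 0, -cos(th))           # s1 stem vector, angle theta to v1
  c1 <- c(0, 0, 0)                        # s0 inner (junction-side) end
  c2 <- c(0, offset, 0)                   # s1 outer (junction-side) end
  if (abs(vec_angle(v1, v2) - theta) > 1e-6)
    stop("internal error: constructed angle mismatch")

  n_m0 <- if (bulged_nt) 4L else 3L
  n_h <- 4L; n_m <- 3L
  # residue numbering along the chain
  r_s0a <- 1:n_bp
  r_m0 <- max(r_s0a) + seq_len(n_m0)
  r_s1a <- max(r_m0) + seq_len(n_bp)
  r_h1 <- max(r_s1a) + seq_len(n_h)
  r_s1b <- max(r_h1) + seq_len(n_bp)
  r_m1 <- max(r_s1b) + seq_len(n_m)
  r_s2a <- max(r_m1) + seq_len(n_bp)
  r_h2 <- max(r_s2a) + seq_len(n_h)
  r_s2b <- max(r_h2) + seq_len(n_bp)
  r_m2 <- max(r_s2b) + seq_len(n_m)
  r_s0b <- max(r_m2) + seq_len(n_bp)

  # s0: pair 1 (5'-most, outer) at the far end, inner pair at the origin
  h0 <- make_ideal_helix(n_bp, rise = rise, twist = twist,
                         R = diag(3), t = c(0, 0, -L),
                         resno1 = r_s0a, resno2 = rev(r_s0b))
  # s1: pair 1 (outer) faces the junction at c2, body extends along v2
  R1 <- rotation_between(c(0, 0, 1), v2)
  h1 <- make_ideal_helix(n_bp, rise = rise, twist = twist,
                         R = R1, t = c2,
                         resno1 = r_s1a, resno2 = rev(r_s1b))
  # s2: outer end near the junction, pointing off to the side
  v3 <- vec_unit(c(-0.55, 0.25, -0.80))
  c3 <- c(-5, 2, 1)
  R2 <- rotation_between(c(0, 0, 1), v3)
  h2 <- make_ideal_helix(n_bp, rise = rise, twist = twist,
                         R = R2, t = c3,
                         resno1 = r_s2a, resno2 = rev(r_s2b))

  s1_far <- c2 + L * v2
  s2_far <- c3 + L * v3
  atoms <- rbind(
    h0$atoms[h0$atoms$resno %in% r_s0a, ],
    loop_residues("A", r_m0, arc_points(c1, c2 + c(2, 0, 2), n_m0)),
    h1$atoms[h1$atoms$resno %in% r_s1a, ],
    loop_residues("A", r_h1, arc_points(s1_far, s1_far + c(4, 4, 0), n_h)),
    h1$atoms[h1$atoms$resno %in% r_s1b, ],
    loop_residues("A", r_m1, arc_points(c2 + c(-2, 0, 1), c3, n_m)),
    h2$atoms[h2$atoms$resno %in% r_s2a, ],
    loop_residues("A", r_h2, arc_points(s2_far, s2_far + c(-4, 4, 0), n_h)),
    h2$atoms[h2$atoms$resno %in% r_s2b, ],
    loop_residues("A", r_m2, arc_points(c3 + c(2, -2, 0), c1 + c(0, -3, 1), n_m)),
    h0$atoms[h0$atoms$resno %in% r_s0b, ]
  )

  if (modified_residue) {
    atoms$resname[atoms$resno == r_h1[1]] <- "5MC"
  }
  if (insertion_code) {
    # the last m2 residue re-uses the previous number with insertion code B
    k <- atoms$resno == r_m2[n_m]
    atoms$resno[k] <- r_m2[n_m - 1L]
    atoms$icode[k] <- "B"
  }
  missing <- data.frame(resname = character(), chain = character(),
                        resno = integer(), icode = character(),
                        stringsAsFactors = FALSE)
  if (missing_residue) {
    drop_no <- r_m1[2]
    missing <- data.frame(resname = atoms$resname[atoms$resno == drop_no][1],
                          chain = "A", resno = drop_no, icode = "",
                          stringsAsFactors = FALSE)
    atoms <- atoms[atoms$resno != drop_no | atoms$chain != "A", ]
  }
  interacting_truth <- NULL
  if (protein_chain) {
    # decoy protein far away, plus one residue whose N sits 5 A from the
    # C1' of s2's outer 5' residue
    target <- as.numeric(atoms[atoms$resno == r_s2a[1] &
                               atoms$elety == "C1'", c("x", "y", "z")][1, ])
    prot <- empty_atoms()
    for (k in 1:3) {
      xyz <- rbind(N = c(60, 60, 10 + 4 * k), CA = c(61.5, 60, 10 + 4 * k),
                   C = c(62.5, 61, 10 + 4 * k), O = c(62.5, 62.2, 10 + 4 * k))
      prot <- rbind(prot, atom_rows("P", k, "ALA", xyz))
    }
    near <- rbind(N = target + c(5, 0, 0), CA = target + c(6.5, 0, 0),
                  C = target + c(7.5, 1, 0), O = target + c(7.5, 2.2, 0))
    prot <- rbind(prot, atom_rows("P", 4L, "ALA", near))
    atoms <- rbind(atoms, prot)
    interacting_truth <- residue_id("A", r_s2a[1])
  }

  db_m0 <- if (bulged_nt) "...." else "..."
  db <- paste0(strrep("(", n_bp), db_m0,
               strrep("(", n_bp), strrep(".", n_h), strrep(")", n_bp),
               if (missing_residue) strrep(".", n_m - 1L) else strrep(".", n_m),
               strrep("(", n_bp), strrep(".", n_h), strrep(")", n_bp),
               strrep(".", n_m), strrep(")", n_bp))
  truth <- data.frame(segment = "m0", stem1 = "s0", stem2 = "s1",
                      angle = theta, offset = offset,
                      stringsAsFactors = FALSE)
  stack_residues <- list(
    s0 = residue_id("A", c(r_s0a[n_bp], r_s0b[1])),   # s0 inner pair
    s1 = residue_id("A", c(r_s1a[1], r_s1b[n_bp])))   # s1 outer pair
  list(atoms = atoms, dotbracket = db, truth = truth, missing = missing,
       stack_residues = stack_residues,
       interacting_truth = interacting_truth)
}

#' Kissing-hairpin fixture with controlled alpha/beta/gamma angles
#'
#' Builds two hairpins whose loops pair with each other through a kissing
#' stem.  The kissing stem runs along +z; the two regular stems are placed
#' so that, under the package's angle conventions (stem vectors away from
#' the loop interface, kissing-stem vector from its 5'-regular-stem side
#' end to the other end), the measured angles are exactly \code{alpha},
#' \code{beta} and \code{gamma}.  The three angles must be mutually
#' realizable (spherical triangle inequality), otherwise generation fails.
#'
#' @param alpha,beta,gamma target angles in degrees.
#' @param intermolecular build the two hairpins on separate chains (the
#'   kissing interaction of an RNA dimer) instead of one chain?
#' @param n_stem,n_kiss base pairs in the regular and kissing stems.
#' @param rise,twist helix parameters.
#' @return list with \code{atoms}, \code{dotbracket}, \code{truth}
#'   (data frame of the constructed angles).
#' @export
make_kissing_fixture <- function(alpha, beta, gamma, intermolecular = FALSE,
                                 n_stem = 6L, n_kiss = 5L,
                                 rise = .aform_rise, twist = .aform_twist) {
  a <- alpha * pi / 180; b <- beta * pi / 180; g <- gamma * pi / 180
  denom <- sin(a) * sin(b)
  cphi <- if (abs(denom) < 1e-9) {
    if (abs(cos(g) - cos(a) * cos(b)) < 1e-6) 1 else NA_real_
  } else (cos(g) - cos(a) * cos(b)) / denom
  if (is.na(cphi) || abs(cphi) > 1 + 1e-9)
    stop("unrealizable angle combination: alpha=", alpha, " beta=", beta,
         " gamma=", gamma)
  cphi <- max(-1, min(1, cphi))
  phi <- acos(cphi)
  vK <- c(0, 0, 1)
  v1 <- c(sin(a), 0, cos(a))
  v2 <- c(sin(b) * cos(phi), sin(b) * sin(phi), cos(b))
  LK <- (n_kiss - 1) * rise
  Ls <- (n_stem - 1) * rise
  P0 <- c(0, 0, 0); P1 <- c(0, 0, LK)     # kissing-stem axis ends
  E1 <- P0 + c(3.0, 0.5, -3.5)            # stem1 interface (inner) end
  E2 <- P1 + c(3.0, -0.5, 3.5)            # stem2 interface (inner) end

  ch1 <- "A"; ch2 <- if (intermolecular) "B" else "A"
  n_lp <- 2L  # unpaired nt on each side of a kissing strand
  # chain layout (intramolecular): s1a, lp, K1, lp, s1b, linker, s2a, lp, K2, lp, s2b
  r <- 0L; nxt <- function(k) { out <- r + seq_len(k); r <<- r + k; out }
  r_s1a <- nxt(n_stem); r_lp1 <- nxt(n_lp); r_K1 <- nxt(n_kiss)
  r_lp2 <- nxt(n_lp); r_s1b <- nxt(n_stem)
  n_link <- if (intermolecular) 0L else 4L
  r_link <- nxt(n_link)
  if (intermolecular) r <- 0L
  r_s2a <- nxt(n_stem); r_lp3 <- nxt(n_lp); r_K2 <- nxt(n_kiss)
  r_lp4 <- nxt(n_lp); r_s2b <- nxt(n_stem)

  # stem1: inner pair at E1, axis direction inner -> outer along v1
  Rs1 <- rotation_between(c(0, 0, 1), -v1)
  t1 <- E1 - as.numeric(Rs1 %*% c(0, 0, (n_stem - 1) * rise))
  h1 <- make_ideal_helix(n_stem, rise = rise, twist = twist, R = Rs1, t = t1,
                         chain1 = ch1, chain2 = ch1,
                         resno1 = r_s1a, resno2 = rev(r_s1b))
  # kissing stem: pair 1 = (K1 start, K2 end) at P0, axis to P1
  hK <- make_ideal_helix(n_kiss, rise = rise, twist = twist,
                         R = diag(3), t = P0,
                         chain1 = ch1, chain2 = ch2,
                         resno1 = r_K1, resno2 = rev(r_K2))
  Rs2 <- rotation_between(c(0, 0, 1), -v2)
  t2 <- E2 - as.numeric(Rs2 %*% c(0, 0, (n_stem - 1) * rise))
  h2 <- make_ideal_helix(n_stem, rise = rise, twist = twist, R = Rs2, t = t2,
                         chain1 = ch2, chain2 = ch2,
                         resno1 = r_s2a, resno2 = rev(r_s2b))

  s1_out <- E1 + Ls * v1; s2_out <- E2 + Ls * v2
  atoms <- rbind(
    h1$atoms[h1$atoms$resno %in% r_s1a, ],
    loop_residues(ch1, r_lp1, arc_points(E1, P0, n_lp)),
    hK$atoms[hK$atoms$resno %in% r_K1 & hK$atoms$chain == ch1, ],
    loop_residues(ch1, r_lp2, arc_points(P1, E1 + c(0, 4, 0), n_lp)),
    h1$atoms[h1$atoms$resno %in% r_s1b, ],
    if (n_link) loop_residues(ch1, r_link,
                              arc_points(s1_out, s2_out, n_link)) else NULL,
    h2$atoms[h2$atoms$resno %in% r_s2a & h2$atoms$chain == ch2, ],
    loop_residues(ch2, r_lp3, arc_points(E2, P1, n_lp)),
    hK$atoms[hK$atoms$resno %in% r_K2 & hK$atoms$chain == ch2, ],
    loop_residues(ch2, r_lp4, arc_points(P0, E2 + c(0, -4, 0), n_lp)),
    h2$atoms[h2$atoms$resno %in% r_s2b & h2$atoms$chain == ch2, ]
  )
  lp <- strrep(".", n_lp)
  part1 <- paste0(strrep("(", n_stem), lp, strrep("[", n_kiss), lp,
                  strrep(")", n_stem))
  part2 <- paste0(strrep("(", n_stem), lp, strrep("]", n_kiss), lp,
                  strrep(")", n_stem))
  db <- if (intermolecular) paste0(part1, "&", part2)
        else paste0(part1, strrep(".", n_link), part2)
  truth <- data.frame(alpha = alpha, beta = beta, gamma = gamma,
                      intermolecular = intermolecular)
  list(atoms = atoms, dotbracket = db, truth = truth)
}

#' H-type pseudoknot fixture at a controlled inter-stem angle
#'
#' One chain whose hairpin loop pairs downstream residues, giving the
#' chord pattern ABAB.  The two helices are placed so that the angle
#' between their stem vectors (each pointing away from the crossing
#' interface, i.e. away from its own inner loop side) is exactly
#' \code{angle}; 180 degrees is the coaxially stacked geometry.
#'
#' @param angle target inter-stem angle in degrees.
#' @param n_bp base pairs per helix.
#' @param rise,twist helix parameters.
#' @return list with \code{atoms}, \code{dotbracket}, \code{truth}.
#' @export
make_htype_fixture <- function(angle, n_bp = 6L,
                               rise = .aform_rise, twist = .aform_twist) {
  th <- angle * pi / 180
  v1 <- c(0, 0, -1)                       # stem 1 vector (away from interface)
  vK <- c(sin(th), 0, -cos(th))           # pk stem vector
  L <- (n_bp - 1) * rise
  E1 <- c(0, 0, 0)                        # stem 1 inner (interface) end
  EK <- c(2.5, 0, 3.5)                    # pk stem inner (interface) end
  r <- 0L; nxt <- function(k) { out <- r + seq_len(k); r <<- r + k; out }
  r_s1a <- nxt(n_bp); r_lp1 <- nxt(2L); r_Ka <- nxt(n_bp)
  r_lp2 <- nxt(2L); r_s1b <- nxt(n_bp); r_lp3 <- nxt(2L); r_Kb <- nxt(n_bp)
  # stem 1: inner pair at E1, body along v1
  R1 <- rotation_between(c(0, 0, 1), -v1)
  t1 <- E1 - as.numeric(R1 %*% c(0, 0, L))
  h1 <- make_ideal_helix(n_bp, rise = rise, twist = twist, R = R1, t = t1,
                         resno1 = r_s1a, resno2 = rev(r_s1b))
  # pk stem: inner pair = 3'-most pair... its outer pair is the 5'-most of
  # strand Ka, which sits deepest in stem 1's loop; the interface end is
  # the inner-pair end only from stem 1's viewpoint.  Geometrically we
  # anchor the end closest to stem 1 at EK and extend along vK.
  RK <- rotation_between(c(0, 0, 1), vK)
  hK <- make_ideal_helix(n_bp, rise = rise, twist = twist, R = RK, t = EK,
                         resno1 = r_Ka, resno2 = rev(r_Kb))
  atoms <- rbind(
    h1$atoms[h1$atoms$resno %in% r_s1a, ],
    loop_residues("A", r_lp1, arc_points(E1, EK, 2L)),
    hK$atoms[hK$atoms$resno %in% r_Ka, ],
    loop_residues("A", r_lp2, arc_points(EK, E1 + c(0, 4, 0), 2L)),
    h1$atoms[h1$atoms$resno %in% r_s1b, ],
    loop_residues("A", r_lp3, arc_points(E1 + c(0, -4, 0), EK + c(0, -4, 0), 2L)),
    hK$atoms[hK$atoms$resno %in% r_Kb, ]
  )
  db <- paste0(strrep("(", n_bp), "..", strrep("[", n_bp), "..",
               strrep(")", n_bp), "..", strrep("]", n_bp))
  list(atoms = atoms, dotbracket = db,
       truth = data.frame(angle = angle))
}

#' Write a DSSR-style JSON stack annotation
#'
#' Emits the minimal dialect consumed by [read_dssr_json()]: a
#' \code{pairs} array with \code{nt1}/\code{nt2}/\code{name} fields and a
#' \code{stacks} array whose entries carry comma-separated nucleotide ids
#' in \code{nts_long}.  Nucleotide ids follow the
#' \code{chain.NAMEnumber[^icode]} grammar, e.g. \code{"A.G14"} or
#' \code{"A.C14^B"}.
#'
#' @param stacks list of character vectors of residue-id strings (see
#'   [residue_id()]), each one continuous stack in order.
#' @param pairs optional 2-column matrix of residue-id strings.
#' @param resnames optional named map residue id -> residue name used in
#'   the DSSR ids (defaults to "N").
#' @param path optional output file; if NULL the JSON text is returned.
#' @return path (invisibly) or JSON text.
#' @export
make_stack_annotation <- function(stacks = list(), pairs = NULL,
                                  resnames = NULL, path = NULL) {
  to_dssr <- function(ids) {
    p <- parse_residue_id(ids)
    nm <- if (is.null(resnames)) rep("N", length(ids))
          else unname(resnames[ids])
    nm[is.na(nm)] <- "N"
    paste0(p$chain, ".", nm, p$number,
           ifelse(nzchar(p$icode), paste0("^", p$icode), ""))
  }
  obj <- list(
    pairs = if (is.null(pairs) || !nrow(pairs)) list() else
      lapply(seq_len(nrow(pairs)), function(k)
        list(nt1 = to_dssr(pairs[k, 1]), nt2 = to_dssr(pairs[k, 2]),
             name = "WC")),
    stacks = lapply(stacks, function(s)
      list(num_nts = length(s), nts_long = paste(to_dssr(s), collapse = ","))))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Write fixture atoms as a toy PDB or mmCIF file
#'
#' \code{write_fixture_pdb} emits standard fixed-width ATOM records (plus
#' REMARK 465 entries for declared missing residues);
#' \code{write_fixture_cif} emits the equivalent \code{atom_site} loop and
#' a \code{pdbx_unobs_or_zero_occ_residues} loop.
#'
#' @param atoms data frame with columns chain, resno, icode, resname,
#'   elety, x, y, z (as produced by the fixture generators).
#' @param path output file.
#' @param missing data frame of missing residues (resname, chain, resno,
#'   icode).
#' @return the path, invisibly.
#' @export
write_fixture_pdb <- function(atoms, path, missing = NULL) {
  lines <- character()
  if (!is.null(missing) && nrow(missing)) {
    lines <- c(lines, "REMARK 465 MISSING RESIDUES",
               "REMARK 465   M RES C SSSEQI",
               sprintf("REMARK 465     %-3s %s %5d%s",
                       missing$resname, missing$chain, missing$resno,
                       ifelse(nzchar(missing$icode), missing$icode, " ")))
  }
  elesy <- substr(atoms$elety, 1, 1)
  for (k in seq_len(nrow(atoms))) {
    nm <- atoms$elety[k]
    nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
    lines <- c(lines, sprintf(
      "ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      k, nm_fmt, " ", atoms$resname[k], atoms$chain[k], atoms$resno[k],
      ifelse(nzchar(atoms$icode[k]), atoms$icode[k], " "),
      atoms$x[k], atoms$y[k], atoms$z[k], 1, 0, elesy[k]))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fixture_pdb
#' @export
write_fixture_cif <- function(atoms, path, missing = NULL) {
  lines <- c("data_fixture", "#", "loop_",
             "_atom_site.group_PDB", "_atom_site.id",
             "_atom_site.type_symbol", "_atom_site.label_atom_id",
             "_atom_site.label_alt_id", "_atom_site.label_comp_id",
             "_atom_site.label_asym_id", "_atom_site.label_entity_id",
             "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
             "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
             "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
             "_atom_site.pdbx_formal_charge",
             "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
             "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
             "_atom_site.pdbx_PDB_model_num")
  elesy <- substr(atoms$elety, 1, 1)
  lines <- c(lines, sprintf(
    "ATOM %d %s \"%s\" . %s %s 1 %d %s %.3f %.3f %.3f 1.00 0.00 ? %d %s %s \"%s\" 1",
    seq_len(nrow(atoms)), elesy, atoms$elety, atoms$resname, atoms$chain,
    atoms$resno, ifelse(nzchar(atoms$icode), atoms$icode, "?"),
    atoms$x, atoms$y, atoms$z, atoms$resno, atoms$resname, atoms$chain,
    atoms$elety))
  if (!is.null(missing) && nrow(missing)) {
    lines <- c(lines, "#", "loop_",
               "_pdbx_unobs_or_zero_occ_residues.polymer_flag",
               "_pdbx_unobs_or_zero_occ_residues.auth_asym_id",
               "_pdbx_unobs_or_zero_occ_residues.auth_comp_id",
               "_pdbx_unobs_or_zero_occ_residues.auth_seq_id",
               "_pdbx_unobs_or_zero_occ_residues.PDB_ins_code",
               sprintf("Y %s %s %d %s", missing$chain, missing$resname,
                       missing$resno,
                       ifelse(nzchar(missing$icode), missing$icode, "?")))
  }
  lines <- c(lines, "#")
  writeLines(lines, path)
  invisible(path)
}
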