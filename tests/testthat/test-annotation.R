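test_that("toy PDB loads with modified, missing and insertion-coded residues", {
  fix <- make_junction_fixture(140, 5, modified_residue = TRUE,
                               missing_residue = TRUE,
                               insertion_code = TRUE, protein_chain = TRUE)
  pf <- tempfile(fileext = ".pdb")
  write_fixture_pdb(fix$atoms, pf, missing = fix$missing)
  m <- load_structure(pf)
  expect_equal(m$rna_chains, "A")
  expect_true("P" %in% m$residues$chain)          # protein chain retained
  expect_false("P" %in% m$rna_chains)
  s <- m$sequences$A
  # the 5MC residue is stored as C with its modification annotated
  mod_no <- fix$atoms$resno[fix$atoms$resname == "5MC"][1]
  mod_rec <- resolve_index(s, residue_id("A", mod_no))
  expect_equal(mod_rec$code, "C")
  expect_equal(mod_rec$mod, "5MC")
  # the declared missing residue is present = FALSE
  miss_id <- residue_id(fix$missing$chain, fix$missing$resno)
  rec <- resolve_index(s, miss_id)
  expect_false(rec$present)
  expect_true(is.na(rec$position))
  expect_gt(nchar(missing_residue_view(s)), nchar(seq_string(s)))
  # the insertion-coded residue resolves by its full id
  ic <- fix$atoms$icode == "B" & fix$atoms$chain == "A"
  expect_true(any(ic))
  icode_id <- residue_id("A", fix$atoms$resno[ic][1], "B")
  expect_true(resolve_index(s, icode_id)$present)
  unlink(pf)
})

test_that("mmCIF rendering of the same content yields the same model", {
  fix <- make_junction_fixture(90, 5, missing_residue = TRUE)
  pf <- tempfile(fileext = ".pdb"); cf <- tempfile(fileext = ".cif")
  write_fixture_pdb(fix$atoms, pf, missing = fix$missing)
  write_fixture_cif(fix$atoms, cf, missing = fix$missing)
  mp <- load_structure(pf); mc <- load_structure(cf)
  expect_equal(mp$residues$id, mc$residues$id)
  expect_equal(mp$residues$present, mc$residues$present)
  expect_equal(mp$atoms[, c("x", "y", "z")], mc$atoms[, c("x", "y", "z")],
               tolerance = 1e-6)
  expect_equal(seq_string(mp$sequences$A), seq_string(mc$sequences$A))
  unlink(c(pf, cf))
})

test_that("base-pair detection recovers every intended pair of ideal helices", {
  for (n in c(2, 5, 9, 14, 20)) {
    set.seed(n)
    seq1 <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                  collapse = "")
    h <- make_ideal_helix(n, seq1 = seq1)
    pf <- tempfile(fileext = ".pdb")
    write_fixture_pdb(h$atoms, pf)
    bp <- detect_basepairs(load_structure(pf))
    expect_equal(nrow(bp), n)
    got <- apply(cbind(bp$id1, bp$id2), 1, function(r) paste(sort(r), collapse = "+"))
    want <- apply(h$pairs, 1, function(r) paste(sort(r), collapse = "+"))
    expect_setequal(got, want)
    expect_true(all(bp$kind == "WC"))
    unlink(pf)
  }
})

test_that("wobble pairs are detected and labelled GU", {
  h <- make_ideal_helix(4, seq1 = "GGGG", seq2 = "CUCU")
  pf <- tempfile(fileext = ".pdb")
  write_fixture_pdb(h$atoms, pf)
  bp <- detect_basepairs(load_structure(pf))
  expect_equal(nrow(bp), 4)
  expect_equal(sort(table(bp$kind), decreasing = TRUE),
               sort(table(c("WC", "GU", "WC", "GU")), decreasing = TRUE))
  unlink(pf)
})

test_that("distant or non-coplanar bases do not pair", {
  h <- make_ideal_helix(1, seq1 = "G")
  a <- h$atoms
  # pull the partner 15 Angstrom away
  far <- a
  sel <- far$resno == 2
  far$x[sel] <- far$x[sel] + 15
  pf <- tempfile(fileext = ".pdb"); write_fixture_pdb(far, pf)
  expect_equal(nrow(detect_basepairs(load_structure(pf))), 0)
  # rotate the partner 60 degrees out of plane about the C1'-C1' axis
  rot <- a
  R <- rnasse:::rotation_about(c(1, 0, 0), 60 * pi / 180)
  pivot <- as.numeric(rot[sel & rot$elety == "N3", c("x", "y", "z")])
  xyz <- as.matrix(rot[sel, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, pivot) %*% t(R), 2, pivot, "+")
  rot[sel, c("x", "y", "z")] <- xyz
  pf2 <- tempfile(fileext = ".pdb"); write_fixture_pdb(rot, pf2)
  expect_equal(nrow(detect_basepairs(load_structure(pf2))), 0)
  unlink(c(pf, pf2))
})

test_that("interaction search honours the 6 A cutoff and C/N-only rule", {
  h <- make_ideal_helix(2, seq1 = "GC")
  base <- h$atoms
  target <- as.numeric(base[base$resno == 1 & base$elety == "C1'",
                            c("x", "y", "z")])
  prot <- function(offset, elety) {
    xyz <- matrix(target + offset, 1, 3); rownames(xyz) <- elety
    rnasse:::atom_rows("P", 1L, "ALA", xyz)
  }
  run <- function(extra) {
    pf <- tempfile(fileext = ".pdb")
    write_fixture_pdb(rbind(base, extra), pf)
    on.exit(unlink(pf))
    interacting_residues(load_structure(pf))
  }
  # offsets point away from the helix so only the 5.9/6.1 contact matters
  expect_true("A:1" %in% run(prot(c(-5.9, 0, 0), "N")))   # inside cutoff
  expect_length(run(prot(c(-6.1, 0, 0), "N")), 0)         # outside
  expect_length(run(prot(c(-3.0, 0, 0), "O")), 0)         # O never counts
})

test_that("grid and brute-force interaction searches agree on random clouds", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 40
    pts <- matrix(runif(3 * n, 0, 30), ncol = 3)
    atoms <- rnasse:::empty_atoms()
    for (k in 1:(n / 2)) {
      xyz <- matrix(pts[k, ], 1, 3); rownames(xyz) <- "C1'"
      atoms <- rbind(atoms, rnasse:::atom_rows("A", k, "A", xyz))
    }
    for (k in (n / 2 + 1):n) {
      xyz <- matrix(pts[k, ], 1, 3)
      rownames(xyz) <- sample(c("N", "CA", "O"), 1)
      atoms <- rbind(atoms, rnasse:::atom_rows("P", k, "ALA", xyz))
    }
    pf <- tempfile(fileext = ".pdb")
    write_fixture_pdb(atoms, pf)
    m <- load_structure(pf)
    expect_identical(interacting_residues(m, method = "grid"),
                     interacting_residues(m, method = "brute"))
    unlink(pf)
  }
})

test_that("chain components follow inter-chain pairs, invariant to labels", {
  pr <- function(a, b) data.frame(id1 = a, id2 = b, stringsAsFactors = FALSE)
  expect_equal(connected_components(c("A", "B"), pr("A:5", "B:9")),
               list(c("A", "B")))
  none <- data.frame(id1 = character(), id2 = character())
  expect_length(connected_components(c("A", "B"), none), 2)
  got <- connected_components(c("A", "B", "C"), pr("A:5", "B:9"))
  expect_setequal(lapply(got, sort), list(c("A", "B"), "C"))
  # relabelling invariance
  relab <- connected_components(c("C", "B", "A"), pr("C:5", "B:9"))
  expect_setequal(lapply(relab, sort), list(c("B", "C"), "A"))
})

test_that("DSSR-style JSON annotations parse ids, pairs and stacks", {
  j <- make_stack_annotation(
    stacks = list(c("A:1", "A:2", "A:3")),
    pairs = cbind("A:1", "A:10"),
    resnames = c("A:1" = "G", "A:2" = "C", "A:3" = "5MC", "A:10" = "C"))
  jf <- tempfile(fileext = ".json"); writeLines(j, jf)
  d <- read_dssr_json(jf)
  expect_equal(d$stacks, list(c("A:1", "A:2", "A:3")))
  expect_equal(d$pairs$id1, "A:1")
  expect_equal(d$pairs$kind, "WC")
  # empty stacks array
  jf2 <- tempfile(fileext = ".json")
  writeLines(make_stack_annotation(stacks = list()), jf2)
  expect_length(read_dssr_json(jf2)$stacks, 0)
  # insertion-code grammar
  expect_equal(rnasse:::dssr_id_to_residue("A.C14^B")$id, "A:14B")
  expect_equal(rnasse:::dssr_id_to_residue("A.5MC14")$name, "5MC")
  expect_equal(rnasse:::dssr_id_to_residue("2:B.U-1")$id, "B:-1")
  expect_error(rnasse:::dssr_id_to_residue("garbage"), "cannot parse")
  # malformed JSON
  jf3 <- tempfile(); writeLines("{not json", jf3)
  expect_error(read_dssr_json(jf3), "malformed JSON")
  unlink(c(jf, jf2, jf3))
})
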