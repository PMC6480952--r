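test_that("axis fitting recovers direction, length and orientation", {
  hp <- hairpin_cg(10)
  ax <- hp$cg$coords$s0
  d <- ax["end", ] - ax["start", ]
  expect_lt(vec_angle(d, c(0, 0, 1)), 1)
  expect_equal(rnasse:::vec_norm(d), 9 * 2.81, tolerance = 0.05)
  # start is at the pair of the 5'-most residue (z = 0 side)
  expect_lt(abs(ax["start", 3]), 0.5)
  # rotating the input rotates the fitted axis identically
  R <- rnasse:::rotation_about(c(1, 2, 0.5), 1.1)
  hp2 <- hairpin_cg(10, R = R, t = c(3, -2, 7))
  d2 <- hp2$cg$coords$s0["end", ] - hp2$cg$coords$s0["start", ]
  expect_lt(vec_angle(d2, as.numeric(R %*% c(0, 0, 1))), 1)
})

test_that("axis length tracks (n-1) * rise across stem sizes", {
  for (n in c(4, 7, 12, 20)) {
    hp <- hairpin_cg(n)
    len <- rnasse:::vec_norm(hp$cg$coords$s0["end", ] - hp$cg$coords$s0["start", ])
    expect_equal(len, (n - 1) * 2.81, tolerance = 0.05 * (n - 1) * 2.81)
  }
})

test_that("twist vectors are unit length and orthogonal to the axis", {
  set.seed(17)
  for (rep in 1:5) {
    R <- rnasse:::rotation_about(rnasse:::vec_unit(rnorm(3)), runif(1, 0, pi))
    hp <- hairpin_cg(sample(3:12, 1), R = R, t = rnorm(3, sd = 10))
    ax <- hp$cg$coords$s0; tw <- hp$cg$twists$s0
    d <- rnasse:::vec_unit(ax["end", ] - ax["start", ])
    for (r in 1:2) {
      expect_equal(rnasse:::vec_norm(tw[r, ]), 1, tolerance = 1e-6)
      expect_lt(abs(sum(tw[r, ] * d)), 1e-6)
    }
  }
})

test_that("rigid motions carry coords and twists along exactly", {
  set.seed(23)
  f <- make_junction_fixture(120, 4)
  cg0 <- cg_from_atoms(f)
  R <- rnasse:::rotation_about(rnasse:::vec_unit(rnorm(3)), 0.9)
  t <- c(5, -11, 2)
  f2 <- f
  f2$atoms[, c("x", "y", "z")] <-
    rnasse:::transform_points(as.matrix(f$atoms[, c("x", "y", "z")]), R, t)
  cg1 <- cg_from_atoms(f2)
  for (el in names(cg0$coords)) {
    moved <- rnasse:::transform_points(cg0$coords[[el]], R, t)
    expect_equal(cg1$coords[[el]], moved, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  for (el in names(cg0$twists)) {
    expect_equal(cg1$twists[[el]], cg0$twists[[el]] %*% t(R),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("a 1-bp stem gets its base-plane normal as axis direction", {
  h <- make_ideal_helix(1, seq1 = "G", resno2 = 6L)
  fix <- list(atoms = rbind(
    h$atoms,
    rnasse:::loop_residues("A", 2:5,
                           matrix(c(6, 0, 4, 0, 6, 5, -6, 0, 4, 0, -6, 3),
                                  ncol = 3, byrow = TRUE))),
    dotbracket = "(....)")
  cg <- load_fixture(fix)
  d <- cg$coords$s0["end", ] - cg$coords$s0["start", ]
  # the fixture pair lies in the z = 0 plane, so the normal is +-z
  expect_lt(min(vec_angle(d, c(0, 0, 1)), vec_angle(d, c(0, 0, -1))), 1)
})

test_that("loop elements inherit their endpoints from the stem axes", {
  f <- make_junction_fixture(90, 5)
  cg <- load_fixture(f)
  bg <- cg$bg
  # hairpin: start equals the adjacent stem's loop-side axis end
  h0_stem <- intersect(bg$edges$h0, names(bg$stems))
  side <- get_sides(cg, h0_stem, "h0")
  expect_equal(cg$coords$h0["start", ],
               cg$coords[[h0_stem]][side[1], ], ignore_attr = TRUE)
  # m segment endpoints are the facing axis ends of its two stems
  m0 <- cg$coords$m0
  expect_equal(m0["start", ], cg$coords$s0[get_sides(cg, "s0", "m0")[1], ],
               ignore_attr = TRUE)
  expect_equal(m0["end", ], cg$coords$s1[get_sides(cg, "s1", "m0")[1], ],
               ignore_attr = TRUE)
})

test_that("interior-loop endpoints face both stems across the loop", {
  h1 <- make_ideal_helix(4, resno1 = 1:4, resno2 = 21:18)
  h2 <- make_ideal_helix(4, R = diag(3), t = c(2, 1, 15),
                         resno1 = 7:10, resno2 = 15:12)
  loop1 <- rnasse:::loop_residues("A", 5:6, rnasse:::arc_points(
    c(0, 0, 8.4), c(2, 1, 15), 2))
  loop2 <- rnasse:::loop_residues("A", 16:17, rnasse:::arc_points(
    c(2, 1, 23), c(0, 0, 10), 2))
  hp <- rnasse:::loop_residues("A", 11:11, matrix(c(2, 1, 30), 1))
  fix <- list(atoms = rbind(h1$atoms, loop1, h2$atoms, hp, loop2),
              dotbracket = "((((..((((.))))..))))")
  cg <- load_fixture(fix)
  expect_setequal(cg$bg$edges$i0, c("s0", "s1"))
  expect_equal(cg$coords$i0["start", ],
               cg$coords$s0[get_sides(cg, "s0", "i0")[1], ], ignore_attr = TRUE)
  expect_equal(cg$coords$i0["end", ],
               cg$coords$s1[get_sides(cg, "s1", "i0")[1], ], ignore_attr = TRUE)
})

test_that("get_sides follows connectivity and rejects non-neighbours", {
  f <- make_junction_fixture(120, 3)
  cg <- load_fixture(f)
  # s0 faces the junction with its inner (end) side
  expect_equal(get_sides(cg, "s0", "m0"), c(2L, 1L))
  # child stem s1 faces the junction with its outer (start) side
  expect_equal(get_sides(cg, "s1", "m0"), c(1L, 2L))
  # hairpin h0 sits at s1's inner side
  expect_equal(get_sides(cg, "s1", "h0"), c(2L, 1L))
  expect_error(get_sides(cg, "s2", "m0"), "not adjacent")
})

test_that("an f element attaches at its stem's 5'-terminal side", {
  h <- make_ideal_helix(4, resno1 = 3:6, resno2 = 16:13)
  lead <- rnasse:::loop_residues("A", 1:2,
    matrix(c(-8, 0, -4, -7, 2, -2), ncol = 3, byrow = TRUE))
  hp <- rnasse:::loop_residues("A", 7:12, rnasse:::arc_points(
    c(0, 0, 8.4), c(0, 0, 16), 6))
  fix <- list(atoms = rbind(lead, h$atoms, hp),
              dotbracket = "..((((......))))")
  cg <- load_fixture(fix)
  expect_equal(get_sides(cg, "s0", "f0"), c(1L, 2L))
  expect_equal(cg$coords$f0["start", ], cg$coords$s0["start", ],
               ignore_attr = TRUE)
})

test_that("the coarse-grain text format round-trips and validates", {
  f <- make_junction_fixture(140, 5)
  cg <- load_fixture(f)
  cg$interacting <- c("A:5", "A:6")
  path <- tempfile(fileext = ".cg")
  write_cg(cg, path, seq = strrep("N", cg$bg$n))
  cg2 <- read_cg(path)
  expect_equal(cg2$bg$elements, cg$bg$elements)
  expect_equal(cg2$ids, cg$ids)
  expect_equal(cg2$interacting, cg$interacting)
  for (el in names(cg$coords))
    expect_lt(max(abs(cg2$coords[[el]] - cg$coords[[el]])), 1e-5)
  for (el in names(cg$twists))
    expect_lt(max(abs(cg2$twists[[el]] - cg$twists[[el]])), 1e-5)
  # tampering with a twist breaks the unit-length invariant on read
  lines <- readLines(path)
  k <- grep("^twist s0", lines)[1]
  parts <- strsplit(lines[k], " ")[[1]]
  parts[3] <- "2.000000"
  lines[k] <- paste(parts, collapse = " ")
  writeLines(lines, path)
  expect_error(read_cg(path), "unit length|orthogonal")
  # 2D-only graphs serialize without coordinate lines
  cg2d <- load_rna({
    fdb <- tempfile(fileext = ".dotbracket")
    writeLines("(((...)))", fdb); fdb
  })[[1]]
  p2 <- tempfile(fileext = ".cg")
  write_cg(cg2d, p2)
  expect_false(any(grepl("^coord", readLines(p2))))
  cg3 <- read_cg(p2)
  expect_equal(cg3$bg$elements, cg2d$bg$elements)
  unlink(c(path, p2))
})
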