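test_that("stem vectors point away from the multiloop segment", {
  f <- make_junction_fixture(120, 3)
  cg <- load_fixture(f)
  # s0 faces m0 with its inner end at the origin; away = toward -z
  v0 <- stem_vector(cg, "s0", "m0")
  expect_lt(vec_angle(v0, c(0, 0, -1)), 1)
  expect_equal(rnasse:::vec_norm(v0), 9 * 2.81, tolerance = 0.1)
  # s1 faces m0 with its outer end: away = along its body
  v1 <- stem_vector(cg, "s1", "m0")
  expect_lt(vec_angle(v1, c(sin(120 * pi / 180), 0, -cos(120 * pi / 180))), 1)
  # the same stem seen from its segment on the other side flips sign
  v0b <- stem_vector(cg, "s0", "m2")
  expect_equal(v0, v0b)   # both m0 and m2 touch s0's inner side
  expect_error(stem_vector(cg, "s2", "m0"), "not adjacent")
})

test_that("inter-stem angles follow the closed form", {
  expect_equal(inter_stem_angle(c(0, 0, 1), c(0, 0, -1)), 180)
  expect_equal(inter_stem_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  th <- 40 * pi / 180
  expect_equal(inter_stem_angle(c(1, 0, 0), c(-cos(th), sin(th), 0)), 140)
  expect_error(inter_stem_angle(c(0, 0, 0), c(1, 0, 0)), "zero")
})

test_that("ray offsets handle collinear, parallel and skew cases exactly", {
  rd <- rnasse:::ray_distance
  # anti-aligned rays on one line, pointing toward each other: distance 0
  expect_equal(rd(c(0, 0, 0), c(1, 0, 0), c(5, 0, 0), c(-1, 0, 0)), 0)
  # co-directed parallel rays anchored 5 apart
  expect_equal(rd(c(0, 0, 0), c(1, 0, 0), c(0, 5, 0), c(1, 0, 0)), 5)
  # diverging collinear rays: distance between the anchors
  expect_equal(rd(c(0, 0, 0), c(-1, 0, 0), c(3, 0, 0), c(1, 0, 0)), 3)
  # skew rays where the ray constraint matters
  expect_equal(rd(c(0, 0, 0), c(1, 0, 0), c(0, 3, 4), c(0, 0, -1)), 3)
})

test_that("ray offset equals a dense grid minimization on random rays", {
  set.seed(29)
  for (rep in 1:25) {
    c1 <- rnorm(3, sd = 5); c2 <- rnorm(3, sd = 5)
    v1 <- rnasse:::vec_unit(rnorm(3)); v2 <- rnasse:::vec_unit(rnorm(3))
    lam <- seq(0, 60, length.out = 1200)
    p1 <- outer(lam, v1) + rep(c1, each = length(lam))
    best <- Inf
    for (l2 in seq(0, 60, length.out = 300)) {
      q <- c2 + l2 * v2
      d2 <- sqrt(rowSums(sweep(p1, 2, q)^2))
      best <- min(best, min(d2))
    }
    got <- rnasse:::ray_distance(c1, v1, c2, v2)
    # the closed form can only improve on the discretized minimum, and
    # never by more than the grid spacing allows
    expect_lte(got, best + 1e-9)
    expect_lt(best - got, 0.2)
  }
})

test_that("angle and offset are symmetric under stem exchange", {
  set.seed(37)
  for (th in c(45, 110, 160)) {
    f <- make_junction_fixture(th, runif(1, 0, 8))
    cg <- load_fixture(f)
    a12 <- inter_stem_angle(stem_vector(cg, "s0", "m0"),
                            stem_vector(cg, "s1", "m0"))
    a21 <- inter_stem_angle(stem_vector(cg, "s1", "m0"),
                            stem_vector(cg, "s0", "m0"))
    expect_equal(a12, a21)
    expect_equal(inter_stem_offset(cg, "s0", "s1", "m0"),
                 inter_stem_offset(cg, "s1", "s0", "m0"))
  }
})

test_that("the stacking predicate matches its definition, incl. bulges", {
  f <- make_junction_fixture(170, 2)
  cg <- load_fixture(f)
  p1 <- f$stack_residues$s0          # s0's m0-side (inner) pair
  p2 <- f$stack_residues$s1          # s1's m0-side (outer) pair
  # direct stack between the closing pairs
  expect_true(helices_are_stacking(cg, "s0", "s1", "m0",
                                   stacks = list(c(p1[1], p2[1]))))
  # stack through an intermediate loop nucleotide, not backbone-connected
  expect_true(helices_are_stacking(cg, "s0", "s1", "m0",
                                   stacks = list(c(p1[2], "A:11", p2[1]))))
  # stacks that touch only one of the two pairs do not count
  expect_false(helices_are_stacking(cg, "s0", "s1", "m0",
                                    stacks = list(c(p1[1], "A:11"),
                                                  c("A:12", p2[2]))))
  # missing annotation is an error, not FALSE
  expect_error(helices_are_stacking(cg, "s0", "s1", "m0"), "annotation")
})

test_that("stacking equals a brute-force scan over all configurations", {
  f <- make_junction_fixture(150, 1)
  cg <- load_fixture(f)
  p1 <- f$stack_residues$s0
  p2 <- f$stack_residues$s1
  others <- residue_id("A", 11:13)
  pool <- c(p1, p2, others)
  set.seed(41)
  for (rep in 1:60) {
    stacks <- replicate(sample(1:3, 1),
                        sample(pool, sample(2:4, 1)), simplify = FALSE)
    got <- helices_are_stacking(cg, "s0", "s1", "m0", stacks = stacks)
    want <- FALSE
    for (st in stacks) for (a in p1) for (b in p2)
      if (a %in% st && b %in% st) want <- TRUE
    expect_equal(got, want)
  }
})

test_that("describe_junctions reports every segment deterministically", {
  f <- make_junction_fixture(143, 5)
  ann <- list(c(f$stack_residues$s0[1], f$stack_residues$s1[1]))
  cg <- load_fixture(f)
  dj <- describe_junctions(cg, stacks = ann)
  expect_equal(nrow(dj), 3)            # 3-way junction: three m segments
  expect_equal(dj$ml, c("m0", "m1", "m2"))
  r <- dj[dj$ml == "m0", ]
  expect_equal(r$angle_deg, 143, tolerance = 0.01)
  expect_equal(r$offset_ang, 5, tolerance = 0.01)
  expect_true(r$stacking_dssr)
  expect_false(any(dj$stacking_dssr[dj$ml != "m0"]))
  # separation vector is recorded start-to-start
  expect_equal(c(r$sep_x, r$sep_y, r$sep_z), c(0, 5, 0), tolerance = 0.01)
  # structures without junctions give an empty table
  hp <- hairpin_cg(6)
  expect_equal(nrow(describe_junctions(hp$cg)), 0)
})

test_that("zero-length segments still get an angle and offset", {
  bg3 <- "((((...))((...))))"
  # place two helices sharing the junction directly (empty m between them)
  h1 <- make_ideal_helix(2, resno1 = 1:2, resno2 = 18:17)
  h2 <- make_ideal_helix(2, R = rnasse:::rotation_between(c(0, 0, 1), c(1, 0, 0)),
                         t = c(2, 0, 6), resno1 = 3:4, resno2 = 9:8)
  h3 <- make_ideal_helix(2, R = rnasse:::rotation_between(c(0, 0, 1), c(-1, 0, 0)),
                         t = c(-2, 0, 6), resno1 = 10:11, resno2 = 16:15)
  lp1 <- rnasse:::loop_residues("A", 5:7, rnasse:::arc_points(c(8, 0, 6), c(12, 3, 6), 3))
  lp2 <- rnasse:::loop_residues("A", 12:14, rnasse:::arc_points(c(-8, 0, 6), c(-10, 3, 6), 3))
  fix <- list(atoms = rbind(h1$atoms, h2$atoms, lp1, h3$atoms, lp2),
              dotbracket = bg3)
  cg <- load_fixture(fix)
  dj <- describe_junctions(cg)
  expect_equal(nrow(dj), 3)
  m_empty <- dj[lengths(cg$bg$elements[dj$ml]) == 0, ]
  expect_true(nrow(m_empty) >= 1)
  expect_false(any(is.na(m_empty$angle_deg)))
  expect_false(any(is.na(m_empty$offset_ang)))
})
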