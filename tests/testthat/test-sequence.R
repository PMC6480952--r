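test_that("residue ids parse, format and order correctly", {
  expect_equal(residue_id("A", 14), "A:14")
  expect_equal(residue_id("A", 14, "B"), "A:14B")
  p <- parse_residue_id(c("A:-2", "B:100C"))
  expect_equal(p$number, c(-2L, 100L))
  expect_equal(p$icode, c("", "C"))
  expect_error(parse_residue_id("nonsense"), "malformed")
  # blank insertion code sorts before letters; numbers numerically
  ids <- c("A:14B", "A:14", "A:2", "A:-1", "B:1", "A:14A")
  expect_equal(ids[order_residue_ids(ids)],
               c("A:-1", "A:2", "A:14", "A:14A", "A:14B", "B:1"))
})

test_that("integer and reference indexing resolve to the same records", {
  s <- rna_sequence(c("G", "A", "C"), ids = residue_id("A", 13:15))
  r2 <- resolve_index(s, 2)
  expect_equal(r2$code, "A")
  expect_equal(r2$id, "A:14")
  r3 <- resolve_index(s, "A:15")
  expect_equal(r3$code, "C")
  expect_equal(r3$position, 3L)
  # negative reference numbering upstream of the functional RNA
  neg <- rna_sequence(c("G", "A", "C"),
                      ids = c(residue_id("A", -2), residue_id("A", -1),
                              residue_id("A", 1)))
  expect_equal(resolve_index(neg, 1)$id, "A:-2")
  # errors: 0-based access, out of range, unknown id
  expect_error(resolve_index(s, 0), "out of range")
  expect_error(resolve_index(s, 4), "out of range")
  expect_error(resolve_index(s, -1), "out of range")
  expect_error(resolve_index(s, "A:99"), "unknown residue id")
})

test_that("integer/reference round trip holds for every present residue", {
  set.seed(3)
  codes <- sample(c("A", "C", "G", "U"), 20, replace = TRUE)
  present <- runif(20) > 0.25
  ids <- residue_id("B", seq(5, by = 2, length.out = 20))
  s <- rna_sequence(codes, ids = ids, present = present)
  pres_ids <- ids[present]
  for (i in seq_along(pres_ids)) {
    expect_identical(resolve_index(s, i), resolve_index(s, pres_ids[i]))
  }
})

test_that("modified residues normalize to their parent with annotation", {
  expect_equal(normalize_residue("G"), list(code = "G", mod = NA_character_))
  expect_equal(normalize_residue("5MC"), list(code = "C", mod = "5MC"))
  expect_equal(normalize_residue("1MA"), list(code = "A", mod = "1MA"))
  expect_equal(normalize_residue("PSU")$code, "U")
  expect_error(normalize_residue("XXX"), "XXX")
  expect_warning(r <- normalize_residue("XXX", permissive = TRUE), "XXX")
  expect_equal(r$code, "N")
  # idempotent on the one-letter output
  for (code in c("5MC", "7MG", "PSU", "1MA")) {
    once <- normalize_residue(code)$code
    expect_equal(normalize_residue(once)$code, once)
  }
  # bundled table maps only onto standard letters
  expect_true(all(modification_table() %in% c("A", "C", "G", "U")))
})

test_that("missing-residue view contains the present-only view", {
  s0 <- rna_sequence(c("G", "A", "C", "U"))
  expect_equal(missing_residue_view(s0), "GACU")
  s1 <- rna_sequence(c("G", "A", "C", "U"),
                     present = c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(missing_residue_view(s1), "GACU")
  expect_equal(seq_string(s1), "GCU")
  expect_equal(missing_residue_view(rna_sequence(character())), "")
  # subsequence property on random sequences
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    s <- rna_sequence(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                      present = runif(n) > 0.3)
    full <- strsplit(missing_residue_view(s), "")[[1]]
    pres <- strsplit(seq_string(s), "")[[1]]
    # greedy subsequence check
    k <- 1
    for (ch in full) if (k <= length(pres) && ch == pres[k]) k <- k + 1
    expect_gt(k, length(pres))
  }
})
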