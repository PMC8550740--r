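test_that("p-distance uses pairwise deletion", {
  expect_equal(p_distance("ACGT", "ACGT"), list(p = 0, n_sites_used = 4L))
  expect_equal(p_distance("AAAA", "AAAT")$p, 0.25)
  # ambiguity site excluded from the pair only
  r <- p_distance("AANA", "AATA")
  expect_equal(r$p, 0)
  expect_equal(r$n_sites_used, 3L)
  # gaps excluded likewise
  expect_equal(p_distance("AC-T", "ACGT")$n_sites_used, 3L)
  expect_error(p_distance("NNN", "AAA"), "no usable sites")
  expect_error(p_distance("ACG", "ACGT"), "equal length")
})

test_that("percent identity is 100 * (1 - p)", {
  expect_equal(percent_identity("ACGT", "ACGT"), 100)
  # 45 mismatches over 1000 sites: p = 0.045 -> 95.5%
  a <- paste(rep("A", 1000), collapse = "")
  b <- paste(c(rep("C", 45), rep("A", 955)), collapse = "")
  expect_equal(percent_identity(a, b), 95.5)
  # two simulated species at 8% target divergence
  sim <- simulate_panel(2, inter_divergence = 0.08, seed = 9)
  pid <- percent_identity(sim$refs$nt[1], sim$refs$nt[2])
  expect_true(abs(pid - 92) <= 1)
})

test_that("Tajima-Nei reduces to Jukes-Cantor on uniform-composition pairs", {
  for (p in seq(0.05, 0.50, by = 0.05)) {
    pr <- uniform_pair(p)
    d <- tajima_nei(pr$a, pr$b)$d
    jc <- -0.75 * log(1 - 4 * p / 3)
    expect_lt(abs(d - jc), 1e-12)
  }
})

test_that("Tajima-Nei matches an independent formula evaluation", {
  # fixed 651-nt pair with 30 scripted substitutions
  orf <- seed_orf()
  set.seed(77)
  pos <- sample(651, 30)
  chars <- strsplit(orf, "")[[1]]
  other <- chars
  for (i in pos) other[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[
    sample.int(3, 1)]
  b <- paste(other, collapse = "")
  tn <- tajima_nei(orf, b)
  expect_lt(abs(tn$d - tn_oracle(orf, b)), 1e-12)
  expect_equal(tn$p, 30 / 651)
  expect_equal(sum(tn$q), 1)
  expect_equal(sum(tn$x), tn$p)
})

test_that("Tajima-Nei obeys its structural invariants", {
  expect_equal(tajima_nei("ACGTACGT", "ACGTACGT")$d, 0)
  set.seed(41)
  for (rep in 1:10) {
    a <- random_nt(300)
    nmut <- sample(5:60, 1)
    chars <- strsplit(a, "")[[1]]
    idx <- sample(300, nmut)
    for (i in idx) chars[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[
      sample.int(3, 1)]
    b <- paste(chars, collapse = "")
    d_ab <- tajima_nei(a, b)
    d_ba <- tajima_nei(b, a)
    expect_equal(d_ab$d, d_ba$d)                   # symmetry
    expect_gte(d_ab$d, p_distance(a, b)$p)         # correction inflates
    expect_gt(d_ab$h, 0)
  }
  # monotonicity of p: one extra mismatched site never decreases p
  a <- paste(rep("ACGT", 25), collapse = "")
  b1 <- mutate_at(a, 1, "T")
  b2 <- mutate_at(b1, 5, "T")
  expect_gt(p_distance(a, b2)$p, p_distance(a, b1)$p)
  # saturation is an explicit error, not a clamped value
  sat_a <- paste(rep("A", 100), collapse = "")
  sat_b <- paste(rep("C", 100), collapse = "")
  expect_error(tajima_nei(sat_a, sat_b), "saturation")
})

test_that("distance matrices are symmetric and agree with pairwise calls", {
  s3 <- stats::setNames(rep("ACGTACGTAC", 3), c("x", "y", "z"))
  dm <- distance_matrix(s3, "percent_identity")
  expect_true(all(dm$values == 100))

  sim <- simulate_panel(6, seed = 13)
  seqs <- stats::setNames(sim$refs$nt, sim$refs$id)
  for (metric in c("p_distance", "tajima_nei")) {
    dm <- distance_matrix(seqs, metric)
    expect_equal(dm$values, t(dm$values))
    expect_true(all(diag(dm$values) == 0))
    fn <- if (metric == "p_distance") function(a, b) p_distance(a, b)$p else
      function(a, b) tajima_nei(a, b)$d
    for (i in 1:5) for (j in (i + 1):6) {
      expect_equal(dm$values[i, j], fn(seqs[[i]], seqs[[j]]))
    }
  }
  two <- distance_matrix(seqs[1:2], "p_distance")
  expect_equal(two$values[1, 2], p_distance(seqs[[1]], seqs[[2]])$p)
  expect_error(distance_matrix(seqs[1], "p_distance"), "at least 2")
})
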