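test_that("the shipped Uganda survey matrix has the published marginals", {
  m <- uganda_counts()
  expect_equal(sum(m), 870L)
  expect_equal(unname(colSums(m)[c("SSA1-SG1", "MED-ASL", "B. Uganda1")]),
               c(137L, 265L, 105L))
  cassava <- m["Manihot esculenta", ]
  expect_equal(sum(cassava), 98L)
  expect_setequal(names(cassava)[cassava > 0],
                  c("SSA1-SG1", "SSA1-SG2", "SSA2"))
  hlgg <- uganda_hlgg()
  expect_setequal(colnames(m), names(hlgg))
  expect_equal(sum(colSums(m)[names(hlgg)[hlgg == "SSA"]]), 344L)
  expect_equal(sum(colSums(m)[names(hlgg)[hlgg == "AMEA"]]), 401L)
})

test_that("count matrices tally assignments with explicit zero rows", {
  f <- write_toy_survey(c(
    survey_header,
    "S1\tManihot esculenta\tCassava\tEuphorbiaceae\tcentral\t1\t1\tw1,w2,w3",
    "S2\tOkra\tOkra\tMalvaceae\teastern\t1\t1\tw4,w5,w6",
    "S3\tBareHost\tBare\tUnknown\twest\t1\t1\tw7,w8,w9"
  ))
  rec <- read_survey_records(f)
  asn <- data.frame(
    seq_id = paste0("w", 1:6),
    call = c("SSA1", "SSA1", "SSA2", "MED-ASL", "MED-ASL", "MED-ASL"),
    subgroup = c("SG1", "SG2", NA, NA, NA, NA)
  )
  m <- build_count_matrix(rec, asn)
  expect_equal(sum(m), 6L)
  expect_equal(m["Manihot esculenta", "SSA1-SG1"], 1L)
  expect_equal(m["Manihot esculenta", "SSA1-SG2"], 1L)
  expect_equal(m["Okra", "MED-ASL"], 3L)
  expect_true(all(m["BareHost", ] == 0L))       # absent host is explicit zeros

  plain <- build_count_matrix(rec, asn, split_subgroups = FALSE)
  expect_equal(plain["Manihot esculenta", "SSA1"], 2L)

  orphan <- rbind(asn, data.frame(seq_id = "ghost", call = "SSA1",
                                  subgroup = NA))
  expect_error(build_count_matrix(rec, orphan), "ghost")

  empty <- build_count_matrix(rec, asn[0, ])
  expect_true(all(empty == 0L))
  expect_equal(nrow(empty), 3L)
})

test_that("composition percentages sum to 100 exactly", {
  m <- uganda_counts()
  comp <- composition_percentages(m)
  expect_equal(sum(comp), 100)
  expect_equal(round(comp[["MED-ASL"]], 1), 30.5)
  one <- matrix(5L, 1, 1, dimnames = list("h", "sp"))
  expect_equal(unname(composition_percentages(one)), 100)
  zero <- matrix(0L, 2, 2)
  expect_error(composition_percentages(zero), "empty")
})

test_that("minimum-support filtering keeps only cells >= min_n", {
  m <- matrix(c(5L, 2L, 0L, 0L, 3L, 1L), 3, 2,
              dimnames = list(c("h1", "h2", "h3"), c("a", "b")))
  out <- min_support_table(m)
  expect_true(all(out[out > 0] >= 3))
  expect_false("h3" %in% rownames(out))        # only a 1-count, dropped
  expect_equal(out["h2", "b"], 3L)
  expect_equal(out["h2", "a"], 0L)             # the 2-count cell is zeroed
  # min_n = 1 keeps every non-zero cell
  expect_equal(min_support_table(m, 1L), m)
  expect_equal(sum(min_support_table(uganda_counts()) >= 3),
               sum(uganda_counts() >= 3))
})

test_that("mixed-sample fraction counts multi-species samples once", {
  f <- write_toy_survey(c(
    survey_header,
    "S1\tA\tA\tF\tc\t1\t1\tw1,w2,w3",
    "S2\tB\tB\tF\tc\t1\t1\tw4,w5,w6"
  ))
  rec <- read_survey_records(f)
  mono <- data.frame(seq_id = paste0("w", 1:6),
                     call = rep(c("SSA1", "SSA2"), each = 3))
  expect_equal(mixed_sample_fraction(rec, mono)$fraction, 0)

  # one sample with three distinct calls still counts once
  tri <- data.frame(seq_id = paste0("w", 1:6),
                    call = c("SSA1", "MED-ASL", "B. Uganda5",
                             "SSA2", "SSA2", "SSA2"))
  mix <- mixed_sample_fraction(rec, tri)
  expect_equal(mix$n_mixed, 1L)
  expect_equal(mix$fraction, 0.5)

  lone <- data.frame(seq_id = "w1", call = "SSA1")
  expect_error(mixed_sample_fraction(rec, lone), "no samples")
})

test_that("hierarchical clustering merges identical profiles first", {
  m <- matrix(c(10, 10, 0,
                10, 10, 0,
                0, 0, 20), 3, 3, byrow = TRUE,
              dimnames = list(c("h1", "h2", "h3"), c("a", "b", "c")))
  hc <- hierarchical_cluster(m, "hosts")
  expect_equal(hc$height[1], 0)                 # identical profiles at height 0
  # hand-computed 3x3 Euclidean oracle: outlier joins last
  d12 <- 0
  d13 <- sqrt(10^2 + 10^2 + 20^2)
  expect_equal(hc$height[2], d13)               # average linkage of equal dists
  last <- hc$merge[2, ]
  expect_true(any(last == -3) || any(last == 2))

  cm <- rbind(m, h4 = c(5, 5, 5))               # constant profile
  expect_error(hierarchical_cluster(cm, "hosts", metric = "correlation"),
               "h4")
  expect_error(hierarchical_cluster(m[1, , drop = FALSE], "hosts"),
               "at least 2")
})

test_that("newick export preserves leaves and merge heights", {
  m <- simulate_block_matrix(2, 3, 3, seed = 31)
  hc <- hierarchical_cluster(m, "hosts")
  f <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc, f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, rownames(m))
  # ape halves merge heights to place nodes midway on an ultrametric tree
  expect_equal(max(ape::node.depth.edgelength(tr)), max(hc$height) / 2,
               tolerance = 1e-6)
})
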