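test_that("the 4% dichotomy is exact, including the boundary", {
  panel <- toy_panel()
  ref1 <- panel$window_nt[[1]]

  a0 <- assign_species(stats::setNames(ref1, "q0"), panel)
  expect_equal(a0$call, panel$entries$species[1])
  expect_equal(a0$min_divergence, 0)

  # 2% from one reference, ~8% from the others: the close species wins
  chars <- strsplit(ref1, "")[[1]]
  set.seed(6)
  idx <- sample(651, 13)  # 13/651 = 2.0%
  for (i in idx) chars[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[1]
  a2 <- assign_species(stats::setNames(paste(chars, collapse = ""), "q2"), panel)
  expect_equal(a2$call, panel$entries$species[1])

  # boundary: 26 mismatches (p = 0.0399) is known, 27 (p = 0.0415) is novel
  mk <- function(nmut) {
    ch <- strsplit(ref1, "")[[1]]
    for (i in seq_len(nmut)) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    paste(ch, collapse = "")
  }
  near <- assign_species(stats::setNames(mk(26), "near"), panel)
  over <- assign_species(stats::setNames(mk(27), "over"), panel)
  expect_false(near$call == "novel")
  expect_lt(near$min_divergence, 0.04)
  expect_equal(over$call, "novel")
  expect_gte(over$min_divergence, 0.04)
})

test_that("novel sequences group by single linkage with canonical names", {
  sim <- simulate_panel(6, seed = 14)          # species SSA1..SSA6
  panel <- build_panel(sim$refs[1:3, ])        # SSA4..SSA6 become novel
  novel <- stats::setNames(sim$refs$nt[4:6], c("nv_c", "nv_a", "nv_b"))

  grp <- cluster_novel(novel, panel)
  expect_equal(length(unique(grp$group)), 3L)  # mutually ~8% divergent
  # numbering continues after the panel species, ordered by smallest id
  expect_equal(grp$group[grp$seq_id == "nv_a"], "SSA4")
  expect_equal(grp$group[grp$seq_id == "nv_b"], "SSA5")
  expect_equal(grp$group[grp$seq_id == "nv_c"], "SSA6")

  # two near-identical novels form one group of two
  q <- simulate_queries(sim, 2, 0.01, seed = 15, species = "SSA5")
  grp2 <- cluster_novel(q$seqs, panel)
  expect_equal(length(unique(grp2$group)), 1L)

  # a novel nearest to a non-tabaci (Uganda clade) reference gets that prefix
  sim_u <- simulate_panel(3, seed = 16, hlgg = c("SSA", "SSA", "Uganda"),
                          species_names = c("SSA1", "SSA2", "B. Uganda1"))
  panel_u <- build_panel(sim_u$refs)
  ch <- strsplit(sim_u$refs$nt[3], "")[[1]]  # drift 5% off B. Uganda1
  set.seed(99)
  for (i in sample(setdiff(1:651, sim_u$used_positions), 33)) {
    ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  }
  nu <- stats::setNames(paste(ch, collapse = ""), "nu_1")
  grp3 <- cluster_novel(nu, panel_u)
  expect_equal(grp3$group, "B. Uganda2")
})

test_that("subgroup calls pick the nearest subgroup reference", {
  sim <- simulate_panel(3, seed = 17)
  sgs <- simulate_queries(sim, 1, 0.012, seed = 18, species = "SSA1")
  sg_refs <- stats::setNames(c(sim$refs$nt[1], sgs$seqs[[1]]), c("SG1", "SG2"))

  hit <- assign_subgroup(sgs$seqs[[1]], sg_refs)
  expect_equal(hit$subgroup, "SG2")
  expect_gt(hit$margin, 0)

  # exact equidistance: lexicographic tie-break, flagged
  tie <- assign_subgroup(sim$refs$nt[1],
                         stats::setNames(rep(sgs$seqs[[1]], 2), c("SG2", "SG1")))
  expect_equal(tie$subgroup, "SG1")
  expect_true(tie$tie)

  expect_true(is.na(assign_subgroup(sim$refs$nt[1], NULL)$subgroup))
})

test_that("batch assignment recovers planted species exactly", {
  sim <- simulate_panel(6, seed = 19)
  panel <- build_panel(sim$refs)
  q <- simulate_queries(sim, 10, 0.01, seed = 20)
  aset <- assign_all(q$seqs, panel)

  truth <- q$truth$species[match(aset$assignments$seq_id, q$truth$seq_id)]
  expect_equal(aset$assignments$call, truth)     # 100% recovery
  expect_equal(sum(aset$tally), length(q$seqs))
  # dichotomy invariant: known call iff divergence strictly below threshold
  expect_equal(!aset$assignments$novel,
               aset$assignments$min_divergence < 0.04)

  # permutation stability: shuffling input changes no call
  set.seed(8)
  shuf <- sample(names(q$seqs))
  aset2 <- assign_all(q$seqs[shuf], panel)
  m <- match(aset$assignments$seq_id, aset2$assignments$seq_id)
  expect_equal(aset$assignments$call, aset2$assignments$call[m])

  # a single planted novel shows up as one novel group of one
  sim9 <- simulate_panel(7, seed = 19)
  novel_seq <- stats::setNames(sim9$refs$nt[7], "lone_novel")
  aset3 <- assign_all(c(q$seqs, novel_seq), panel)
  novels <- aset3$assignments[aset3$assignments$novel, ]
  expect_equal(nrow(novels), 1L)
  expect_equal(novels$seq_id, "lone_novel")

  # empty input gives an empty tally
  empty <- assign_all(stats::setNames(character(0), character(0)), panel)
  expect_equal(nrow(empty$assignments), 0L)
})
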