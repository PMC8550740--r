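test_that("conserved mask reflects column invariance across the panel", {
  orf <- seed_orf()
  # identical references: every amino-acid column invariant
  refs <- data.frame(id = c("r1", "r2", "r3"), species = c("a", "b", "c"),
                     nt = orf)
  p <- build_panel(refs)
  expect_true(all(p$conserved_mask))
  expect_equal(length(p$conserved_mask), 217L)

  # one non-synonymous difference: mask false exactly there
  # codon 100 (0-based): change its first base to force an aa change
  pos <- 100 * 3 + 1
  alt <- mutate_at(orf, pos, setdiff(c("A", "C", "G", "T"),
                                     substr(orf, pos, pos))[1])
  expect_false(translate_nt(alt)$peptide == translate_nt(orf)$peptide)
  p2 <- build_panel(data.frame(id = c("r1", "r2"), species = c("a", "b"),
                               nt = c(orf, alt)))
  expect_false(p2$conserved_mask[101])
  expect_true(all(p2$conserved_mask[-101]))
})

test_that("mask fraction on simulated references matches a direct column scan", {
  sim <- simulate_panel(5, inter_divergence = 0.10, seed = 5)
  p <- build_panel(sim$refs)
  # brute-force oracle: compare peptide columns directly
  peps <- vapply(sim$refs$nt, function(x) translate_nt(x)$peptide, character(1))
  mat <- do.call(rbind, strsplit(peps, ""))
  oracle <- apply(mat, 2, function(col) length(unique(col)) == 1L)
  expect_equal(unname(p$conserved_mask), unname(oracle))
})

test_that("panel building enforces its preconditions", {
  orf <- seed_orf()
  expect_error(build_panel(data.frame(id = "r1", species = "a", nt = orf)),
               "at least 2")
  expect_error(build_panel(data.frame(id = c("r1", "r2"), species = c("a", ""),
                                      nt = orf)), "non-empty")
})

test_that("align_query maps the window and detects gaps", {
  panel <- toy_panel()
  ref1 <- panel$entries$nt[1]

  ident <- align_query(stats::setNames(ref1, "q"), panel)
  expect_equal(ident$ref_id, panel$entries$id[1])
  expect_equal(ident$identity, 1)
  expect_length(ident$query_gaps, 0L)
  expect_true(ident$spans_window)

  # one internal base deleted: exactly one 1-column gap in the query row
  del <- paste0(substr(ref1, 1, 299), substr(ref1, 301, 651))
  dal <- align_query(stats::setNames(del, "q"), panel)
  expect_length(dal$query_gaps, 1L)
  expect_length(dal$ref_gaps, 0L)
})

test_that("flanked amplicons map the window to the interior", {
  panel <- toy_panel()
  ref1 <- panel$entries$nt[1]
  set.seed(3)
  flanked <- paste0(random_nt(20), ref1, random_nt(20))
  al <- align_query(stats::setNames(flanked, "q"), panel)
  expect_true(al$spans_window)
  expect_length(al$query_gaps, 0L)
  expect_length(al$ref_gaps, 0L)
  expect_equal(al$identity, 1)
  expect_equal(al$query_start, 21L)   # window sits 20 nt into the amplicon

  # independent DP oracle agrees with the aligner's score on a small pair
  a <- "ACGTACGTAAGGTT"; b <- "ACGTCGTAAGGTTT"
  expect_equal(whiteflyCOI:::.nw_align(a, b)$score, nw_score(a, b))
})

test_that("indel screening is window-scoped", {
  panel <- toy_panel()
  ref1 <- panel$entries$nt[1]
  clean <- align_query(stats::setNames(ref1, "q"), panel)
  expect_equal(screen_indels(clean)$status, "pass")

  del <- paste0(substr(ref1, 1, 299), substr(ref1, 301, 651))
  damaged <- align_query(stats::setNames(del, "q"), panel)
  ind <- screen_indels(damaged)
  expect_equal(ind$status, "fail_indel")
  expect_length(ind$gap_positions, 1L)

  # flanking-region gaps (outside the window) do not fail the sequence
  set.seed(4)
  flanked <- paste0(random_nt(25), ref1)
  fal <- align_query(stats::setNames(flanked, "q"), panel)
  expect_equal(screen_indels(fal)$status, "pass")
})

test_that("trimming returns exactly the 651-nt barcode in frame 0", {
  panel <- toy_panel()
  ref1 <- panel$entries$nt[1]
  set.seed(5)
  # 864-nt amplicon spanning the window, as the PCR product would
  amplicon <- paste0(random_nt(100), ref1, random_nt(113))
  expect_equal(nchar(amplicon), 864L)
  al <- align_query(stats::setNames(amplicon, "q"), panel)
  tr <- trim_to_barcode(al)
  expect_equal(nchar(tr$nt), 651L)
  expect_equal(tr$nt, ref1)
  expect_equal(tr$frame, 0L)

  # window truncated at the end: not spanning
  short <- substr(ref1, 1, 641)
  sal <- align_query(stats::setNames(short, "q"), panel)
  expect_false(sal$spans_window)
  expect_error(trim_to_barcode(sal), "span")
})

test_that("peptide screen catches stops and conserved-site violations", {
  panel <- toy_panel()
  ref1 <- panel$entries$nt[1]
  expect_equal(screen_peptide(ref1, panel)$status, "pass")

  # plant TAA at codon 50 (0-based)
  stopped <- mutate_at(ref1, 50 * 3 + 1:3, c("T", "A", "A"))
  sp <- screen_peptide(stopped, panel)
  expect_equal(sp$status, "fail_premature_stop")
  expect_true(50L %in% sp$diagnostics$position)

  # non-stop, non-synonymous substitution at a conserved column
  cons <- which(panel$conserved_mask)
  target <- NULL
  for (codon_i in cons - 1L) {
    for (base in c("A", "C", "G", "T")) {
      cand <- mutate_at(ref1, codon_i * 3 + 1, base)
      tr <- translate_nt(cand)
      aa <- substr(tr$peptide, codon_i + 1, codon_i + 1)
      if (length(tr$stops) == 0 && aa != panel$consensus_aa[codon_i + 1]) {
        target <- list(nt = cand, codon = codon_i); break
      }
    }
    if (!is.null(target)) break
  }
  cv <- screen_peptide(target$nt, panel)
  expect_equal(cv$status, "fail_conserved_violation")
  expect_true(target$codon %in% cv$diagnostics$position)
})

test_that("qc_pipeline is complete, sound and deterministic", {
  sim <- toy_sim()
  panel <- build_panel(sim$refs)
  q <- simulate_queries(sim, 4, 0.01, seed = 21)
  nm <- simulate_numts(sim, 4, indel_p = 1, stop_p = 0, seed = 22)
  batch <- c(q$seqs, nm$seqs)

  rep1 <- qc_pipeline(batch, panel)
  expect_equal(sum(rep1$summary), length(batch))          # completeness
  expect_equal(unname(rep1$summary["pass"]), 12L)
  expect_equal(unname(rep1$summary["fail_indel"]), 4L)

  # unmutated panel members always pass against their own panel
  own <- qc_pipeline(stats::setNames(sim$refs$nt, sim$refs$id), panel)
  expect_equal(unname(own$summary["pass"]), nrow(sim$refs))

  # determinism: no randomness anywhere in QC
  rep2 <- qc_pipeline(batch, panel)
  expect_identical(rep1, rep2)

  # empty input, empty report
  empty <- qc_pipeline(stats::setNames(character(0), character(0)), panel)
  expect_equal(nrow(empty$results), 0L)
  expect_equal(sum(empty$summary), 0L)

  # all-NUMT batch: zero passes, batch never aborts
  all_bad <- qc_pipeline(simulate_numts(sim, 6, 0.5, 0.5, seed = 23)$seqs, panel)
  expect_equal(unname(all_bad$summary["pass"]), 0L)
  expect_equal(sum(all_bad$summary), 6L)
})

test_that("qc reports serialise to JSON and passing FASTA content survives", {
  sim <- toy_sim()
  panel <- build_panel(sim$refs)
  q <- simulate_queries(sim, 2, 0.01, seed = 31)
  rep <- qc_pipeline(q$seqs, panel)
  jf <- tempfile(fileext = ".json"); sf <- tempfile(fileext = ".tsv")
  write_qc_report(rep, jf, sf)
  parsed <- jsonlite::read_json(jf)
  expect_length(parsed, nrow(rep$results))
  expect_equal(sort(names(qc_passing(rep))), sort(names(q$seqs)))
})
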