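test_that("zero target fraction yields no targets and n=0 with targets errors", {
  sim <- simulate_fractionation(small_config(target_fraction = 0),
                                sequences = FALSE)
  expect_false(any(sim$annotation$is_target))
  expect_error(simulate_fractionation(sim_config(n_transcripts = 0,
                                                 target_fraction = 0.1)),
               "n_transcripts")
})

test_that("identical seed reproduces the experiment exactly", {
  a <- simulate_fractionation(small_config(planted_motif = "GTGT"))
  b <- simulate_fractionation(small_config(planted_motif = "GTGT"))
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$utr3, b$utr3)
})

test_that("transcript records satisfy their invariants", {
  sim <- simulate_fractionation(small_config(planted_motif = "GTGTGTGTGT"))
  ann <- sim$annotation
  tx <- !ann$is_spikein
  expect_true(all(ann$utr3_length[tx] > 0))
  expect_true(all(ann$utr3_length[tx] < ann$mrna_length[tx]))
  expect_identical(unname(nchar(sim$utr3)), ann$utr3_length[tx])
  expect_false(any(ann$is_target & ann$is_spikein))
  # planted motif present in every target UTR, absent-by-chance tolerated in bg
  targets <- ann$transcript_id[ann$is_target]
  expect_true(all(grepl("GTGTGTGTGT", sim$utr3[targets], fixed = TRUE)))
})

test_that("expected molecule allocation conserves abundance", {
  sim <- simulate_fractionation(small_config(), sequences = FALSE)
  tr <- sim$truth
  expect_equal(sum(tr$p_base), 1, tolerance = 1e-9)
  expect_equal(sum(tr$p_long), 1, tolerance = 1e-9)
  cp <- tr$config$tail$stability_coupling
  a_wt <- tr$abundance * ifelse(tr$is_target, 1 + cp, 1)
  expect_equal(unname(rowSums(tr$expected$WT)), unname(a_wt), tolerance = 1e-9)
  expect_equal(unname(rowSums(tr$expected$mut)), unname(tr$abundance),
               tolerance = 1e-9)
})

test_that("tail extension shifts target mass to later fractions", {
  # Monte-Carlo oracle: sample molecules, allocate each by its own
  # fraction probabilities, compare the mean eluted fraction index
  fm <- fractionation_model()
  tm <- tail_model(delta = 200)
  set.seed(99)
  mc_mean_fraction <- function(mean_tail) {
    L <- rgamma(1e4, shape = tm$baseline_shape,
                rate = tm$baseline_shape / mean_tail)
    p <- fraction_probabilities(L, fm)
    f <- vapply(seq_len(nrow(p)), function(i) sample.int(6, 1, prob = p[i, ]),
                integer(1))
    mean(f)
  }
  mc_wt <- mc_mean_fraction(tm$baseline_mean + tm$delta)
  mc_mut <- mc_mean_fraction(tm$baseline_mean)
  expect_gt(mc_wt, mc_mut)
  # the generator's expected profiles agree with the oracle
  exp_wt <- sum(seq_len(6) * polyafrac:::expected_fraction_profile(
    tm$baseline_mean + tm$delta, tm$baseline_shape, fm))
  exp_mut <- sum(seq_len(6) * polyafrac:::expected_fraction_profile(
    tm$baseline_mean, tm$baseline_shape, fm))
  expect_equal(mc_wt, exp_wt, tolerance = 0.05)
  expect_equal(mc_mut, exp_mut, tolerance = 0.05)
  # and realized counts show the same ordering for targets
  sim <- simulate_fractionation(small_config(tail = tm), sequences = FALSE)
  cnt <- sim$counts$counts[sim$annotation$is_target, ]
  sam <- sim$counts$samples
  wmean <- function(cond) {
    libs <- sam$condition == cond
    sum(rep(sam$fraction[libs], each = nrow(cnt)) * cnt[, libs]) /
      sum(cnt[, libs])
  }
  expect_gt(wmean("WT"), wmean("mut"))
})

test_that("increasing delta monotonically increases expected long-fraction mass", {
  fm <- fractionation_model()
  mass <- vapply(c(0, 50, 150, 300), function(d) {
    p <- polyafrac:::expected_fraction_profile(90 + d, 2, fm)
    p[5] + p[6]
  }, numeric(1))
  expect_true(all(diff(mass) > 0))
})

test_that("spike-in counts are exchangeable between conditions", {
  cfg <- function(s) sim_config(n_transcripts = 100, mean_depth = 2e4,
                                n_spikeins = 20, seed = s)
  pvals <- vapply(1:100, function(s) {
    sim <- simulate_fractionation(cfg(s), sequences = FALSE)
    spk <- sim$counts$counts[sim$counts$is_spikein, ]
    sam <- sim$counts$samples
    suppressWarnings(wilcox.test(colSums(spk[, sam$condition == "WT"]),
                                 colSums(spk[, sam$condition == "mut"]))$p.value)
  }, numeric(1))
  expect_lt(mean(pvals < 0.05), 0.15)
  expect_gt(median(pvals), 0.2)
})

test_that("LFQ simulation is deterministic with sound ground truth", {
  a <- simulate_lfq(n_proteins = 200, n_enriched = 10, seed = 5)
  b <- simulate_lfq(n_proteins = 200, n_enriched = 10, seed = 5)
  expect_identical(a, b)
  # enriched proteins' true specificity clears the background median
  tr <- a$truth
  expect_true(all(tr$true_specificity[tr$is_enriched] >=
                    median(tr$true_specificity[!tr$is_enriched])))
  # no enrichment -> bait and control drawn from the same law
  n0 <- simulate_lfq(n_proteins = 500, n_enriched = 0, seed = 6)
  p <- suppressWarnings(wilcox.test(log(n0$lfq$bait_1),
                                    log(n0$lfq$control_1))$p.value)
  expect_gt(p, 0.01)
  expect_error(simulate_lfq(n_proteins = 5, n_enriched = 6))
})
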