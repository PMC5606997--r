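test_that("hit-set comparison handles identity, disjointness and symmetry", {
  u <- sprintf("t%d", 1:20)
  a <- u[1:5]
  same <- compare_hit_sets(a, a, u)
  expect_equal(same$jaccard, 1)
  expect_equal(same$overlap_fraction_of_b, 1)
  disj <- compare_hit_sets(a, u[6:10], u)
  expect_equal(disj$n_overlap, 0)
  expect_equal(disj$jaccard, 0)
  ab <- compare_hit_sets(u[1:6], u[4:12], u)
  ba <- compare_hit_sets(u[4:12], u[1:6], u)
  expect_equal(ab$n_overlap, ba$n_overlap)
  expect_equal(ab$jaccard, ba$jaccard)
  expect_true(ab$n_overlap <= min(ab$n_a, ab$n_b))
  expect_error(compare_hit_sets(c(a, "zzz"), a, u), "zzz")
})

test_that("hypergeometric overlap p matches exhaustive enumeration", {
  u <- letters[1:10]
  a <- u[1:4]
  b <- c(u[1:3], u[5:6])  # |B| = 5, overlap 3
  cmp <- compare_hit_sets(a, b, u)
  draws <- combn(10, 5)
  overlaps <- colSums(matrix(draws %in% 1:4, nrow = 5))
  expect_equal(cmp$hypergeometric_p, mean(overlaps >= 3), tolerance = 1e-12)
})

test_that("length bias test pins its extremes and rejects degenerate input", {
  ann <- data.frame(transcript_id = sprintf("t%03d", 1:100),
                    utr3_length = 1:100 * 10L,
                    mrna_length = 1:100 * 50L + 500L,
                    is_spikein = FALSE)
  shortest <- ann$transcript_id[1:10]
  lb <- length_bias_test(shortest, ann, "utr3_length", n_perm = 200, seed = 1)
  expect_lt(lb$median_difference, 0)
  expect_equal(lb$p_value, 1 / 201)
  expect_error(length_bias_test(character(), ann), "empty")
  expect_error(length_bias_test(ann$transcript_id, ann), "strict subset")
  expect_error(length_bias_test("nope", ann), "absent")
})

test_that("length bias p-values are calibrated under random hit sets", {
  set.seed(33)
  ann <- data.frame(transcript_id = sprintf("t%03d", 1:100),
                    utr3_length = sample(100:2000, 100),
                    mrna_length = sample(600:9000, 100),
                    is_spikein = FALSE)
  p <- vapply(1:200, function(i) {
    hits <- sample(ann$transcript_id, 10)
    length_bias_test(hits, ann, "utr3_length", n_perm = 99, seed = i)$p_value
  }, numeric(1))
  # ~5% of runs below 0.05, within 3 binomial SEs
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 200) + 1e-9)
})

test_that("k-mer enrichment finds planted GU repeats and nothing in null", {
  set.seed(44)
  bg <- polyafrac:::random_dna(rep(300L, 60))
  fg <- polyafrac:::random_dna(rep(300L, 30))
  # identical fg and bg -> zero enrichment everywhere
  ke0 <- kmer_enrichment(bg, bg, k = 2, n_perm = 50, seed = 1)
  expect_equal(ke0$log2_enrichment, rep(0, 16))
  expect_true(all(grepl("^[ACGU]+$", ke0$kmer)))
  # plant isolated GT dinucleotides through the foreground (a periodic
  # GT-repeat would enrich TG almost equally)
  fg <- vapply(fg, function(s) {
    for (pos in seq(5, 285, by = 15)) substr(s, pos, pos + 1) <- "GT"
    s
  }, character(1))
  ke <- kmer_enrichment(fg, bg, k = 2, n_perm = 300, seed = 2)
  expect_equal(ke$kmer[1], "GU")
  expect_lte(ke$q[1], 0.05)
  expect_gt(ke$log2_enrichment[1], 0)
  # errors on degenerate input
  expect_error(kmer_enrichment(character(), bg), "non-empty")
  expect_error(kmer_enrichment(fg, bg, k = 500), "shortest")
})

test_that("single-sequence foreground identical to a background member is unremarkable", {
  set.seed(55)
  bg <- polyafrac:::random_dna(rep(200L, 40))
  ke <- kmer_enrichment(bg[1], bg, k = 2, n_perm = 200, seed = 3)
  expect_gt(median(ke$p), 0.2)
  expect_true(all(ke$q >= ke$p))
})

test_that("expression coupling is exact on identity input and signed in simulation", {
  sm <- simulate_fractionation(small_config(mean_depth = 2e5), sequences = FALSE)
  ft <- polyafit(sm)
  rmean <- rowMeans(cbind(ft$table$log2_ratio_f5, ft$table$log2_ratio_f6))
  ident <- expression_coupling(ft, setNames(rmean, ft$table$transcript_id))
  expect_equal(ident$rho, 1)
  expect_true(ident$n >= 10)
  # coupling = 1 gives a positive rank correlation across seeds
  rho1 <- vapply(1:8, function(s) {
    cfg <- sim_config(n_transcripts = 800, mean_depth = 1e5, seed = s,
                      tail = tail_model(stability_coupling = 1))
    suppressWarnings(
      expression_coupling(polyafit(simulate_fractionation(cfg, sequences = FALSE)))$rho)
  }, numeric(1))
  expect_gte(sum(rho1 > 0), 7)
  # warning and unreliable flag below 10 hits
  few <- ft
  few$table$combined_hit <- c(rep(TRUE, 3), rep(FALSE, nrow(ft$table) - 3))
  expect_warning(res <- expression_coupling(few), "unreliable")
  expect_false(res$reliable)
})

test_that("label enrichment reduces to the hypergeometric overlap test", {
  u <- sprintf("g%d", 1:50)
  hits <- u[1:10]
  lab <- u[6:20]
  le <- label_enrichment(hits, lab, u)
  expect_equal(le$n_overlap, 5)
  expect_equal(le$p, phyper(4, 10, 40, 15, lower.tail = FALSE))
})
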