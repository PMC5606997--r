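# shared fixtures and independent oracles

small_config <- function(n_transcripts = 300, mean_depth = 5e4,
                         n_spikeins = 12, seed = 42, ...) {
  sim_config(n_transcripts = n_transcripts, mean_depth = mean_depth,
             n_spikeins = n_spikeins, seed = seed, ...)
}

# build a minimal single-replicate experiment from per-library count vectors
make_counts <- function(wt_f1, wt_f5, wt_f6, mut_f1, mut_f5, mut_f6,
                        ids = sprintf("T%02d", seq_along(wt_f1)),
                        is_spikein = NULL) {
  mat <- cbind(WT_f1_r1 = wt_f1, WT_f5_r1 = wt_f5, WT_f6_r1 = wt_f6,
               mut_f1_r1 = mut_f1, mut_f5_r1 = mut_f5, mut_f6_r1 = mut_f6)
  rownames(mat) <- ids
  samples <- data.frame(
    library_id = colnames(mat),
    condition = rep(c("WT", "mut"), each = 3),
    fraction = rep(c(1L, 5L, 6L), 2),
    replicate = 1L)
  polya_counts(mat, samples, is_spikein)
}

# brute-force polyadenylation ratio: direct arithmetic on the quotient,
# independent of the package's log-difference path
oracle_ratio <- function(counts, alpha, norm = TRUE) {
  sf <- if (norm) colSums(counts) / median(colSums(counts)) else rep(1, ncol(counts))
  nrm <- sweep(counts, 2, sf, "/")
  log2(((nrm[, "WT_f5_r1"] + alpha) / (nrm[, "WT_f1_r1"] + alpha)) /
         ((nrm[, "mut_f5_r1"] + alpha) / (nrm[, "mut_f1_r1"] + alpha)))
}

# exhaustive Benjamini-Hochberg step-up: sort, largest i with p_(i) <= i q / m
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
  rej
}

sim_sensitivity <- function(fit, sim) {
  tg <- names(which(sim$truth$is_target))
  if (!length(tg)) return(NA_real_)
  mean(tg %in% hits(fit))
}

sim_fdp <- function(fit, sim) {
  h <- hits(fit)
  if (!length(h)) return(0)
  tg <- names(which(sim$truth$is_target))
  mean(!(h %in% tg))
}
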