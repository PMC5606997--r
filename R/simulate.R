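#' Simulate an oligo-dT fractionation RNA-seq experiment
#'
#' Generates a complete fractionation experiment with known ground truth.
#' Each transcript has a steady-state abundance (log-normal across
#' transcripts) and a gamma tail-length law; target transcripts get their
#' mean tail extended by `delta` nt in the WT condition and, when
#' `stability_coupling > 0`, a proportional abundance increase. Molecules
#' are allocated to the six elution fractions through
#' [fraction_probabilities()] (in expectation, via quadrature over the tail
#' law), spike-in rows are added with expected counts identical in every
#' library, and each library's counts are drawn negative-binomially around
#' the composition scaled to the library depth. 3'-UTR annotations and
#' sequences (i.i.d. ACGT background, optional planted motif in targets)
#' complete the ground truth.
#'
#' The same seed reproduces the output exactly; per-library count draws use
#' sub-streams derived from the master seed.
#'
#' @param config A [sim_config()].
#' @param sequences Generate 3'-UTR sequences? Sequence generation uses its
#'   own sub-stream, so counts are identical either way.
#' @return An object of class `"polya_sim"`: a list with elements `counts`
#'   (a [polya_counts()] object), `annotation` (transcript records:
#'   `transcript_id`, `mrna_length`, `utr3_length`, `is_target`,
#'   `is_spikein`), `utr3` (named sequences or `NULL`) and `truth`
#'   (the config, per-transcript abundances, fraction profiles and expected
#'   pre-depth-scaling per-fraction abundances).
#' @examples
#' sim <- simulate_fractionation(sim_config(n_transcripts = 100,
#'                                          mean_depth = 2e4, seed = 7))
#' sim$counts
#' @export
simulate_fractionation <- function(config = sim_config(), sequences = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_transcripts
  if (n == 0 && config$target_fraction > 0)
    stop("target_fraction > 0 requires n_transcripts > 0")
  tm <- config$tail
  fm <- config$fractionation
  set.seed(config$seed)

  tx_id <- if (n) sprintf("TX%05d", seq_len(n)) else character(0)
  is_target <- rep(FALSE, n)
  if (!is.null(config$target_ids)) {
    if (!all(config$target_ids %in% tx_id))
      stop("target_ids not among simulated transcript ids")
    is_target <- tx_id %in% config$target_ids
  } else if (n > 0 && config$target_fraction > 0) {
    is_target[sample.int(n, round(n * config$target_fraction))] <- TRUE
  }

  abundance <- if (n) stats::rlnorm(n, meanlog = log(100), sdlog = 1) else numeric(0)
  mrna_length <- pmax(500L, as.integer(round(stats::rlnorm(n, log(2500), 0.45))))
  utr_len <- as.integer(round(stats::rlnorm(n, log(800), 0.6)))
  utr_len[is_target] <- as.integer(round(utr_len[is_target] * config$utr_length_bias))
  utr_len <- pmin(pmax(utr_len, 30L), mrna_length - 50L)

  m <- config$n_spikeins
  spike_id <- if (m) sprintf("SPIKE%03d", seq_len(m)) else character(0)
  spike_len <- as.integer(round(stats::runif(m, 250, 2000)))
  spike_raw <- stats::rlnorm(m, 0, 1)

  # expected fraction profiles: one for baseline tails, one for extended
  p_base <- expected_fraction_profile(tm$baseline_mean, tm$baseline_shape, fm)
  p_long <- if (tm$delta > 0)
    expected_fraction_profile(tm$baseline_mean + tm$delta, tm$baseline_shape, fm)
  else p_base

  nf <- fm$n_fractions
  P_wt <- matrix(p_base, n, nf, byrow = TRUE)
  if (any(is_target))
    P_wt[is_target, ] <- matrix(p_long, sum(is_target), nf, byrow = TRUE)
  A_wt <- abundance * ifelse(is_target, 1 + tm$stability_coupling, 1)
  E <- list(WT = A_wt * P_wt, mut = abundance * matrix(p_base, n, nf, byrow = TRUE))

  # spike mass fixed per library at ~5% of the mean fraction mass
  if (m) {
    mean_mass <- if (n) mean(c(colSums(E$WT), colSums(E$mut))) else 1
    spike_ab <- spike_raw / sum(spike_raw) * 0.05 * max(mean_mass, 1e-12)
  } else spike_ab <- numeric(0)

  libs <- expand.grid(replicate = seq_len(config$replicates),
                      fraction = seq_len(nf), condition = c("WT", "mut"),
                      stringsAsFactors = FALSE)
  libs <- libs[, c("condition", "fraction", "replicate")]
  libs$library_id <- sprintf("%s_f%d_r%d", libs$condition, libs$fraction,
                             libs$replicate)
  counts <- matrix(0L, n + m, nrow(libs),
                   dimnames = list(c(tx_id, spike_id), libs$library_id))
  size <- 1 / config$nb_dispersion
  for (i in seq_len(nrow(libs))) {
    set.seed(derive_seed(config$seed, 100L + i))
    rel <- c(E[[libs$condition[i]]][, libs$fraction[i]], spike_ab)
    depth <- config$mean_depth * exp(stats::rnorm(1, 0, 0.15))
    mu <- depth * rel / sum(rel)
    counts[, i] <- stats::rnbinom(length(mu), mu = mu, size = size)
  }

  utr_seq <- NULL
  if (sequences && n) {
    set.seed(derive_seed(config$seed, 1L))
    utr_seq <- random_dna(utr_len)
    if (!is.null(config$planted_motif) && any(is_target)) {
      motif <- config$planted_motif
      nm <- nchar(motif)
      for (j in which(is_target)) {
        span <- utr_len[j] - nm + 1L
        if (span < 1L) next
        for (pos in sample.int(span, min(3L, span)))
          substr(utr_seq[j], pos, pos + nm - 1L) <- motif
      }
    }
    names(utr_seq) <- tx_id
  }

  annotation <- data.frame(
    transcript_id = c(tx_id, spike_id),
    mrna_length = c(mrna_length, spike_len),
    utr3_length = c(utr_len, rep(NA_integer_, m)),
    is_target = c(is_target, rep(FALSE, m)),
    is_spikein = c(rep(FALSE, n), rep(TRUE, m)),
    stringsAsFactors = FALSE)

  samples <- libs[, c("library_id", "condition", "fraction", "replicate")]
  structure(list(
    counts = polya_counts(counts, samples,
                          c(rep(FALSE, n), rep(TRUE, m))),
    annotation = annotation,
    utr3 = utr_seq,
    truth = list(config = config,
                 is_target = stats::setNames(is_target, tx_id),
                 abundance = stats::setNames(abundance, tx_id),
                 p_base = p_base, p_long = p_long,
                 expected = E, spike_ab = stats::setNames(spike_ab, spike_id))),
    class = "polya_sim")
}

#' @export
print.polya_sim <- function(x, ...) {
  cat(sprintf("polya_sim: %d transcripts (%d targets), %d spike-ins, %d libraries (seed %d)\n",
              sum(!x$annotation$is_spikein), sum(x$annotation$is_target),
              sum(x$annotation$is_spikein), ncol(x$counts$counts),
              x$truth$config$seed))
  invisible(x)
}

#' Simulate a Co-IP label-free quantification table
#'
#' Generates a protein table with log-normal LFQ intensities over bait and
#' control runs. Enriched proteins (true interactors) carry bait-level
#' signal but are either absent from the control or strongly depleted
#' there; a configurable subset of background proteins is flagged as common
#' contaminants.
#'
#' @param n_proteins Total number of proteins.
#' @param n_enriched Number of true bait-enriched proteins.
#' @param n_contaminants Number of background proteins flagged contaminant.
#' @param n_bait,n_control Replicate runs per arm.
#' @param seed Seed; identical seeds reproduce the table exactly.
#' @return A list with `lfq` (data frame: `protein_id`, `mw_kda`, one
#'   intensity column per run), `runs` (run sheet: `run`, `role`), and
#'   `truth` (data frame with `is_enriched`, `is_contaminant`, and the
#'   generating `true_specificity`).
#' @export
simulate_lfq <- function(n_proteins = 1000, n_enriched = 20,
                         n_contaminants = 10, n_bait = 2, n_control = 2,
                         seed = 1) {
  stopifnot(n_proteins >= 1, n_enriched >= 0, n_enriched <= n_proteins,
            n_contaminants >= 0, n_contaminants <= n_proteins - n_enriched,
            n_bait >= 1, n_control >= 1)
  set.seed(seed)
  id <- sprintf("P%04d", seq_len(n_proteins))
  mw <- stats::rlnorm(n_proteins, log(50), 0.4)
  base <- stats::rlnorm(n_proteins, log(1e8), 1.5)
  enriched <- rep(FALSE, n_proteins)
  if (n_enriched) enriched[sample.int(n_proteins, n_enriched)] <- TRUE
  contaminant <- rep(FALSE, n_proteins)
  if (n_contaminants)
    contaminant[sample(which(!enriched), n_contaminants)] <- TRUE

  noise <- function(k) matrix(stats::rlnorm(n_proteins * k, 0, 0.25),
                              n_proteins, k)
  bait <- base * noise(n_bait)
  ctrl <- base * noise(n_control)
  if (n_enriched) {
    # bait-only or bait >> control
    absent <- enriched & (stats::runif(n_proteins) < 0.5)
    ctrl[absent, ] <- 0
    ctrl[enriched & !absent, ] <- ctrl[enriched & !absent, , drop = FALSE] / 30
  }
  colnames(bait) <- sprintf("bait_%d", seq_len(n_bait))
  colnames(ctrl) <- sprintf("control_%d", seq_len(n_control))
  mean_ctrl <- rowMeans(ctrl)
  truth <- data.frame(protein_id = id, is_enriched = enriched,
                      is_contaminant = contaminant,
                      true_specificity = rowMeans(bait) / pmax(mean_ctrl, 1),
                      stringsAsFactors = FALSE)
  list(lfq = data.frame(protein_id = id, mw_kda = mw, bait, ctrl,
                        stringsAsFactors = FALSE),
       runs = data.frame(run = c(colnames(bait), colnames(ctrl)),
                         role = rep(c("bait", "control"), c(n_bait, n_control)),
                         stringsAsFactors = FALSE),
       truth = truth)
}
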