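#' Poly(A) tail-length model
#'
#' Describes per-transcript poly(A) tail lengths as gamma distributed with a
#' fixed shape and a condition-dependent mean. Transcripts flagged as targets
#' of the polymerase get their mean tail extended by `delta` nucleotides in
#' the active-enzyme (WT) condition only, and optionally a steady-state
#' abundance increase coupled to that polyadenylation
#' (`stability_coupling`), mimicking stabilisation of the extended mRNAs.
#'
#' @param baseline_mean Mean tail length (nt) of non-target transcripts and
#'   of every transcript in the catalytically dead (mut) condition.
#' @param baseline_shape Gamma shape of the tail-length distribution; the
#'   gamma law is non-negative and right-skewed like measured tail-length
#'   distributions.
#' @param delta Mean tail extension (nt) applied to targets in WT only.
#' @param stability_coupling Multiplier on the total molecule count of
#'   targets in WT (`0` = no coupling; `1` doubles their abundance).
#' @return An object of class `"tail_model"`.
#' @examples
#' tail_model(baseline_mean = 90, delta = 300)
#' @export
tail_model <- function(baseline_mean = 90, baseline_shape = 2, delta = 300,
                       stability_coupling = 1) {
  stopifnot(baseline_mean > 0, baseline_shape > 0, delta >= 0,
            stability_coupling >= 0)
  structure(list(baseline_mean = baseline_mean, baseline_shape = baseline_shape,
                 delta = delta, stability_coupling = stability_coupling),
            class = "tail_model")
}

#' Oligo-dT elution fractionation model
#'
#' Models the stepwise low-salt elution that partitions mRNAs into ordered
#' fractions by tail length: fraction 1 holds the shortest tails, the last
#' fraction the longest. Boundaries between fractions are blurred by a
#' logistic kernel of scale `softness`, reflecting the imperfect separation
#' of an affinity elution series.
#'
#' @param breakpoints Strictly increasing tail-length boundaries (nt) between
#'   consecutive fractions; `length(breakpoints) + 1` fractions result.
#' @param softness Logistic scale (nt) of the boundary blur; small values
#'   approach a hard partition.
#' @return An object of class `"fractionation_model"`.
#' @export
fractionation_model <- function(breakpoints = c(30, 60, 100, 150, 220),
                                softness = 10) {
  stopifnot(is.numeric(breakpoints), length(breakpoints) >= 1,
            all(is.finite(breakpoints)), !is.unsorted(breakpoints, strictly = TRUE),
            is.numeric(softness), length(softness) == 1, softness > 0)
  structure(list(breakpoints = as.numeric(breakpoints),
                 n_fractions = length(breakpoints) + 1L,
                 softness = as.numeric(softness)),
            class = "fractionation_model")
}

#' Fraction membership probabilities for a tail length
#'
#' Probability that a molecule with a given poly(A) tail length elutes in
#' each fraction, defined as successive differences of logistic CDFs at the
#' fraction breakpoints. Probabilities sum to one; as the tail grows, mass
#' moves monotonically towards later (longer-tail) fractions.
#'
#' @param tail_length Tail length(s) in nt; finite and non-negative.
#' @param model A [fractionation_model()].
#' @return A numeric vector of `n_fractions` probabilities for a single
#'   length, or a matrix (lengths by fractions) for a vector input.
#' @examples
#' fraction_probabilities(120, fractionation_model())
#' @export
fraction_probabilities <- function(tail_length, model = fractionation_model()) {
  if (!is.numeric(tail_length) || length(tail_length) == 0 ||
      any(!is.finite(tail_length)) || any(tail_length < 0))
    stop("`tail_length` must be finite and non-negative")
  b <- model$breakpoints
  cum <- stats::plogis(outer(-as.numeric(tail_length), b, `+`) / model$softness)
  p <- cbind(cum[, 1L, drop = FALSE],
             cum[, -1L, drop = FALSE] - cum[, -length(b), drop = FALSE],
             1 - cum[, length(b), drop = FALSE])
  colnames(p) <- paste0("fraction_", seq_len(model$n_fractions))
  if (length(tail_length) == 1L) p[1L, ] else p
}

# expected fraction profile of a gamma tail-length law, by midpoint
# quadrature on the quantile scale
expected_fraction_profile <- function(mean, shape, model = fractionation_model(),
                                      nq = 256L) {
  q <- stats::qgamma((seq_len(nq) - 0.5) / nq, shape = shape, rate = shape / mean)
  colMeans(fraction_probabilities(q, model))
}

#' Configuration of a synthetic fractionation experiment
#'
#' Bundles every knob of the generator: library design (conditions WT/mut,
#' one library per fraction and replicate), transcriptome size, the tail and
#' fractionation models, sequencing depth and negative-binomial noise,
#' ERCC-like spike-ins, and the target-specific 3'-UTR features (length
#' scaling and an optionally planted motif).
#'
#' @param n_transcripts Number of (non-spike-in) transcripts.
#' @param target_fraction Fraction of transcripts that are true polymerase
#'   targets (tail elongated in WT).
#' @param replicates Libraries per (condition, fraction); the default single
#'   library per fraction matches a typical elution-series design.
#' @param mean_depth Mean reads per library.
#' @param nb_dispersion Negative-binomial (gamma-Poisson) dispersion of
#'   sequencing counts.
#' @param tail A [tail_model()].
#' @param fractionation A [fractionation_model()].
#' @param n_spikeins Number of spike-in control rows, identical in
#'   expectation across conditions and fractions (the ERCC mix has 92).
#' @param utr_length_bias Multiplier on target 3'-UTR lengths (1 = none;
#'   values below 1 emulate target transcripts having shorter UTRs).
#' @param planted_motif Optional motif (DNA or RNA alphabet) planted in
#'   target 3'-UTRs; `NULL` plants nothing.
#' @param target_ids Optional explicit character vector of target transcript
#'   ids (overrides `target_fraction`), useful for simulating two cell lines
#'   with partially shared target sets.
#' @param seed Master seed; per-library sub-streams are derived from it
#'   deterministically.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_transcripts = 5000, target_fraction = 0.1,
                       replicates = 1, mean_depth = 1e6, nb_dispersion = 0.05,
                       tail = tail_model(), fractionation = fractionation_model(),
                       n_spikeins = 92, utr_length_bias = 1,
                       planted_motif = NULL, target_ids = NULL, seed = 1) {
  stopifnot(n_transcripts >= 0, target_fraction >= 0, target_fraction <= 1,
            replicates >= 1, mean_depth > 0, nb_dispersion > 0,
            inherits(tail, "tail_model"),
            inherits(fractionation, "fractionation_model"),
            n_spikeins >= 0, utr_length_bias > 0)
  if (!is.null(planted_motif)) {
    planted_motif <- toupper(rna_to_dna(planted_motif))
    stopifnot(grepl("^[ACGT]+$", planted_motif))
  }
  structure(list(n_transcripts = as.integer(n_transcripts),
                 target_fraction = target_fraction,
                 replicates = as.integer(replicates),
                 mean_depth = mean_depth, nb_dispersion = nb_dispersion,
                 tail = tail, fractionation = fractionation,
                 n_spikeins = as.integer(n_spikeins),
                 utr_length_bias = utr_length_bias,
                 planted_motif = planted_motif,
                 target_ids = target_ids,
                 seed = as.integer(seed)),
            class = "sim_config")
}
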