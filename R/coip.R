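#' Score Co-IP mass-spectrometry enrichment from LFQ intensities
#'
#' Computes the two dot-plot coordinates used to read a label-free Co-IP
#' experiment: *abundance* = mean bait LFQ intensity divided by the
#' protein's molecular weight, and *specificity* = mean bait LFQ intensity
#' divided by the mean negative-control LFQ intensity, with the background
#' level set to `background_floor` (default 1, in raw LFQ units) for
#' proteins not detected in the control. Proteins undetected in the bait
#' are dropped; contaminant-flagged proteins stay in the scored table but
#' are excluded from exported plot coordinates.
#'
#' @param lfq Data frame with `protein_id`, `mw_kda` and one intensity
#'   column per run (0 = not detected).
#' @param runs Run sheet data frame with columns `run` and `role`
#'   (`"bait"` or `"control"`).
#' @param contaminants Character vector of contaminant protein ids.
#' @param background_floor Background level substituted for proteins
#'   undetected in the control.
#' @return Data frame of class `"coip_scores"`: `protein_id`, `mw_kda`,
#'   `lfq_bait`, `lfq_control`, `abundance`, `specificity`,
#'   `is_contaminant`.
#' @examples
#' sim <- simulate_lfq(n_proteins = 50, n_enriched = 5, seed = 2)
#' head(score_coip(sim$lfq, sim$runs))
#' @export
score_coip <- function(lfq, runs, contaminants = character(),
                       background_floor = 1) {
  stopifnot(is.data.frame(lfq), is.data.frame(runs),
            all(c("protein_id", "mw_kda") %in% names(lfq)),
            all(c("run", "role") %in% names(runs)),
            background_floor > 0)
  bad_role <- setdiff(unique(runs$role), c("bait", "control"))
  if (length(bad_role))
    stop("unknown run role(s): ", paste(bad_role, collapse = ", "))
  miss <- setdiff(runs$run, names(lfq))
  if (length(miss))
    stop("run(s) missing from LFQ table: ", paste(miss, collapse = ", "))
  bad_mw <- is.na(lfq$mw_kda) | lfq$mw_kda <= 0
  if (any(bad_mw))
    stop("missing or non-positive molecular weight for protein: ",
         paste(utils::head(lfq$protein_id[bad_mw], 5), collapse = ", "))
  bait_cols <- runs$run[runs$role == "bait"]
  ctrl_cols <- runs$run[runs$role == "control"]
  if (!length(bait_cols) || !length(ctrl_cols))
    stop("run sheet needs at least one bait and one control run")
  inten <- as.matrix(lfq[c(bait_cols, ctrl_cols)])
  if (any(inten < 0, na.rm = TRUE)) {
    bad <- which(inten < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative LFQ intensity for protein '%s'",
                 lfq$protein_id[bad[1]]))
  }
  mean_bait <- rowMeans(as.matrix(lfq[bait_cols]))
  mean_ctrl <- rowMeans(as.matrix(lfq[ctrl_cols]))
  detected <- mean_bait > 0
  background <- ifelse(mean_ctrl > 0, mean_ctrl, background_floor)
  out <- data.frame(protein_id = as.character(lfq$protein_id),
                    mw_kda = lfq$mw_kda,
                    lfq_bait = mean_bait, lfq_control = mean_ctrl,
                    abundance = mean_bait / lfq$mw_kda,
                    specificity = mean_bait / background,
                    is_contaminant = lfq$protein_id %in% contaminants,
                    stringsAsFactors = FALSE)[detected, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("coip_scores", "data.frame")
  out
}

#' Dot-plot coordinates of scored Co-IP proteins
#'
#' Log10 abundance (x) and log10 specificity (y) of every scored,
#' non-contaminant protein; the specificity background floor guarantees
#' finite coordinates. The bait itself can be flagged for labelling.
#'
#' @param scores A [score_coip()] result.
#' @param bait Optional bait protein id to flag.
#' @return Data frame with `protein_id`, `log10_abundance`,
#'   `log10_specificity`, `is_bait`.
#' @export
dotplot_coords <- function(scores, bait = NULL) {
  stopifnot(inherits(scores, "coip_scores"))
  s <- scores[!scores$is_contaminant, , drop = FALSE]
  data.frame(protein_id = s$protein_id,
             log10_abundance = log10(s$abundance),
             log10_specificity = log10(s$specificity),
             is_bait = if (is.null(bait)) FALSE else s$protein_id %in% bait,
             stringsAsFactors = FALSE)
}

#' @export
plot.coip_scores <- function(x, bait = NULL, ...) {
  xy <- dotplot_coords(x, bait)
  graphics::plot(xy$log10_abundance, xy$log10_specificity,
                 pch = 19, col = ifelse(xy$is_bait, "red", "grey30"),
                 xlab = "log10 abundance (LFQ / MW)",
                 ylab = "log10 specificity (bait / background)", ...)
  invisible(x)
}

#' Read an LFQ table, run sheet and optional contaminant list
#'
#' @param lfq_path TSV with `protein_id`, `mw_kda` and one column per run.
#' @param runs_path TSV with `run` and `role` columns.
#' @param contaminants_path Optional plain-text file, one protein id per
#'   line.
#' @return List with `lfq`, `runs` and `contaminants`.
#' @export
read_lfq <- function(lfq_path, runs_path, contaminants_path = NULL) {
  lfq <- read_tsv(lfq_path)
  runs <- read_tsv(runs_path)
  contaminants <- if (is.null(contaminants_path)) character()
                  else readLines(contaminants_path)
  contaminants <- contaminants[nzchar(contaminants)]
  list(lfq = lfq, runs = runs, contaminants = contaminants)
}
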