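#' Normalize fraction libraries by spike-in or total counts
#'
#' Computes one size factor per library — the sum over spike-in rows
#' (`mode = "spikein"`, the fraction-independent anchor) or over all rows
#' (`mode = "total"`) — anchored so the median library has factor 1, and
#' divides each library's counts by its factor. `mode = "auto"` picks
#' spike-in normalization when at least three spike-in rows are present.
#' Median anchoring keeps normalized counts of every other library exactly
#' unchanged when a single library is rescaled.
#'
#' @param x A [polya_counts()] object.
#' @param mode `"auto"`, `"spikein"` or `"total"`.
#' @return An object of class `"polya_norm"`: normalized `values`,
#'   `size_factors`, the `mode` used, the sample sheet and spike-in flags.
#' @export
normalize_counts <- function(x, mode = c("auto", "spikein", "total")) {
  stopifnot(inherits(x, "polya_counts"))
  mode <- match.arg(mode)
  if (mode == "auto")
    mode <- if (sum(x$is_spikein) >= 3) "spikein" else "total"
  sel <- if (mode == "spikein") x$is_spikein else rep(TRUE, nrow(x$counts))
  if (mode == "spikein" && sum(sel) < 3)
    stop("spike-in normalization requires at least 3 spike-in rows")
  raw <- colSums(x$counts[sel, , drop = FALSE])
  if (any(raw == 0))
    stop(sprintf("zero %s sum in library: %s",
                 if (mode == "spikein") "spike-in" else "total",
                 paste(names(raw)[raw == 0], collapse = ", ")))
  sf <- raw / stats::median(raw)
  structure(list(values = sweep(x$counts, 2, sf, `/`),
                 size_factors = sf, mode = mode,
                 samples = x$samples, is_spikein = x$is_spikein),
            class = "polya_norm")
}

#' @export
print.polya_norm <- function(x, ...) {
  cat(sprintf("polya_norm: %d x %d normalized counts (%s size factors)\n",
              nrow(x$values), ncol(x$values), x$mode))
  print(round(x$size_factors, 3))
  invisible(x)
}

# replicate-averaged normalized counts of one (condition, fraction) group
cond_fraction_means <- function(nc, condition, fraction) {
  libs <- nc$samples$library_id[nc$samples$condition == condition &
                                nc$samples$fraction == fraction]
  if (!length(libs))
    stop(sprintf("no library for condition %s, fraction %d", condition, fraction))
  rowMeans(nc$values[, libs, drop = FALSE])
}

#' Per-transcript log2 polyadenylation ratio
#'
#' The ratio-of-ratios statistic: the abundance of a transcript in a long
#' poly(A) fraction `k` relative to the short fraction, in the WT
#' (active-enzyme) condition, divided by the same relative abundance in the
#' catalytic-mutant condition, on replicate-averaged normalized counts with
#' a pseudocount:
#' \deqn{r = \log_2\frac{(n_{k} + \alpha)/(n_{1} + \alpha)\,[\mathrm{WT}]}{
#'                      (n_{k} + \alpha)/(n_{1} + \alpha)\,[\mathrm{mut}]}}
#' Swapping the condition labels negates the statistic exactly. With
#' `pseudocount = 0`, transcripts with zero denominators yield `NaN`/`Inf`
#' rather than an error.
#'
#' @param nc A [normalize_counts()] result.
#' @param k Long fraction index (5 or 6 in a six-fraction elution).
#' @param pseudocount Pseudocount \eqn{\alpha \ge 0} added to the averaged
#'   normalized counts.
#' @param short_fraction Reference short-tail fraction (default 1).
#' @return Named numeric vector of log2 ratios (all rows, including
#'   spike-ins; callers typically drop spike-ins downstream).
#' @export
polya_ratio <- function(nc, k = 5, pseudocount = 0.5, short_fraction = 1) {
  stopifnot(inherits(nc, "polya_norm"), pseudocount >= 0)
  l2 <- function(v) log2(v + pseudocount)
  (l2(cond_fraction_means(nc, "WT", k)) -
     l2(cond_fraction_means(nc, "WT", short_fraction))) -
    (l2(cond_fraction_means(nc, "mut", k)) -
       l2(cond_fraction_means(nc, "mut", short_fraction)))
}

#' Fit the robust normal null of a log-ratio distribution
#'
#' The bulk of transcripts is unaffected by the polymerase, so the log2
#' polyadenylation ratios of most transcripts form an approximately normal
#' null around zero, with an outlying right tail of true substrates. The
#' null is fitted robustly — location = median, scale = 1.4826 x MAD — so
#' that the outlier population does not inflate the fitted spread.
#'
#' @param x Numeric vector of log2 ratios; non-finite values are dropped and
#'   at least 3 finite values are required.
#' @return An object of class `"polya_null"` with elements `mu`, `sigma`,
#'   `method` (`"median-MAD"`) and `n_used`.
#' @export
fit_null <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3)
    stop("need at least 3 finite log-ratios to fit the null")
  mu <- stats::median(x)
  sigma <- stats::mad(x)  # constant 1.4826 for normal consistency
  if (sigma <= 0)
    stop("degenerate null: MAD of the log-ratios is zero")
  structure(list(mu = mu, sigma = sigma, method = "median-MAD",
                 n_used = length(x)),
            class = "polya_null")
}

#' @export
print.polya_null <- function(x, ...) {
  cat(sprintf("normal null (%s): mu = %.4f, sigma = %.4f, n = %d\n",
              x$method, x$mu, x$sigma, x$n_used))
  invisible(x)
}

#' Call polyadenylated-transcript hits from long-fraction ratios
#'
#' Standardizes each fraction's log2 ratios against its fitted null
#' (`z = (r - mu)/sigma`), takes one-sided right-tail normal p-values,
#' adjusts them by Benjamini-Hochberg within each fraction, and flags a
#' transcript as a combined hit when it is significant in *every* long
#' fraction and passes the expression filter (mean normalized short-fraction
#' count across conditions at or above `min_expr`).
#'
#' @param ratios Named list of log2-ratio vectors, one per long fraction
#'   (names are fraction labels, e.g. `"5"`, `"6"`); all vectors must cover
#'   the same transcripts.
#' @param nulls Named list of [fit_null()] results matching `ratios`.
#' @param expression Named vector of mean normalized short-fraction counts.
#' @param q_threshold BH-adjusted significance threshold per fraction.
#' @param min_expr Expression filter on the short-fraction mean.
#' @return A data frame with, per fraction `k`: `log2_ratio_fk`, `z_fk`,
#'   `p_fk`, `q_fk`, `hit_fk`; plus `mean_f1_norm`, `expression_pass` and
#'   `combined_hit`.
#' @export
call_hits <- function(ratios, nulls, expression, q_threshold = 0.05,
                      min_expr = 10) {
  stopifnot(is.list(ratios), is.list(nulls), length(ratios) >= 1,
            identical(names(ratios), names(nulls)),
            q_threshold > 0, min_expr >= 0)
  ids <- names(ratios[[1]])
  out <- data.frame(transcript_id = ids, stringsAsFactors = FALSE)
  combined <- rep(TRUE, length(ids))
  for (k in names(ratios)) {
    r <- ratios[[k]]
    if (!identical(names(r), ids))
      stop("transcript sets differ between fraction ratio tables")
    nl <- nulls[[k]]
    z <- (r - nl$mu) / nl$sigma
    p <- stats::pnorm(z, lower.tail = FALSE)
    q <- stats::p.adjust(p, method = "BH")
    hit <- !is.na(q) & q <= q_threshold
    out[[paste0("log2_ratio_f", k)]] <- unname(r)
    out[[paste0("z_f", k)]] <- unname(z)
    out[[paste0("p_f", k)]] <- unname(p)
    out[[paste0("q_f", k)]] <- unname(q)
    out[[paste0("hit_f", k)]] <- hit
    combined <- combined & hit
  }
  expression <- expression[ids]
  out$mean_f1_norm <- unname(expression)
  out$expression_pass <- !is.na(expression) & expression >= min_expr
  out$combined_hit <- combined & out$expression_pass
  out
}
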