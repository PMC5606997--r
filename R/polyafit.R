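#' Fit the polyadenylation-ratio model to a fractionation experiment
#'
#' The central fitting function. Normalizes the libraries, computes the
#' per-transcript log2 polyadenylation ratio for each long fraction, fits a
#' robust normal null per fraction, and calls hits: transcripts whose
#' ratios are significant outliers (BH `q <= q_threshold`, one-sided right
#' tail) in **both** long fractions and that pass the expression filter on
#' the short fraction. Spike-in rows anchor normalization and are excluded
#' from the ratio table and the null fit.
#'
#' @param x A [polya_counts()] object or a `"polya_sim"` from
#'   [simulate_fractionation()].
#' @param pseudocount Pseudocount added to averaged normalized counts before
#'   forming ratios; prevents division by zero.
#' @param norm Normalization mode, see [normalize_counts()].
#' @param q_threshold Per-fraction BH significance threshold.
#' @param min_expr Expression filter: minimum mean normalized short-fraction
#'   count across conditions.
#' @param long_fractions Long-tail fraction indices (default 5 and 6).
#' @param short_fraction Short-tail reference fraction (default 1).
#' @return An object of class `"polyafit"` with components `table` (the
#'   per-transcript ratio/hit data frame), `null` (per-fraction
#'   [fit_null()] objects), `normalized` (the `"polya_norm"` object) and
#'   `params`. Methods: [print.polyafit()], [summary.polyafit()],
#'   [coef.polyafit()], [residuals.polyafit()], [plot.polyafit()], and the
#'   [hits()] accessor.
#' @examples
#' sim <- simulate_fractionation(sim_config(n_transcripts = 200,
#'                                          mean_depth = 5e4, seed = 3))
#' fit <- polyafit(sim)
#' summary(fit)
#' head(hits(fit))
#' @export
polyafit <- function(x, pseudocount = 0.5, norm = c("auto", "spikein", "total"),
                     q_threshold = 0.05, min_expr = 10,
                     long_fractions = c(5L, 6L), short_fraction = 1L) {
  if (inherits(x, "polya_sim")) x <- x$counts
  stopifnot(inherits(x, "polya_counts"))
  nc <- normalize_counts(x, match.arg(norm))
  keep <- !nc$is_spikein
  ratios <- lapply(long_fractions, function(k)
    polya_ratio(nc, k, pseudocount, short_fraction)[keep])
  names(ratios) <- as.character(long_fractions)
  # an exactly constant log-ratio distribution (e.g. WT identical to mut)
  # has no outliers: keep the fit usable, call nothing in that fraction
  nulls <- lapply(ratios, function(r) tryCatch(fit_null(r), error = function(e) {
    warning("degenerate log-ratio null (zero spread); no hits called",
            call. = FALSE)
    structure(list(mu = stats::median(r[is.finite(r)]), sigma = NA_real_,
                   method = "median-MAD", n_used = sum(is.finite(r))),
              class = "polya_null")
  }))
  expr <- rowMeans(cbind(cond_fraction_means(nc, "WT", short_fraction),
                         cond_fraction_means(nc, "mut", short_fraction)))[keep]
  table <- call_hits(ratios, nulls, expr, q_threshold, min_expr)
  structure(list(table = table, null = nulls, normalized = nc,
                 params = list(pseudocount = pseudocount, norm = nc$mode,
                               q_threshold = q_threshold, min_expr = min_expr,
                               long_fractions = as.integer(long_fractions),
                               short_fraction = as.integer(short_fraction))),
            class = "polyafit")
}

#' Combined-hit transcripts of a polyadenylation fit
#'
#' @param fit A [polyafit()] object.
#' @param which `"combined"` (default) for the both-fractions rule, or a
#'   fraction label (e.g. `"5"`) for single-fraction hits.
#' @return Character vector of transcript ids.
#' @export
hits <- function(fit, which = "combined") {
  stopifnot(inherits(fit, "polyafit"))
  col <- if (identical(which, "combined")) "combined_hit"
         else paste0("hit_f", which)
  if (is.null(fit$table[[col]])) stop("unknown hit column: ", col)
  fit$table$transcript_id[fit$table[[col]]]
}

#' @export
print.polyafit <- function(x, ...) {
  cat(sprintf("polyafit: %d transcripts, %d libraries, %s normalization\n",
              nrow(x$table), ncol(x$normalized$values), x$params$norm))
  for (k in names(x$null))
    cat(sprintf("  fraction %s null: mu = %.4f, sigma = %.4f; hits: %d\n",
                k, x$null[[k]]$mu, x$null[[k]]$sigma,
                sum(x$table[[paste0("hit_f", k)]])))
  cat(sprintf("  combined hits (all long fractions + expression filter): %d\n",
              sum(x$table$combined_hit)))
  invisible(x)
}

#' @rdname print.polyafit
#' @param object,x A `"polyafit"` object.
#' @param ... Unused.
#' @export
summary.polyafit <- function(object, ...) {
  tab <- object$table
  per <- do.call(rbind, lapply(names(object$null), function(k) data.frame(
    fraction = k, mu = object$null[[k]]$mu, sigma = object$null[[k]]$sigma,
    n_used = object$null[[k]]$n_used,
    n_hits = sum(tab[[paste0("hit_f", k)]]))))
  structure(list(per_fraction = per,
                 n_transcripts = nrow(tab),
                 n_expression_pass = sum(tab$expression_pass),
                 n_combined = sum(tab$combined_hit),
                 params = object$params),
            class = "summary.polyafit")
}

#' @export
print.summary.polyafit <- function(x, ...) {
  cat("Polyadenylation-ratio fit\n")
  cat(sprintf("  transcripts: %d; passing expression filter (>= %g): %d\n",
              x$n_transcripts, x$params$min_expr, x$n_expression_pass))
  cat("  per-fraction robust normal null and hit counts (BH q <=",
      format(x$params$q_threshold), "):\n")
  print(x$per_fraction, row.names = FALSE, digits = 4)
  cat(sprintf("  combined hits: %d\n", x$n_combined))
  invisible(x)
}

#' @rdname print.polyafit
#' @export
coef.polyafit <- function(object, ...) {
  t(vapply(object$null, function(nl) c(mu = nl$mu, sigma = nl$sigma),
           numeric(2)))
}

#' @rdname print.polyafit
#' @export
residuals.polyafit <- function(object, ...) {
  zc <- paste0("z_f", names(object$null))
  m <- as.matrix(object$table[zc])
  dimnames(m) <- list(object$table$transcript_id, names(object$null))
  m
}

#' Histogram of polyadenylation ratios with the fitted normal null
#'
#' Draws, for each long fraction, the histogram of log2 polyadenylation
#' ratios with the fitted null density as a red line, emphasising the
#' outlying population of polymerase substrates on the right tail.
#'
#' @param x A [polyafit()] object.
#' @param breaks Histogram breaks (passed to [graphics::hist()]).
#' @param ... Further arguments for [graphics::hist()].
#' @return Invisibly, `x`.
#' @export
plot.polyafit <- function(x, breaks = 60, ...) {
  ks <- names(x$null)
  op <- graphics::par(mfrow = c(1, length(ks)))
  on.exit(graphics::par(op))
  for (k in ks) {
    r <- x$table[[paste0("log2_ratio_f", k)]]
    r <- r[is.finite(r)]
    graphics::hist(r, breaks = breaks, freq = FALSE,
                   main = paste("Fraction", k),
                   xlab = "log2 polyadenylation ratio", ...)
    xx <- seq(min(r), max(r), length.out = 400)
    graphics::lines(xx, stats::dnorm(xx, x$null[[k]]$mu, x$null[[k]]$sigma),
                    col = "red", lwd = 2)
  }
  invisible(x)
}
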