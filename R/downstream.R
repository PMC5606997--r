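#' Concordance of two hit sets against a common universe
#'
#' Exact overlap counts, Jaccard index, the fraction of set B found in A
#' (the way a Venn "60% of B's hits are shared" statement is read), and a
#' hypergeometric upper-tail p-value for an overlap at least as large as
#' observed given the set sizes and the universe.
#'
#' @param hits_a,hits_b Character vectors of transcript ids; both must be
#'   subsets of `universe`.
#' @param universe Character vector of all tested transcripts.
#' @return An object of class `"hitset_comparison"` with `n_a`, `n_b`,
#'   `n_overlap`, `n_universe`, `jaccard`, `overlap_fraction_of_b` and
#'   `hypergeometric_p`.
#' @export
compare_hit_sets <- function(hits_a, hits_b, universe) {
  hits_a <- unique(as.character(hits_a))
  hits_b <- unique(as.character(hits_b))
  universe <- unique(as.character(universe))
  stray <- setdiff(union(hits_a, hits_b), universe)
  if (length(stray))
    stop("hits not in universe: ", paste(utils::head(stray, 5), collapse = ", "),
         if (length(stray) > 5) ", ..." else "")
  n_a <- length(hits_a); n_b <- length(hits_b)
  n_o <- length(intersect(hits_a, hits_b)); n_u <- length(universe)
  structure(list(
    n_a = n_a, n_b = n_b, n_overlap = n_o, n_universe = n_u,
    jaccard = if (n_a + n_b - n_o > 0) n_o / (n_a + n_b - n_o) else NaN,
    overlap_fraction_of_b = if (n_b > 0) n_o / n_b else NaN,
    hypergeometric_p = stats::phyper(n_o - 1, n_a, n_u - n_a, n_b,
                                     lower.tail = FALSE)),
    class = "hitset_comparison")
}

#' @export
print.hitset_comparison <- function(x, ...) {
  cat(sprintf("hit-set overlap: |A| = %d, |B| = %d, shared = %d (universe %d)\n",
              x$n_a, x$n_b, x$n_overlap, x$n_universe))
  cat(sprintf("  jaccard = %.3f; fraction of B shared = %.3f; hypergeometric p = %.3g\n",
              x$jaccard, x$overlap_fraction_of_b, x$hypergeometric_p))
  invisible(x)
}

#' Permutation test for a length bias in hit transcripts
#'
#' Tests whether hit transcripts are biased towards shorter 3'-UTRs (or
#' total mRNA length): the statistic is the median feature value of hits
#' minus the median of non-hits, and the left-tail p-value comes from
#' `n_perm` random hit sets of the same size, with +1 smoothing (so
#' `p >= 1/(n_perm + 1)`).
#'
#' @param hits Character vector of hit transcript ids; must be a non-empty
#'   strict subset of the annotated (non-spike-in) transcripts.
#' @param annotation Annotation data frame with `transcript_id`,
#'   `utr3_length`, `mrna_length` and (optionally) `is_spikein`.
#' @param feature `"utr3_length"` or `"mrna_length"`.
#' @param n_perm Number of permutations (at least 100 recommended).
#' @param seed Seed for the permutation draw.
#' @return A list of class `"length_bias"` with `feature`,
#'   `median_difference`, `p_value` and `n_perm`.
#' @export
length_bias_test <- function(hits, annotation,
                             feature = c("utr3_length", "mrna_length"),
                             n_perm = 1000, seed = 1) {
  feature <- match.arg(feature)
  stopifnot(n_perm >= 1)
  ann <- annotation
  if (!is.null(ann$is_spikein)) ann <- ann[!ann$is_spikein, , drop = FALSE]
  if (!length(hits)) stop("empty hit set")
  miss <- setdiff(hits, ann$transcript_id)
  if (length(miss))
    stop("hits absent from annotation: ",
         paste(utils::head(miss, 5), collapse = ", "))
  if (length(unique(hits)) >= nrow(ann))
    stop("hit set must be a strict subset of the annotated transcripts")
  v <- ann[[feature]]
  ishit <- ann$transcript_id %in% hits
  obs <- stats::median(v[ishit]) - stats::median(v[!ishit])
  m <- sum(ishit)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(nrow(ann), m)
    stats::median(v[idx]) - stats::median(v[-idx])
  }, numeric(1))
  structure(list(feature = feature, median_difference = obs,
                 p_value = (1 + sum(perm <= obs)) / (n_perm + 1),
                 n_perm = n_perm, n_hits = m),
            class = "length_bias")
}

#' @export
print.length_bias <- function(x, ...) {
  cat(sprintf("length bias (%s): median difference = %.1f, permutation p = %.4g (%d hits, %d perms)\n",
              x$feature, x$median_difference, x$p_value, x$n_hits, x$n_perm))
  invisible(x)
}

#' k-mer enrichment in hit 3'-UTRs against a background set
#'
#' Exhaustive k-mer composition test, a transparent stand-in for de novo
#' motif discovery: overlapping k-mer occurrence frequencies (per
#' nucleotide position) are compared between foreground and background
#' UTRs, with a pseudo-count log2 enrichment and a right-tail p-value from
#' permutation of sequence labels between the two sets. q-values are BH
#' over all `4^k` k-mers; k-mers are reported in the RNA alphabet
#' (GU, CU, ...).
#'
#' @param fg,bg Foreground and background sequences: named character
#'   vectors (DNA or RNA alphabet) or `DNAStringSet`s. Both non-empty; `k`
#'   must not exceed the shortest sequence.
#' @param k k-mer size (2 for dinucleotide composition).
#' @param n_perm Label permutations for the p-value.
#' @param seed Seed for the permutations.
#' @param pseudo Pseudo-occurrences added when forming the log2 enrichment.
#' @return Data frame of class `"kmer_enrichment"`, one row per k-mer,
#'   sorted by decreasing `log2_enrichment`: `kmer`, `fg_freq`, `bg_freq`,
#'   `log2_enrichment`, `p`, `q`.
#' @export
kmer_enrichment <- function(fg, bg, k = 2, n_perm = 1000, seed = 1,
                            pseudo = 0.5) {
  as_dss <- function(x)
    if (inherits(x, "DNAStringSet")) x
    else Biostrings::DNAStringSet(rna_to_dna(as.character(x)))
  fg <- as_dss(fg); bg <- as_dss(bg)
  if (!length(fg) || !length(bg))
    stop("foreground and background must both be non-empty")
  if (k < 1 || k > min(Biostrings::width(fg), Biostrings::width(bg)))
    stop("`k` must be between 1 and the shortest sequence length")
  M <- rbind(Biostrings::oligonucleotideFrequency(fg, width = k),
             Biostrings::oligonucleotideFrequency(bg, width = k))
  pos <- c(Biostrings::width(fg), Biostrings::width(bg)) - k + 1
  n_fg <- length(fg); n_all <- nrow(M)
  tot_occ <- colSums(M); tot_pos <- sum(pos)

  stat_for <- function(idx) {
    occ_f <- colSums(M[idx, , drop = FALSE]); pos_f <- sum(pos[idx])
    log2((occ_f + pseudo) / (pos_f + pseudo * 4^k)) -
      log2((tot_occ - occ_f + pseudo) / (tot_pos - pos_f + pseudo * 4^k))
  }
  obs_idx <- seq_len(n_fg)
  obs <- stat_for(obs_idx)
  set.seed(seed)
  exceed <- numeric(4^k)
  for (i in seq_len(n_perm))
    exceed <- exceed + (stat_for(sample.int(n_all, n_fg)) >= obs)
  p <- (1 + exceed) / (n_perm + 1)
  occ_fg <- colSums(M[obs_idx, , drop = FALSE])
  out <- data.frame(
    kmer = dna_to_rna(colnames(M)),
    fg_freq = occ_fg / sum(pos[obs_idx]),
    bg_freq = (tot_occ - occ_fg) / (tot_pos - sum(pos[obs_idx])),
    log2_enrichment = unname(obs),
    p = unname(p),
    q = unname(stats::p.adjust(p, method = "BH")),
    stringsAsFactors = FALSE)
  out <- out[order(-out$log2_enrichment), ]
  rownames(out) <- NULL
  class(out) <- c("kmer_enrichment", "data.frame")
  out
}

#' Total-expression log2 fold change per transcript
#'
#' Log2 fold change (WT vs mut) of total normalized abundance, summed over
#' all sequenced fractions after replicate averaging, with the fit's
#' pseudocount. Used to relate polyadenylation to steady-state levels.
#'
#' @param fit A [polyafit()] object.
#' @return Named numeric vector over the fit's (non-spike-in) transcripts.
#' @export
expression_log2fc <- function(fit) {
  stopifnot(inherits(fit, "polyafit"))
  nc <- fit$normalized
  alpha <- fit$params$pseudocount
  total <- function(cc) {
    fr <- sort(unique(nc$samples$fraction[nc$samples$condition == cc]))
    Reduce(`+`, lapply(fr, function(f) cond_fraction_means(nc, cc, f)))
  }
  fc <- log2(total("WT") + alpha) - log2(total("mut") + alpha)
  fc[!nc$is_spikein]
}

#' Correlation between polyadenylation and expression change
#'
#' Spearman rank correlation, over combined hits, between the long-fraction
#' log2 polyadenylation ratio (mean across the long fractions) and the
#' transcript's total-expression log2 fold change (WT vs mut). A positive
#' correlation indicates that polyadenylated transcripts are also
#' stabilised.
#'
#' @param fit A [polyafit()] object.
#' @param expression Optional named vector of log2 fold changes; defaults
#'   to [expression_log2fc()] on the fit.
#' @return List of class `"expression_coupling"`: `rho`, `p`, `n`,
#'   `reliable` (`FALSE`, with a warning, below 10 hits).
#' @export
expression_coupling <- function(fit, expression = NULL) {
  stopifnot(inherits(fit, "polyafit"))
  if (is.null(expression)) expression <- expression_log2fc(fit)
  tab <- fit$table
  sel <- tab$combined_hit
  n <- sum(sel)
  reliable <- n >= 10
  if (!reliable)
    warning("fewer than 10 combined hits; coupling estimate flagged unreliable")
  rcols <- paste0("log2_ratio_f", names(fit$null))
  r <- rowMeans(as.matrix(tab[rcols]))
  e <- expression[tab$transcript_id]
  if (n >= 2) {
    ct <- suppressWarnings(stats::cor.test(r[sel], e[sel], method = "spearman",
                                           exact = FALSE))
    rho <- unname(ct$estimate); p <- ct$p.value
  } else {
    rho <- NA_real_; p <- NA_real_
  }
  structure(list(rho = rho, p = p, n = n, reliable = reliable),
            class = "expression_coupling")
}

#' @export
print.expression_coupling <- function(x, ...) {
  cat(sprintf("polyadenylation-expression coupling: Spearman rho = %.3f (p = %.3g, n = %d%s)\n",
              x$rho, x$p, x$n, if (x$reliable) "" else "; unreliable"))
  invisible(x)
}

#' Hypergeometric enrichment of a transcript label among hits
#'
#' Generic label (e.g. functional category) over-representation test for a
#' hit set against a tested universe — a transparent stand-in for web-based
#' functional annotation clustering.
#'
#' @param hits Character vector of hit ids.
#' @param labelled Character vector of ids carrying the label.
#' @param universe All tested ids.
#' @return List with counts and the hypergeometric upper-tail `p`.
#' @export
label_enrichment <- function(hits, labelled, universe) {
  cmp <- compare_hit_sets(hits, intersect(labelled, universe), universe)
  list(n_hits = cmp$n_a, n_labelled = cmp$n_b, n_overlap = cmp$n_overlap,
       n_universe = cmp$n_universe, p = cmp$hypergeometric_p)
}
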