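#' Fraction count matrix container
#'
#' Validated container for fractionation-seq counts: a non-negative integer
#' matrix (rows = transcripts including spike-ins, columns = libraries) plus
#' a sample sheet mapping each library to its condition (`WT`/`mut`),
#' fraction (1..6) and replicate, and a spike-in flag per row.
#'
#' @param counts Integer matrix of counts; row names are transcript ids,
#'   column names library ids.
#' @param samples Data frame with columns `library_id`, `condition`,
#'   `fraction`, `replicate` covering every count column.
#' @param is_spikein Logical vector (one per row) flagging spike-in rows;
#'   defaults to all `FALSE`.
#' @return An object of class `"polya_counts"`.
#' @export
polya_counts <- function(counts, samples, is_spikein = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` needs transcript row names and library column names")
  bad <- which(!is.finite(counts) | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer count at row '%s', column '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative count at row '%s', column '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "integer"
  need <- c("library_id", "condition", "fraction", "replicate")
  if (!all(need %in% names(samples)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  samples$library_id <- as.character(samples$library_id)
  samples$condition <- as.character(samples$condition)
  samples$fraction <- as.integer(samples$fraction)
  bad_cond <- setdiff(unique(samples$condition), c("WT", "mut"))
  if (length(bad_cond))
    stop("unknown condition label(s): ", paste(bad_cond, collapse = ", "))
  if (any(!samples$fraction %in% 1:6))
    stop("fraction labels must be in 1..6")
  missing <- setdiff(colnames(counts), samples$library_id)
  if (length(missing))
    stop("sample sheet missing librar", if (length(missing) > 1) "ies: " else "y: ",
         paste(missing, collapse = ", "))
  samples <- samples[match(colnames(counts), samples$library_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (is.null(is_spikein)) is_spikein <- rep(FALSE, nrow(counts))
  stopifnot(length(is_spikein) == nrow(counts))
  is_spikein <- stats::setNames(as.logical(is_spikein), rownames(counts))
  structure(list(counts = counts, samples = samples, is_spikein = is_spikein),
            class = "polya_counts")
}

#' @export
print.polya_counts <- function(x, ...) {
  cat(sprintf("polya_counts: %d transcripts (%d spike-ins) x %d libraries\n",
              nrow(x$counts), sum(x$is_spikein), ncol(x$counts)))
  cat(sprintf("  conditions: %s; fractions: %s\n",
              paste(unique(x$samples$condition), collapse = ", "),
              paste(sort(unique(x$samples$fraction)), collapse = ", ")))
  invisible(x)
}

#' Read a fraction count matrix and sample sheet from TSV files
#'
#' Lines starting with `#` (provenance headers) are skipped. Counts are
#' validated to be non-negative integers and every count column must appear
#' in the sample sheet.
#'
#' @param counts_path TSV with a `transcript_id` first column and one column
#'   per library.
#' @param samples_path TSV with columns `library_id`, `condition`,
#'   `fraction`, `replicate`.
#' @param spike_pattern Regular expression identifying spike-in rows by
#'   transcript id.
#' @return A [polya_counts()] object.
#' @export
read_counts <- function(counts_path, samples_path,
                        spike_pattern = "^(SPIKE|ERCC)") {
  raw <- read_tsv(counts_path)
  if (names(raw)[1] != "transcript_id")
    stop("first column of the counts table must be 'transcript_id'")
  mat <- as.matrix(raw[, -1, drop = FALSE])
  rownames(mat) <- raw$transcript_id
  samples <- read_tsv(samples_path)
  polya_counts(mat, samples, grepl(spike_pattern, rownames(mat)))
}

#' Write a simulated experiment to plain-text files
#'
#' Emits `counts.tsv`, `samples.tsv`, `annotation.tsv` and (when sequences
#' were generated) `utr3.fasta` into `dir`. TSVs carry a `#` provenance
#' header with package version, seed and configuration hash.
#'
#' @param sim A `"polya_sim"` object from [simulate_fractionation()].
#' @param dir Output directory, created if absent.
#' @return Invisibly, the paths written.
#' @export
write_experiment <- function(sim, dir) {
  stopifnot(inherits(sim, "polya_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- sim$truth$config$seed
  extra <- paste0("config=", config_hash(sim$truth$config))
  cdf <- data.frame(transcript_id = rownames(sim$counts$counts),
                    sim$counts$counts, check.names = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             annotation = file.path(dir, "annotation.tsv"))
  write_tsv(cdf, paths["counts"], seed, extra)
  write_tsv(sim$counts$samples, paths["samples"], seed, extra)
  write_tsv(sim$annotation, paths["annotation"], seed, extra)
  if (!is.null(sim$utr3)) {
    fa <- file.path(dir, "utr3.fasta")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$utr3), fa)
    paths <- c(paths, utr3 = fa)
  }
  invisible(paths)
}

#' Read 3'-UTR sequences from a FASTA file
#'
#' @param path FASTA path; headers are transcript ids.
#' @return A named character vector of DNA sequences.
#' @export
read_utr_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
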