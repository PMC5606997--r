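# internal helpers shared across modules

# deterministic sub-stream seeds derived from one master seed; kept < 2^31
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 1000003) * 1009 + index * 7919) %% 2147483629L
}

# small rolling hash for provenance headers (not cryptographic)
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = " ")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

dna_to_rna <- function(x) chartr("Tt", "Uu", x)
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

# i.i.d. uniform ACGT sequences, one string per requested length
random_dna <- function(lengths) {
  stopifnot(all(lengths > 0))
  chars <- sample(c("A", "C", "G", "T"), sum(lengths), replace = TRUE)
  idx <- rep.int(seq_along(lengths), lengths)
  unname(vapply(split(chars, idx), paste0, character(1), collapse = ""))
}

provenance_lines <- function(seed, extra = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("polyafrac")),
                  error = function(e) "dev")
  c(sprintf("# polyafrac %s; seed=%s%s", ver, format(seed),
            if (is.null(extra)) "" else paste0("; ", extra)))
}

write_tsv <- function(df, path, seed = NULL, extra = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(provenance_lines(seed, extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}
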