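# Internal helpers shared across modules.

# Lightweight structured logging: every filtering decision is reported via
# message() with a stage tag so runs are auditable (and silenceable with
# suppressMessages()).
log_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Reverse complement of DNA sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] operating
#' on plain character vectors in the DNA alphabet.
#'
#' @param x character vector of DNA sequences (`ACGTN`).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Normalise a nucleotide string to the internal alphabet: DNA uppercase,
# U -> T. RNA is accepted on input; one alphabet simplifies matching.
normalize_seq <- function(x) {
  chartr("U", "T", toupper(x))
}

# Validate normalised sequences; err_label names the offending record.
check_alphabet <- function(seqs, ids, context = "sequence") {
  if (any(!nzchar(seqs))) {
    stop(sprintf("empty %s for id '%s'", context, ids[!nzchar(seqs)][1]),
         call. = FALSE)
  }
  pos <- regexpr("[^ACGTN]", seqs)
  bad <- which(pos > 0L)
  if (length(bad) > 0L) {
    i <- bad[1]
    stop(sprintf(
      "invalid character '%s' at position %d of %s '%s' (allowed: ACGTUN)",
      substr(seqs[i], pos[i], pos[i]), pos[i], context, ids[i]), call. = FALSE)
  }
  invisible(TRUE)
}

# Row means/variances of a matrix ignoring NAs (used on small rank matrices).
row_moments <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  v <- rowSums((m - mu)^2, na.rm = TRUE) / pmax(n - 1L, 1L)
  v[n < 2L] <- NA_real_
  list(mean = mu, var = v, n = n)
}

# Provenance header written at the top of every output TSV.
provenance_line <- function(params = list(), seed = NULL) {
  ver <- as.character(utils::packageVersion("mirisc"))
  kv <- c(
    sprintf("mirisc=%s", ver),
    if (!is.null(seed)) sprintf("seed=%s", seed),
    if (length(params)) sprintf("%s=%s", names(params),
                                vapply(params, format, character(1)))
  )
  paste0("# ", paste(kv, collapse = " "))
}

# Strict TSV writer: no quoting, "." decimal, one "#" provenance line on top.
write_tsv_report <- function(df, path, params = list(), seed = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_line(params, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_tsv_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
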