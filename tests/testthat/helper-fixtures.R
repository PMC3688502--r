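# Shared fixture builders; everything is generated in code at test time.

tmp_file <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

small_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_mirnas = 40, n_genes = 200, frac_targets = 0.1,
               utr_len_meanlog = log(120))
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# naive per-position 7-mer match counter: the independent oracle for
# count_matches
naive_count <- function(utr, sites) {
  total <- 0L
  for (s in unique(sites)) {
    w <- nchar(s)
    if (nchar(utr) < w) next
    for (i in seq_len(nchar(utr) - w + 1L)) {
      if (substr(utr, i, i + w - 1L) == s) total <- total + 1L
    }
  }
  total
}

# exhaustive hypergeometric upper tail by enumeration over all draws of B
# from the universe (feasible for |U| <= 12)
enum_hyper_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  special <- seq_len(K)
  overlap <- apply(draws, 2L, function(d) sum(d %in% special))
  mean(overlap >= k)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
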