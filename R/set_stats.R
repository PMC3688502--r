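# set_stats: gene-set overlap and percent-rank comparison statistics.
# Over-representation p-values are upper-tail hypergeometric probabilities
# including the observed count, P(X >= k).

#' Hypergeometric overlap of two gene sets within a universe
#'
#' Members outside the universe are dropped (with a logged count) before
#' testing. With `k = |A intersect B|`, the p-value is `P(X >= k)` for `X ~
#' Hypergeometric(N = |U|, K = |A|, n = |B|)` and the expected overlap is
#' `|A||B|/|U|`.
#'
#' @param set_a,set_b [gene_set()] objects (or character vectors).
#' @param universe [gene_set()] (or character vector) of all eligible genes.
#' @return one-row data.frame: `set_a`, `set_b`, `universe_n`, `n_a`, `n_b`,
#'   `observed_k`, `expected`, `percent_of_a`, `p`.
#' @examples
#' hypergeom_overlap(gene_set("A", letters[1:4]), gene_set("B", letters[1:5]),
#'                   gene_set("U", letters[1:10]))
#' @export
hypergeom_overlap <- function(set_a, set_b, universe) {
  as_set <- function(x, nm) if (inherits(x, "gene_set")) x else gene_set(nm, x)
  A <- as_set(set_a, "A"); B <- as_set(set_b, "B"); U <- as_set(universe, "U")
  if (length(U$members) == 0L) stop("empty universe", call. = FALSE)
  clip <- function(s) {
    inside <- s$members %in% U$members
    if (any(!inside)) {
      log_msg("overlap", "set '%s': dropped %d member(s) outside the universe",
              s$name, sum(!inside))
    }
    s$members[inside]
  }
  a <- clip(A); b <- clip(B)
  N <- length(U$members); na <- length(a); nb <- length(b)
  k <- length(intersect(a, b))
  p <- stats::phyper(k - 1L, na, N - na, nb, lower.tail = FALSE)
  data.frame(set_a = A$name, set_b = B$name, universe_n = N,
             n_a = na, n_b = nb, observed_k = k,
             expected = na * nb / N,
             percent_of_a = if (na > 0L) 100 * k / na else NA_real_,
             p = p, stringsAsFactors = FALSE)
}

#' Mean percent-rank comparison of a gene set against all testable genes
#'
#' Two-sided two-sample Student's t-test (pooled variance) of the set
#' members' mean percent ranks versus the ranks of all testable genes.
#'
#' @param set_a [gene_set()] (or character vector) of genes of interest.
#' @param ranks named numeric vector: mean percent rank per testable gene.
#' @return list with `mean_a`, `mean_bg`, `n_a`, `n_bg`, `p`.
#' @export
mean_rank_comparison <- function(set_a, ranks) {
  members <- if (inherits(set_a, "gene_set")) set_a$members else
    unique(as.character(set_a))
  stopifnot(!is.null(names(ranks)))
  ranks <- ranks[!is.na(ranks)]
  a <- ranks[names(ranks) %in% members]
  if (length(a) < 2L) {
    stop("need >= 2 testable set members for the rank comparison",
         call. = FALSE)
  }
  res <- stats::t.test(a, ranks, var.equal = TRUE)
  list(mean_a = mean(a), mean_bg = mean(ranks),
       n_a = length(a), n_bg = length(ranks), p = res$p.value)
}

#' Hypergeometric test of the fraction of genes carrying a seed site
#'
#' Tests whether the number of set genes with at least one perfect 7-mer site
#' exceeds expectation given the universe-wide fraction: `p = P(X >= k_a)`,
#' `X ~ Hypergeometric(N = n_u, K = k_u, n = n_a)`.
#'
#' @param k_a set genes with at least one site.
#' @param n_a set size.
#' @param k_u universe genes with at least one site.
#' @param n_u universe size.
#' @return upper-tail p-value.
#' @export
frac_with_site_test <- function(k_a, n_a, k_u, n_u) {
  if (!(k_a <= n_a && n_a <= n_u && k_a <= k_u && k_u <= n_u) ||
      any(c(k_a, n_a, k_u, n_u) < 0)) {
    stop("inconsistent counts: need k_a <= n_a <= n_u and k_a <= k_u <= n_u",
         call. = FALSE)
  }
  stats::phyper(k_a - 1L, k_u, n_u - k_u, n_a, lower.tail = FALSE)
}

#' Overlap report across several gene sets
#'
#' @param sets named list of [gene_set()] objects compared against `set_a`.
#' @param set_a the focal [gene_set()].
#' @param universe the shared universe [gene_set()].
#' @return data.frame with one row per comparison.
#' @export
overlap_report <- function(set_a, sets, universe) {
  do.call(rbind, lapply(sets, hypergeom_overlap, set_a = set_a,
                        universe = universe))
}
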