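# mirna_enrichment: per-miRNA IP-vs-Total enrichment from small-RNA read
# counts. Counts are converted to relative concentrations (read fractions),
# normalised to the lowest relative concentration observed anywhere in the
# analysis, log2-transformed, and compared between fractions with a
# two-sample Student's t-test per miRNA.

#' Relative concentration of miRNAs within one library
#'
#' The relative concentration of a miRNA is its read count divided by the
#' total reads of the library, after adding `pseudocount` to every count.
#' The pseudocount (default 0 here; the pipeline default is 0.5) keeps zero
#' counts representable on the log scale.
#'
#' @param counts named numeric vector of non-negative read counts.
#' @param pseudocount non-negative value added to every count first.
#' @return named vector of fractions summing to 1.
#' @export
relative_concentration <- function(counts, pseudocount = 0) {
  stopifnot(length(counts) >= 1L, pseudocount >= 0, all(counts >= 0))
  x <- counts + pseudocount
  tot <- sum(x)
  if (tot <= 0) {
    stop("all-zero library with pseudocount = 0: relative concentration undefined",
         call. = FALSE)
  }
  x / tot
}

#' Relative abundance: normalise to the lowest relative concentration
#'
#' Every relative concentration is divided by the global minimum entry of the
#' whole miRNA x library matrix and expressed in log2, so all libraries share
#' one scale and the minimum entry maps to exactly 0.
#'
#' @param rel_conc numeric matrix (miRNA x library) of positive fractions.
#' @return matrix of log2 relative abundances with attributes `min_ref` (the
#'   linear-scale normaliser) and `pseudocount` if present on the input.
#' @export
relative_abundance <- function(rel_conc) {
  stopifnot(is.matrix(rel_conc))
  if (any(rel_conc <= 0)) {
    stop("nonpositive relative concentration; use a pseudocount", call. = FALSE)
  }
  min_ref <- min(rel_conc)
  out <- log2(rel_conc / min_ref)
  attr(out, "min_ref") <- min_ref
  out
}

# Vectorised two-sample t over matrix rows (ip | total blocks).
# var_equal = TRUE: Student's pooled-variance form; FALSE: Welch.
row_t_test <- function(ip, total, var_equal = TRUE) {
  n1 <- ncol(ip); n2 <- ncol(total)
  m1 <- rowMeans(ip); m2 <- rowMeans(total)
  v1 <- rowSums((ip - m1)^2) / (n1 - 1L)
  v2 <- rowSums((total - m2)^2) / (n2 - 1L)
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2L, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # degenerate rows: zero variance in both groups
  degen <- se == 0
  p[degen & m1 == m2] <- 1          # identical constants: no evidence
  p[degen & m1 != m2] <- 0          # limit of |t| -> Inf
  list(t = tstat, df = df, p = p, mean_ip = m1, mean_total = m2)
}

#' Enrichment test for a single miRNA
#'
#' Two-sided two-sample Student's t-test (pooled variance by default) on log2
#' relative abundances, with the call assigned at `alpha`: `enriched` when the
#' IP mean exceeds the Total mean at p < alpha, `depleted` for the opposite
#' direction, `neither` otherwise.
#'
#' @param ip,total numeric vectors of per-replicate log2 relative abundances
#'   (at least 2 values each).
#' @param alpha significance level for the call.
#' @param var_equal use the pooled-variance Student form (default) or Welch.
#' @param mirna optional id carried into the record.
#' @return list with `mirna`, `mean_ip`, `mean_total`, `delta` (log2 fold,
#'   IP vs Total), `t`, `df`, `p`, `call`.
#' @export
enrichment_test <- function(ip, total, alpha = 0.01, var_equal = TRUE,
                            mirna = NA_character_) {
  if (length(ip) < 2L || length(total) < 2L) {
    stop("need >= 2 replicates per fraction", call. = FALSE)
  }
  res <- row_t_test(matrix(ip, nrow = 1L), matrix(total, nrow = 1L),
                    var_equal = var_equal)
  delta <- res$mean_ip - res$mean_total
  call <- "neither"
  if (is.finite(res$p) && res$p < alpha) {
    call <- if (delta > 0) "enriched" else if (delta < 0) "depleted" else "neither"
  }
  list(mirna = mirna, mean_ip = res$mean_ip, mean_total = res$mean_total,
       delta = delta, t = res$t, df = res$df, p = res$p, call = call)
}

#' Linear fold change of an enrichment record
#'
#' Returns `2^delta`. Depletion (`delta < 0`) is conventionally reported as a
#' `2^-delta`-fold depletion; [format_fold()] renders that wording.
#'
#' @param x an enrichment record (list with `delta`) or a numeric `delta`.
#' @return linear fold (IP vs Total).
#' @export
fold_change <- function(x) {
  delta <- if (is.list(x)) x$delta else x
  2^delta
}

#' Human-readable fold change
#'
#' @param x an enrichment record or numeric log2 fold.
#' @param digits significant digits.
#' @return string such as `"2-fold enriched"` or `"19-fold depleted"`.
#' @export
format_fold <- function(x, digits = 3) {
  delta <- if (is.list(x)) x$delta else x
  if (delta < 0) {
    sprintf("%s-fold depleted", signif(2^-delta, digits))
  } else {
    sprintf("%s-fold enriched", signif(2^delta, digits))
  }
}

#' miRNA IP-vs-Total enrichment analysis
#'
#' The full small-RNA stage: read fractions per library (with pseudocount),
#' global normalisation to the lowest relative concentration, log2 transform,
#' and a per-miRNA two-sample t-test of IP versus Total replicates. Raw
#' p-values are thresholded at `alpha` (no multiple-testing correction,
#' matching the raw-p convention of IP screens); a Benjamini-Hochberg FDR
#' column is included for information.
#'
#' @param counts a [mirna_counts()] matrix (or coercible numeric matrix with
#'   `IP_<r>` / `TOTAL_<r>` columns).
#' @param pseudocount added to every count before the read fraction
#'   (default 0.5).
#' @param alpha significance level of the enriched/depleted calls.
#' @param var_equal pooled-variance Student's t (default) or Welch.
#' @return object of class `mirna_enrichment`: list with `table` (one row per
#'   miRNA: `mirna`, `mean_ip`, `mean_total`, `delta_log2`, `fold_linear`,
#'   `p`, `bh_fdr`, `call`), the log2 `abundance` matrix, and the parameters.
#' @examples
#' sim <- gen_mirna_counts(sim_config(seed = 7, n_mirnas = 50))
#' fit <- mirna_enrichment(sim$counts)
#' fit
#' head(as.data.frame(fit))
#' @export
mirna_enrichment <- function(counts, pseudocount = 0.5, alpha = 0.01,
                             var_equal = TRUE) {
  if (!inherits(counts, "mirna_counts")) counts <- mirna_counts(as.matrix(counts))
  libs <- colnames(counts)
  rc <- apply(unclass(counts), 2L, relative_concentration,
              pseudocount = pseudocount)
  ab <- relative_abundance(rc)
  ip_cols <- grepl("^IP_", libs)
  res <- row_t_test(ab[, ip_cols, drop = FALSE],
                    ab[, !ip_cols, drop = FALSE], var_equal = var_equal)
  delta <- res$mean_ip - res$mean_total
  call <- rep("neither", nrow(counts))
  sig <- is.finite(res$p) & res$p < alpha
  call[sig & delta > 0] <- "enriched"
  call[sig & delta < 0] <- "depleted"
  tab <- data.frame(
    mirna = rownames(counts),
    mean_ip = res$mean_ip, mean_total = res$mean_total,
    delta_log2 = delta, fold_linear = 2^delta,
    p = res$p, bh_fdr = stats::p.adjust(res$p, method = "BH"),
    call = call, stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, abundance = ab, alpha = alpha,
                 pseudocount = pseudocount, var_equal = var_equal,
                 n_replicates = sum(ip_cols)),
            class = "mirna_enrichment")
}

#' @export
print.mirna_enrichment <- function(x, ...) {
  n <- table(factor(x$table$call, levels = c("enriched", "depleted", "neither")))
  cat(sprintf("miRNA IP-vs-Total enrichment (%d miRNAs, %d replicates/fraction)\n",
              nrow(x$table), x$n_replicates))
  cat(sprintf("  Student's t (%s), alpha = %g, pseudocount = %g\n",
              if (x$var_equal) "pooled variance" else "Welch", x$alpha,
              x$pseudocount))
  cat(sprintf("  enriched: %d   depleted: %d   neither: %d\n",
              n[["enriched"]], n[["depleted"]], n[["neither"]]))
  invisible(x)
}

#' @export
summary.mirna_enrichment <- function(object, ...) {
  print(object)
  tab <- object$table
  top <- tab[order(tab$p), ]
  top <- top[top$call != "neither", , drop = FALSE]
  if (nrow(top) > 0L) {
    cat("\ntop calls:\n")
    show <- utils::head(top, 10L)
    show$fold <- vapply(show$delta_log2, format_fold, character(1))
    print(show[, c("mirna", "delta_log2", "fold", "p", "bh_fdr", "call")],
          row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' @export
as.data.frame.mirna_enrichment <- function(x, ...) x$table

#' @export
coef.mirna_enrichment <- function(object, ...) {
  stats::setNames(object$table$delta_log2, object$table$mirna)
}

#' @export
plot.mirna_enrichment <- function(x, ...) {
  tab <- x$table
  col <- c(enriched = "firebrick", depleted = "steelblue", neither = "grey60")
  graphics::plot(tab$delta_log2, -log10(tab$p),
                 col = col[tab$call], pch = 19, cex = 0.6,
                 xlab = expression(log[2] ~ "fold (IP vs Total)"),
                 ylab = expression(-log[10] ~ p), ...)
  graphics::abline(h = -log10(x$alpha), lty = 2, col = "grey40")
  invisible(x)
}

#' Write the per-miRNA enrichment table as TSV
#'
#' @param fit a `mirna_enrichment` object.
#' @param path output path.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_mirna_enrichment <- function(fit, path, seed = NULL) {
  write_tsv_report(fit$table, path,
                   params = list(alpha = fit$alpha,
                                 pseudocount = fit$pseudocount),
                   seed = seed)
}
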