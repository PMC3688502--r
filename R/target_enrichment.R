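# target_enrichment: miRISC-associated mRNAs from IP/Total microarray signal.
# Per replicate, IP/Total ratios of that replicate's reliably detected probes
# are converted to percent ranks; probes reliable in >= min_reliable
# replicates are "testable"; each probe's ranks are compared to the pooled
# ranks of all testable probes by a one-tailed t-test; probes collapse to
# genes by minimum p; a single-probe-per-gene replicate from a second
# platform is merged in and significance recomputed.

#' Testable entities from detection flags
#'
#' An entity is testable when it carries a reliable signal (in both IP and
#' Total channels) in at least `min_reliable` replicates.
#'
#' @param det_ip,det_total logical entity x replicate detection matrices.
#' @param min_reliable minimum number of reliable replicates (default 2).
#' @return logical vector, `TRUE` for testable entities.
#' @export
testable_entities <- function(det_ip, det_total = det_ip, min_reliable = 2L) {
  stopifnot(ncol(as.matrix(det_ip)) >= 1L)
  det <- as.matrix(det_ip) & as.matrix(det_total)
  rowSums(det, na.rm = TRUE) >= min_reliable
}

#' Percent ranks of IP/Total ratios within one replicate
#'
#' Ranks (1 = smallest, average ranks for ties) mapped to `(r - 0.5)/n`. The
#' transform is symmetric, avoids the 0/1 endpoints, and has mean exactly 0.5
#' for complete data.
#'
#' @param ratios vector of at least 2 finite positive IP/Total ratios.
#' @return vector of percent ranks strictly inside (0, 1).
#' @export
percent_rank <- function(ratios) {
  if (length(ratios) < 2L) stop("need >= 2 ratios to rank", call. = FALSE)
  if (any(!is.finite(ratios) | ratios <= 0)) {
    stop("ratios must be finite and positive", call. = FALSE)
  }
  (rank(ratios, ties.method = "average") - 0.5) / length(ratios)
}

# One-tailed (entity > background) Welch p for each row of a rank matrix
# against precomputed background moments. Rows with < 2 values get NA.
welch_greater_p <- function(rank_mat, bg_mean, bg_var, bg_n) {
  mom <- row_moments(rank_mat)
  se2 <- mom$var / mom$n + bg_var / bg_n
  tstat <- (mom$mean - bg_mean) / sqrt(se2)
  df <- se2^2 / ((mom$var / mom$n)^2 / pmax(mom$n - 1L, 1L) +
                   (bg_var / bg_n)^2 / (bg_n - 1L))
  p <- stats::pt(tstat, df, lower.tail = FALSE)
  # zero-variance entities are handled by the formula itself: the Welch se
  # collapses to the background term and df to bg_n - 1
  p[mom$n < 2L] <- NA_real_
  list(p = p, mean = mom$mean, n = mom$n)
}

#' One-tailed t-test of one entity's ranks against the testable background
#'
#' Welch two-sample t-test with alternative "entity mean greater than
#' background mean" (IP association is enrichment).
#'
#' @param entity_ranks the entity's per-replicate percent ranks (>= 2 values,
#'   `NA` allowed and dropped).
#' @param background_ranks pooled percent ranks of all testable entities.
#' @return one-tailed p-value.
#' @export
gene_pvalue <- function(entity_ranks, background_ranks) {
  x <- entity_ranks[!is.na(entity_ranks)]
  if (length(x) < 2L) stop("entity needs >= 2 rank values", call. = FALSE)
  bg <- background_ranks[!is.na(background_ranks)]
  welch_greater_p(matrix(x, nrow = 1L), mean(bg), stats::var(bg),
                  length(bg))$p
}

#' Collapse probe-level records to one record per gene
#'
#' Among a gene's probes (across its transcripts), the probe with the lowest
#' p-value wins; ties are broken by larger mean percent rank, then by
#' lexicographic probe id. Percent ranks are not altered by the filtering.
#'
#' @param records data.frame with columns `probe`, `transcript`, `gene`,
#'   `p`, `mean_rank`, plus any rank columns to carry along.
#' @return the winning rows, one per gene, ordered by gene id.
#' @export
collapse_probes <- function(records) {
  stopifnot(all(c("probe", "gene", "p", "mean_rank") %in% names(records)))
  keep <- !is.na(records$gene) & nzchar(records$gene)
  if (any(!keep)) {
    log_msg("target", "excluded %d unmapped probe(s)", sum(!keep))
    records <- records[keep, , drop = FALSE]
  }
  o <- order(records$gene, records$p, -records$mean_rank, records$probe)
  records <- records[o, , drop = FALSE]
  out <- records[!duplicated(records$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge a single-probe-per-gene platform into gene records
#'
#' For genes present on both platforms the extra percent rank is appended and
#' the one-tailed p-value recomputed over the extended rank vector; genes
#' absent from the extra platform keep their original p. Extra-platform genes
#' missing from the primary records carry a single value, cannot be tested,
#' and are dropped with a log entry.
#'
#' @param records collapsed per-gene data.frame with rank columns `r1..rK`,
#'   `mean_rank` and `p`.
#' @param p2_ranks named numeric vector: percent rank per gene on the extra
#'   platform.
#' @param background_ranks pooled background rank vector used for the
#'   recomputation.
#' @return `records` with columns `r<K+1>`, updated `mean_rank`, `p`.
#' @export
merge_platform <- function(records, p2_ranks, background_ranks) {
  rank_cols <- grep("^r[0-9]+$", names(records), value = TRUE)
  newcol <- sprintf("r%d", length(rank_cols) + 1L)
  records[[newcol]] <- unname(p2_ranks[records$gene])
  orphan <- setdiff(names(p2_ranks), records$gene)
  if (length(orphan) > 0L) {
    log_msg("target",
            "%d extra-platform gene(s) absent from primary platform dropped (single value, untestable)",
            length(orphan))
  }
  rank_mat <- as.matrix(records[, c(rank_cols, newcol), drop = FALSE])
  bg <- background_ranks[!is.na(background_ranks)]
  res <- welch_greater_p(rank_mat, mean(bg), stats::var(bg), length(bg))
  upd <- !is.na(records[[newcol]])
  records$mean_rank[upd] <- res$mean[upd]
  records$p[upd] <- res$p[upd]
  records
}

#' Call IP-enriched genes
#'
#' @param records per-gene data.frame with a `p` column.
#' @param alpha significance level; the inequality is strict (`p < alpha`).
#' @return character vector of enriched gene ids.
#' @export
call_enriched <- function(records, alpha = 0.001) {
  genes <- records$gene[!is.na(records$p) & records$p < alpha]
  log_msg("target", "%d of %d testable genes enriched at p < %g",
          length(genes), nrow(records), alpha)
  genes
}

#' Microarray IP/Total target-enrichment analysis
#'
#' The full array stage. Primary-platform replicates are processed first:
#' detection flags define each replicate's reliable probes, IP/Total ratios of
#' those probes are percent-ranked within the replicate, probes reliable in at
#' least `min_reliable` replicates are testable, and each testable probe's
#' ranks are tested one-tailed against the pooled ranks of all testable
#' probes. Probes then collapse to genes by minimum p. Finally the extra
#' platform's single-probe percent ranks are appended per gene and
#' significance recomputed.
#'
#' @param signals a [probe_signal()] object.
#' @param alpha significance level for the enriched call (strict `<`).
#' @param min_reliable replicates of reliable signal required for testability.
#' @param p2_in_background also pool the extra platform's ranks into the
#'   background used for the recomputation (default TRUE).
#' @return object of class `target_enrichment`: list with `genes` (one row
#'   per testable gene: `gene`, `chosen_probe`, `chosen_transcript`,
#'   `r1..rK`, `mean_rank`, `p`, `enriched`), `n_testable_probes`,
#'   `background_mean` and parameters.
#' @examples
#' sim <- gen_microarray(sim_config(seed = 3, n_genes = 400, frac_targets = 0.05))
#' fit <- target_enrichment(sim$signals)
#' fit
#' @export
target_enrichment <- function(signals, alpha = 0.001, min_reliable = 2L,
                              p2_in_background = TRUE) {
  stopifnot(inherits(signals, "probe_signal"))
  p1 <- which(signals$platform == "P1")
  p2 <- which(signals$platform != "P1")
  det <- signals$det_ip & signals$det_total &
    !is.na(signals$ip) & !is.na(signals$total)
  ratio <- signals$ip / signals$total

  # percent ranks per primary replicate over that replicate's reliable probes
  ranks <- matrix(NA_real_, nrow(ratio), ncol(ratio))
  for (r in c(p1, p2)) {
    idx <- which(det[, r] & is.finite(ratio[, r]) & ratio[, r] > 0)
    if (length(idx) >= 2L) ranks[idx, r] <- percent_rank(ratio[idx, r])
  }

  testable <- testable_entities(signals$det_ip[, p1, drop = FALSE],
                                signals$det_total[, p1, drop = FALSE],
                                min_reliable = min_reliable)
  prow <- platform_row(signals)
  log_msg("target", "%d of %d primary-platform probes testable (>= %d reliable replicates)",
          sum(testable & prow == "P1"), sum(prow == "P1"), min_reliable)

  prim <- testable & prow == "P1"
  if (!any(prim)) {
    log_msg("target", "no testable probes; empty result")
    empty <- data.frame(gene = character(0), chosen_probe = character(0),
                        chosen_transcript = character(0),
                        mean_rank = numeric(0), p = numeric(0),
                        enriched = logical(0), stringsAsFactors = FALSE)
    return(structure(list(genes = empty, alpha = alpha,
                          min_reliable = min_reliable,
                          n_testable_probes = 0L,
                          background_mean = NA_real_,
                          p2_in_background = p2_in_background),
                     class = "target_enrichment"))
  }
  rank1 <- ranks[prim, p1, drop = FALSE]
  colnames(rank1) <- sprintf("r%d", seq_along(p1))
  bg1 <- as.vector(rank1)
  res1 <- welch_greater_p(rank1, mean(bg1, na.rm = TRUE),
                          stats::var(bg1, na.rm = TRUE), sum(!is.na(bg1)))
  records <- data.frame(signals$info[prim, c("probe", "transcript", "gene")],
                        rank1, mean_rank = res1$mean, p = res1$p,
                        stringsAsFactors = FALSE)
  droppable <- res1$n < 2L
  if (any(droppable)) {
    log_msg("target", "dropped %d testable probe(s) with < 2 rank values",
            sum(droppable))
    records <- records[!droppable, , drop = FALSE]
  }
  genes <- collapse_probes(records)
  names(genes)[names(genes) == "probe"] <- "chosen_probe"
  names(genes)[names(genes) == "transcript"] <- "chosen_transcript"

  if (length(p2) > 0L) {
    for (r in p2) {
      p2_ok <- which(!is.na(ranks[, r]))
      p2_ranks <- stats::setNames(ranks[p2_ok, r], signals$info$gene[p2_ok])
      bg <- if (p2_in_background) c(bg1, unname(p2_ranks)) else bg1
      genes <- merge_platform(genes, p2_ranks, bg)
    }
  }
  genes$enriched <- !is.na(genes$p) & genes$p < alpha
  genes <- genes[order(genes$gene), , drop = FALSE]
  first <- c("gene", "chosen_probe", "chosen_transcript")
  genes <- genes[, c(first, setdiff(names(genes), first)), drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genes = genes, alpha = alpha, min_reliable = min_reliable,
                 n_testable_probes = nrow(records),
                 background_mean = mean(bg1, na.rm = TRUE),
                 p2_in_background = p2_in_background),
            class = "target_enrichment")
}

# platform label per probe row (P1 probes have data only in P1 columns)
platform_row <- function(ps) {
  p1 <- which(ps$platform == "P1")
  ifelse(rowSums(!is.na(ps$ip[, p1, drop = FALSE])) > 0L, "P1", "P2")
}

#' @export
print.target_enrichment <- function(x, ...) {
  cat(sprintf("IP/Total percent-rank target enrichment\n"))
  cat(sprintf("  %d testable genes (%d testable probes), background mean rank %.3f\n",
              nrow(x$genes), x$n_testable_probes, x$background_mean))
  cat(sprintf("  %d genes enriched at p < %g (one-tailed Welch t vs pooled background)\n",
              sum(x$genes$enriched), x$alpha))
  invisible(x)
}

#' @export
summary.target_enrichment <- function(object, ...) {
  print(object)
  top <- object$genes[order(object$genes$p), ]
  cat("\ntop genes:\n")
  print(utils::head(top[, c("gene", "chosen_probe", "mean_rank", "p", "enriched")], 10L),
        row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
as.data.frame.target_enrichment <- function(x, ...) x$genes

#' Write the per-gene target-enrichment table as TSV
#'
#' @param fit a `target_enrichment` object.
#' @param path output path.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_target_enrichment <- function(fit, path, seed = NULL) {
  write_tsv_report(fit$genes, path,
                   params = list(alpha = fit$alpha,
                                 min_reliable = fit$min_reliable),
                   seed = seed)
}
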