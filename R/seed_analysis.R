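# seed_analysis: perfect 7-mer miRNA seed sites (nucleotides 2-8) in 3'UTR
# sets. A site is the UTR-strand sequence exactly complementary to miRNA
# nt 2-8; the control is the reverse complement of the site. Densities are
# matches per 1000 nt of UTR, reported relative to a reference set, and the
# UTR-length comparison is a Mood's median test on a fixed quantile grid.

#' Perfect 7-mer seed site of a miRNA
#'
#' Extracts nucleotides 2-8 (1-based, 5'->3') of the mature sequence and
#' returns their reverse complement in the DNA alphabet: the sequence a 3'UTR
#' must contain for a perfect 7-mer match.
#'
#' @param mirna_seq character vector of mature miRNA sequences (RNA or DNA,
#'   length >= 8 nt each).
#' @return character vector of 7-nt DNA site sequences.
#' @examples
#' seed_site("UAAGGCACGCGGUGAAUGCCA")  # "GTGCCTT"
#' @export
seed_site <- function(mirna_seq) {
  s <- normalize_seq(mirna_seq)
  if (any(nchar(s) < 8L)) {
    stop("mature miRNA sequence shorter than 8 nt: cannot extract nt 2-8",
         call. = FALSE)
  }
  revcomp(substr(s, 2L, 8L))
}

#' Control sequence for a seed site
#'
#' The reverse complement of the site string (equivalently, miRNA nt 2-8
#' transcribed to DNA, read 5'->3'). Used as a matched-composition negative
#' control: real target sets should show no excess of control matches.
#'
#' @param site character vector of 7-nt DNA sites.
#' @return character vector of control 7-mers. Applying the function twice
#'   recovers the input.
#' @export
control_site <- function(site) {
  stopifnot(all(nchar(site) == 7L))
  revcomp(site)
}

#' Count perfect site matches in UTR sequences
#'
#' Counts all exact occurrences of any site in each UTR, summed over sites.
#' Overlapping occurrences count; a position matching two distinct sites
#' counts twice; `N` never matches.
#'
#' @param utr_seq character vector of UTR sequences (DNA uppercase).
#' @param sites character vector of 7-nt site sequences (duplicates removed).
#' @return integer vector of match counts, one per UTR.
#' @export
count_matches <- function(utr_seq, sites) {
  sites <- unique(sites)
  subj <- Biostrings::DNAStringSet(utr_seq)
  out <- integer(length(utr_seq))
  for (s in sites) {
    out <- out + Biostrings::vcountPattern(s, subj, fixed = TRUE)
  }
  out
}

# Resolve one UTR per gene: the longest annotated UTR wins (ties by
# lexicographic transcript id for determinism).
longest_utr_per_gene <- function(utrs) {
  stopifnot(all(c("transcript", "gene", "seq") %in% names(utrs)))
  o <- order(utrs$gene, -nchar(utrs$seq), utrs$transcript)
  u <- utrs[o, , drop = FALSE]
  u[!duplicated(u$gene), , drop = FALSE]
}

#' Seed-site density report for a gene set
#'
#' Aggregates perfect 7-mer matches and UTR lengths over a gene set (one UTR
#' per gene: the longest annotated one) and reports density per 1000 nt, the
#' fraction of genes with at least one site, density relative to a reference
#' set, the same quantities for the reverse-complement control sites, and the
#' median UTR length.
#'
#' @param genes a [gene_set()] (or character vector of gene ids).
#' @param utrs data.frame with columns `transcript`, `gene`, `seq`.
#' @param sites character vector of 7-nt seed sites.
#' @param reference a [gene_set()] (or character vector) whose density is the
#'   denominator of `relative_density`; typically all testable genes.
#' @return one-row data.frame: `set_name`, `n_genes`, `total_utr_nt`,
#'   `total_matches`, `density_per_kb`, `frac_with_site`, `relative_density`,
#'   `control_matches`, `control_density_per_kb`, `relative_control_density`,
#'   `median_utr_len`.
#' @export
density_report <- function(genes, utrs, sites, reference) {
  gset <- if (inherits(genes, "gene_set")) genes else gene_set("set", genes)
  rset <- if (inherits(reference, "gene_set")) reference else
    gene_set("reference", reference)
  per_gene <- longest_utr_per_gene(utrs)
  ctrl <- control_site(sites)

  set_stats <- function(members, label) {
    members <- unique(members)
    hit <- members %in% per_gene$gene
    if (any(!hit)) {
      log_msg("seed", "set '%s': %d gene(s) with no UTR excluded", label,
              sum(!hit))
    }
    u <- per_gene[match(members[hit], per_gene$gene), , drop = FALSE]
    if (nrow(u) == 0L) {
      stop("gene set '", label, "' has no genes with UTRs", call. = FALSE)
    }
    n_match <- count_matches(u$seq, sites)
    n_ctrl <- count_matches(u$seq, ctrl)
    lens <- nchar(u$seq)
    list(n = nrow(u), nt = sum(lens), matches = sum(n_match),
         ctrl_matches = sum(n_ctrl),
         frac = mean(n_match >= 1L), median_len = stats::median(lens),
         lens = lens)
  }
  a <- set_stats(gset$members, gset$name)
  r <- set_stats(rset$members, rset$name)
  dens <- function(m, nt) 1000 * m / nt
  data.frame(
    set_name = gset$name,
    n_genes = a$n,
    total_utr_nt = a$nt,
    total_matches = a$matches,
    density_per_kb = dens(a$matches, a$nt),
    frac_with_site = a$frac,
    relative_density = dens(a$matches, a$nt) / dens(r$matches, r$nt),
    control_matches = a$ctrl_matches,
    control_density_per_kb = dens(a$ctrl_matches, a$nt),
    relative_control_density = dens(a$ctrl_matches, a$nt) /
      dens(r$ctrl_matches, r$nt),
    median_utr_len = a$median_len,
    stringsAsFactors = FALSE)
}

#' Seed-site report over several gene sets
#'
#' @param sets list of [gene_set()] objects.
#' @param utrs,sites,reference as in [density_report()].
#' @return data.frame with one row per set (class `seed_report`).
#' @export
seed_report <- function(sets, utrs, sites, reference) {
  rows <- lapply(sets, density_report, utrs = utrs, sites = sites,
                 reference = reference)
  out <- do.call(rbind, rows)
  class(out) <- c("seed_report", class(out))
  out
}

#' Mood's median test of two UTR-length distributions on a quantile grid
#'
#' Each length vector is reduced to `n_points` quantiles at probabilities
#' `i/n_points` (linear interpolation of the empirical distribution function,
#' so a vector of exactly `n_points` values is returned unchanged), then
#' Mood's median test is applied: counts above / not above the grand median
#' of the pooled points form a 2x2 table tested by chi-square (1 df, no
#' continuity correction).
#'
#' @param lengths_a,lengths_b numeric vectors of UTR lengths.
#' @param n_points quantile points per set (default 400, i.e. every 0.25th
#'   percentile).
#' @return list with `median_a`, `median_b` (medians of the full vectors),
#'   `p`, and the 2x2 `table`.
#' @export
median_utr_test <- function(lengths_a, lengths_b, n_points = 400L) {
  stopifnot(length(lengths_a) >= 1L, length(lengths_b) >= 1L)
  grid <- function(x) {
    if (length(x) < n_points) return(sort(x))
    stats::quantile(x, probs = seq_len(n_points) / n_points, type = 4,
                    names = FALSE)
  }
  qa <- grid(lengths_a)
  qb <- grid(lengths_b)
  pooled <- c(qa, qb)
  if (length(unique(pooled)) == 1L) {
    warning("constant lengths: median test degenerate, p = 1")
    return(list(median_a = stats::median(lengths_a),
                median_b = stats::median(lengths_b), p = 1,
                table = NULL))
  }
  gm <- stats::median(pooled)
  tab <- rbind(A = c(above = sum(qa > gm), not_above = sum(qa <= gm)),
               B = c(above = sum(qb > gm), not_above = sum(qb <= gm)))
  p <- if (any(colSums(tab) == 0L)) {
    1  # all points on one side of the grand median: no signal
  } else {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }
  list(median_a = stats::median(lengths_a),
       median_b = stats::median(lengths_b), p = p, table = tab)
}
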