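# synthetic_data: generators emitting inputs with the statistical structure
# the analysis assumes (negative-binomial read counts, log-normal array
# signals, uniform-background UTRs with planted seed sites), plus planted
# ground truth for recovery tests. All randomness flows from one seed;
# each generator draws from a fixed derived stream so stages are reproducible
# independently of call order.

.stream_offsets <- c(mirna_seqs = 11L, counts = 101L, array = 202L, utrs = 303L)

stream_seed <- function(seed, stream) {
  s <- (as.integer(seed) %% 2000000000L) + .stream_offsets[[stream]]
  as.integer(s)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic miRISC-IP experiment. Defaults mirror
#' the design the pipeline targets: four paired IP/Total small-RNA libraries,
#' four same-platform array replicates plus one single-probe-per-gene
#' replicate from a second platform, a miRNA complement of 250, and a gene
#' universe of 17673 with ~4% planted IP-enriched targets.
#'
#' @param seed integer RNG seed; all generator streams derive from it.
#' @param n_mirnas number of miRNA species.
#' @param n_replicates paired IP/Total biological replicates.
#' @param frac_enriched,frac_depleted proportions of miRNAs planted as
#'   IP-enriched / IP-depleted (their sum must be at most 1).
#' @param effect_log2 planted |log2 fold| for affected miRNAs and target genes.
#' @param dispersion negative-binomial dispersion of read counts (0 = Poisson).
#' @param total_reads nominal library depth before per-library scaling.
#' @param n_genes number of genes on the arrays.
#' @param frac_targets proportion of genes planted as miRISC-associated.
#' @param probes_per_gene integer range `c(min, max)` of probes per gene on
#'   platform 1 (platform 2 always has exactly one probe per gene).
#' @param detect_dropout probability that a probe x replicate x channel
#'   detection flag is unreliable.
#' @param n_platform2 number of extra-platform array replicates.
#' @param utr_len_meanlog,utr_len_sdlog log-normal parameters of 3'UTR length
#'   in nucleotides.
#' @param planted_sites_per_target perfect 7-mer seed sites planted in each
#'   target gene's UTR.
#' @param mirna_length length of simulated mature miRNAs.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_mirnas = 250L,
                       n_replicates = 4L,
                       frac_enriched = 0.065,
                       frac_depleted = 0.13,
                       effect_log2 = 2,
                       dispersion = 0.1,
                       total_reads = 5e6,
                       n_genes = 17673L,
                       frac_targets = 0.042,
                       probes_per_gene = c(1L, 3L),
                       detect_dropout = 0.05,
                       n_platform2 = 1L,
                       utr_len_meanlog = log(140),
                       utr_len_sdlog = 0.8,
                       planted_sites_per_target = 2L,
                       mirna_length = 22L) {
  cfg <- list(seed = as.integer(seed), n_mirnas = as.integer(n_mirnas),
              n_replicates = as.integer(n_replicates),
              frac_enriched = frac_enriched, frac_depleted = frac_depleted,
              effect_log2 = effect_log2, dispersion = dispersion,
              total_reads = total_reads, n_genes = as.integer(n_genes),
              frac_targets = frac_targets,
              probes_per_gene = as.integer(probes_per_gene),
              detect_dropout = detect_dropout,
              n_platform2 = as.integer(n_platform2),
              utr_len_meanlog = utr_len_meanlog,
              utr_len_sdlog = utr_len_sdlog,
              planted_sites_per_target = as.integer(planted_sites_per_target),
              mirna_length = as.integer(mirna_length))
  props <- c(cfg$frac_enriched, cfg$frac_depleted, cfg$frac_targets,
             cfg$detect_dropout)
  if (any(props < 0 | props > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$frac_enriched + cfg$frac_depleted > 1) {
    stop("frac_enriched + frac_depleted must be <= 1", call. = FALSE)
  }
  if (cfg$n_mirnas < 1L || cfg$n_genes < 1L || cfg$n_replicates < 2L) {
    stop("counts must be positive (and n_replicates >= 2)", call. = FALSE)
  }
  if (cfg$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (length(cfg$probes_per_gene) != 2L ||
      any(cfg$probes_per_gene < 1L) ||
      cfg$probes_per_gene[1] > cfg$probes_per_gene[2]) {
    stop("probes_per_gene must be an increasing positive range", call. = FALSE)
  }
  if (cfg$mirna_length < 8L) stop("mirna_length must be >= 8", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("simulation config:\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, paste(x[[k]], collapse = " ")))
  invisible(x)
}

#' Simulate mature miRNA sequences
#'
#' Random sequences over ACGT (no attempt at realistic base composition);
#' their only role is to carry distinct seed regions.
#'
#' @param config a [sim_config()].
#' @return data.frame of sequence records (`id`, `seq`, `desc`).
#' @export
gen_mirna_seqs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, "mirna_seqs"))
  n <- config$n_mirnas
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), config$mirna_length, replace = TRUE),
          collapse = "")
  }, character(1))
  # distinct seed regions keep planted-site counting exact
  while (anyDuplicated(substr(seqs, 2, 8))) {
    d <- which(duplicated(substr(seqs, 2, 8)))
    seqs[d] <- vapply(d, function(i) {
      paste(sample(c("A", "C", "G", "T"), config$mirna_length, replace = TRUE),
            collapse = "")
    }, character(1))
  }
  data.frame(id = sprintf("sim-miR-%03d", seq_len(n)), seq = seqs,
             desc = "", stringsAsFactors = FALSE)
}

#' Simulate an IP/Total small-RNA count experiment
#'
#' Total-fraction counts are drawn negative-binomially around miRNA-specific
#' baseline abundances spread log-uniformly over four orders of magnitude.
#' IP-fraction means are multiplied by `2^effect_log2` for planted enriched
#' miRNAs and `2^-effect_log2` for depleted ones, after which every library's
#' expected depth is rescaled to within 2x of the nominal depth so enrichment
#' is not confounded with sequencing depth.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a [mirna_counts()] matrix) and `truth` (sets of
#'   planted enriched/depleted miRNA ids).
#' @export
gen_mirna_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, "counts"))
  n <- config$n_mirnas
  nrep <- config$n_replicates
  ids <- sprintf("sim-miR-%03d", seq_len(n))
  base <- 10^stats::runif(n, 0, 4)
  n_enr <- round(config$frac_enriched * n)
  n_dep <- round(config$frac_depleted * n)
  flagged <- sample(n, n_enr + n_dep)
  enriched <- flagged[seq_len(n_enr)]
  depleted <- setdiff(flagged, enriched)
  eff <- rep(1, n)
  eff[enriched] <- 2^config$effect_log2
  eff[depleted] <- 2^-config$effect_log2
  total_rel <- base / sum(base)
  ip_rel <- base * eff / sum(base * eff)
  depth <- config$total_reads * stats::runif(2L * nrep, 0.75, 1.35)
  mu <- cbind(outer(ip_rel, depth[seq_len(nrep)]),
              outer(total_rel, depth[nrep + seq_len(nrep)]))
  cnt <- if (config$dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
           nrow = n)
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), nrow = n)
  }
  dimnames(cnt) <- list(ids, c(sprintf("IP_%d", seq_len(nrep)),
                               sprintf("TOTAL_%d", seq_len(nrep))))
  list(counts = mirna_counts(cnt),
       truth = list(enriched_mirnas = ids[enriched],
                    depleted_mirnas = ids[depleted]))
}

#' Simulate an IP/Total microarray experiment on two platforms
#'
#' Per-gene baseline intensities are log-normal; platform-1 probes (1 to
#' `probes_per_gene[2]` per gene) carry a log-normal affinity; Total signal is
#' baseline x affinity x replicate noise and IP signal additionally carries
#' the gene effect `2^effect_log2` for planted target genes. The extra
#' platform contributes `n_platform2` replicates with exactly one probe per
#' gene. Every probe x replicate x channel gets an independent detection flag
#' that is unreliable with probability `detect_dropout`.
#'
#' @param config a [sim_config()].
#' @return list with `signals` (a [probe_signal()] object) and `truth`
#'   (planted target gene ids).
#' @export
gen_microarray <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, "array"))
  ng <- config$n_genes
  genes <- sprintf("g%05d", seq_len(ng))
  targets <- sort(sample(ng, round(config$frac_targets * ng)))
  eff <- rep(1, ng)
  eff[targets] <- 2^config$effect_log2
  gene_mu <- stats::rlnorm(ng, meanlog = 7, sdlog = 1.2)

  npr <- sample(seq(config$probes_per_gene[1], config$probes_per_gene[2]),
                ng, replace = TRUE)
  gidx1 <- rep.int(seq_len(ng), npr)
  probe_no <- sequence(npr)
  info1 <- data.frame(
    probe = sprintf("A_%s_p%d", genes[gidx1], probe_no),
    transcript = sprintf("%s.t%d", genes[gidx1], probe_no),
    gene = genes[gidx1], stringsAsFactors = FALSE)
  info2 <- data.frame(
    probe = sprintf("B_%s", genes), transcript = sprintf("%s.t1", genes),
    gene = genes, stringsAsFactors = FALSE)

  n1 <- config$n_replicates
  n2 <- config$n_platform2
  nrep <- n1 + n2
  npro1 <- nrow(info1)
  affinity <- stats::rlnorm(npro1, 0, 0.3)

  blank <- function(nr) matrix(NA_real_, nr, nrep)
  ip <- total <- blank(npro1 + ng)
  # noise structure: a gene x replicate biological component shared by all
  # probes of the gene (the mRNA amount in that replicate's IP / Total
  # fraction) plus a smaller probe-level technical component
  bio <- function() stats::rlnorm(ng, 0, 0.2)
  tech <- function(nr) stats::rlnorm(nr, 0, 0.12)
  for (r in seq_len(n1)) {
    bt <- bio(); bi <- bio()
    total[seq_len(npro1), r] <- gene_mu[gidx1] * affinity * bt[gidx1] * tech(npro1)
    ip[seq_len(npro1), r] <- gene_mu[gidx1] * affinity * eff[gidx1] *
      bi[gidx1] * tech(npro1)
  }
  for (r in n1 + seq_len(n2)) {
    total[npro1 + seq_len(ng), r] <- gene_mu * bio() * tech(ng)
    ip[npro1 + seq_len(ng), r] <- gene_mu * eff * bio() * tech(ng)
  }
  det <- function() {
    d <- matrix(stats::runif(length(ip)) >= config$detect_dropout,
                nrow(ip), nrep)
    d & !is.na(ip)
  }
  ps <- probe_signal(rbind(info1, info2), ip = ip, total = total,
                     det_ip = det(), det_total = det(),
                     platform = c(rep("P1", n1), rep("P2", n2)))
  list(signals = ps,
       truth = list(target_genes = genes[targets]))
}

#' Simulate 3'UTR sequences with planted seed sites
#'
#' UTR lengths are log-normal; the background composition is uniform over
#' ACGT. For every planted target gene, `planted_sites_per_target` perfect
#' 7-mer sites (reverse complements of miRNA nucleotides 2-8, drawn from the
#' planted-enriched miRNAs when any exist, otherwise from all miRNAs) are
#' written at random non-overlapping positions of the gene's longest UTR.
#' Background UTRs are left untouched, so their matches arise by chance only.
#' A minority of genes get a second, strictly shorter transcript to exercise
#' the longest-UTR-per-gene rule downstream.
#'
#' @param config a [sim_config()].
#' @param mirnas data.frame of miRNA sequence records (see [gen_mirna_seqs()]).
#' @param truth list with at least `target_genes`; optionally
#'   `enriched_mirnas` to restrict the planted site pool.
#' @return list with `utrs` (data.frame `transcript`, `gene`, `seq`) and
#'   `truth` (the input truth plus `planted_sites`, a per-gene list of 1-based
#'   site start positions in the planted transcript).
#' @export
gen_utrs <- function(config, mirnas, truth) {
  stopifnot(inherits(config, "sim_config"), nrow(mirnas) > 0L)
  set.seed(stream_seed(config$seed, "utrs"))
  ng <- config$n_genes
  genes <- sprintf("g%05d", seq_len(ng))
  targets <- intersect(truth$target_genes, genes)
  pool_ids <- if (length(truth$enriched_mirnas %||% character(0)) > 0L) {
    truth$enriched_mirnas
  } else {
    mirnas$id
  }
  pool <- seed_site(mirnas$seq[mirnas$id %in% pool_ids])
  if (length(pool) == 0L) pool <- seed_site(mirnas$seq)

  k <- config$planted_sites_per_target
  need <- 7L * k + (k - 1L)  # sites + 1 nt spacing between them
  rand_seq <- function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }
  draw_len <- function(min_len) {
    for (i in seq_len(100L)) {
      len <- max(30L, round(stats::rlnorm(1, config$utr_len_meanlog,
                                          config$utr_len_sdlog)))
      if (len >= min_len) return(len)
    }
    log_msg("sim", "UTR length redraw failed 100x; extending to %d nt", min_len)
    min_len
  }

  is_target <- genes %in% targets
  lens <- pmax(30L, round(stats::rlnorm(ng, config$utr_len_meanlog,
                                        config$utr_len_sdlog)))
  planted <- vector("list", ng)
  seqs <- character(ng)
  for (i in seq_len(ng)) {
    len <- lens[i]
    if (is_target[i] && k > 0L) {
      if (len < need) len <- draw_len(need)
      s <- rand_seq(len)
      # non-overlapping placement by rejection over 7-nt windows
      starts <- integer(0)
      avail <- seq_len(len - 6L)
      for (j in seq_len(k)) {
        pos <- avail[sample.int(length(avail), 1L)]
        starts <- c(starts, pos)
        avail <- setdiff(avail, (pos - 6L):(pos + 6L))
        if (length(avail) == 0L && j < k) {
          # extremely short UTR; extend deterministically
          s <- paste0(s, rand_seq(need))
          len <- nchar(s)
          avail <- setdiff(seq_len(len - 6L),
                           unlist(lapply(starts, function(p) (p - 6L):(p + 6L))))
        }
      }
      for (pos in starts) {
        substr(s, pos, pos + 6L) <- pool[sample.int(length(pool), 1L)]
      }
      planted[[i]] <- sort(starts)
      seqs[i] <- s
    } else {
      seqs[i] <- rand_seq(len)
    }
  }
  utrs <- data.frame(transcript = sprintf("%s.t1", genes), gene = genes,
                     seq = seqs, stringsAsFactors = FALSE)
  # second, strictly shorter transcript for ~10% of genes
  alt <- which(stats::runif(ng) < 0.1 & nchar(seqs) > 40L)
  if (length(alt) > 0L) {
    alt_len <- pmax(30L, floor(nchar(seqs[alt]) / 2))
    utrs <- rbind(utrs, data.frame(
      transcript = sprintf("%s.t2", genes[alt]), gene = genes[alt],
      seq = vapply(alt_len, rand_seq, character(1)),
      stringsAsFactors = FALSE))
  }
  names(planted) <- genes
  truth$planted_sites <- planted[is_target]
  list(utrs = utrs, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete miRISC-IP study
#'
#' Convenience wrapper running [gen_mirna_seqs()], [gen_mirna_counts()],
#' [gen_microarray()] and [gen_utrs()] under one configuration, with one
#' merged ground-truth list.
#'
#' @param config a [sim_config()].
#' @return list with `mirnas`, `counts`, `signals`, `utrs` and `truth`.
#' @export
simulate_study <- function(config = sim_config()) {
  mirnas <- gen_mirna_seqs(config)
  sm <- gen_mirna_counts(config)
  ar <- gen_microarray(config)
  truth <- c(sm$truth, ar$truth)
  ut <- gen_utrs(config, mirnas, truth)
  list(mirnas = mirnas, counts = sm$counts, signals = ar$signals,
       utrs = ut$utrs, truth = ut$truth)
}
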