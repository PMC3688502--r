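# Pipeline entry point: stages of the analysis exposed behind one
# configuration, with deterministic seeding, file outputs and a run manifest.
# The exported functions are the interface; scripts/pipeline.R in the source
# repository wraps them for shell use.

#' Pipeline run configuration
#'
#' @param seed integer seed driving all randomness (simulation).
#' @param out_dir directory receiving stage outputs (created if missing).
#' @param alpha_mirna significance level for miRNA enrichment calls.
#' @param alpha_gene significance level for gene enrichment calls.
#' @param min_reliable replicates of reliable signal for testability.
#' @param pseudocount count offset in relative-concentration computation.
#' @param n_points_median quantile points per set in the UTR median test.
#' @param sim a [sim_config()] for the `simulate` stage (defaults to
#'   `sim_config(seed)`).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("mirisc_run_"),
                       alpha_mirna = 0.01, alpha_gene = 0.001,
                       min_reliable = 2L, pseudocount = 0.5,
                       n_points_median = 400L,
                       sim = sim_config(seed = seed)) {
  stopifnot(alpha_mirna > 0, alpha_mirna < 1, alpha_gene > 0, alpha_gene < 1)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 alpha_mirna = alpha_mirna, alpha_gene = alpha_gene,
                 min_reliable = as.integer(min_reliable),
                 pseudocount = pseudocount,
                 n_points_median = as.integer(n_points_median),
                 sim = sim),
            class = "run_config")
}

stage_paths <- function(config) {
  d <- config$out_dir
  list(counts = file.path(d, "mirna_counts.tsv"),
       probes = file.path(d, "probe_signals.tsv"),
       mirnas = file.path(d, "mirnas.fasta"),
       utrs = file.path(d, "utrs.fasta"),
       truth = file.path(d, "truth.tsv"),
       mirna_enrich = file.path(d, "mirna_enrichment.tsv"),
       gene_enrich = file.path(d, "gene_enrichment.tsv"),
       seed_scan = file.path(d, "seed_report.tsv"),
       overlap = file.path(d, "overlap.tsv"),
       report = file.path(d, "report.pdf"),
       manifest = file.path(d, "manifest.txt"))
}

write_manifest <- function(config, stage, inputs = character(0)) {
  paths <- stage_paths(config)
  lines <- c(
    sprintf("stage: %s", stage),
    sprintf("mirisc_version: %s", utils::packageVersion("mirisc")),
    sprintf("seed: %d", config$seed),
    sprintf("alpha_mirna: %g", config$alpha_mirna),
    sprintf("alpha_gene: %g", config$alpha_gene),
    sprintf("min_reliable: %d", config$min_reliable),
    sprintf("pseudocount: %g", config$pseudocount),
    sprintf("n_points_median: %d", config$n_points_median),
    vapply(inputs, function(f) {
      sprintf("input: %s md5=%s", basename(f), unname(tools::md5sum(f)))
    }, character(1))
  )
  cat(paste0(paste(lines, collapse = "\n"), "\n"), file = paths$manifest,
      append = file.exists(paths$manifest))
  invisible(paths$manifest)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` writes the synthetic study (counts, probe signals,
#' miRNA and UTR FASTA, truth labels); `mirna-enrich` runs
#' [mirna_enrichment()] on the count table; `target-enrich` runs
#' [target_enrichment()] on the probe table; `seed-scan` runs [seed_report()]
#' for the enriched-gene set against all testable genes; `overlap` tests the
#' enriched set against the planted truth set with [hypergeom_overlap()];
#' `report` chains all stages and draws summary histograms. A manifest with
#' parameters, seed and input checksums is appended alongside every stage.
#'
#' @param stage one of `simulate`, `mirna-enrich`, `target-enrich`,
#'   `seed-scan`, `overlap`, `report`.
#' @param config a [run_config()].
#' @return named list of output file paths, invisibly.
#' @export
run_stage <- function(stage = c("simulate", "mirna-enrich", "target-enrich",
                                "seed-scan", "overlap", "report"),
                      config = run_config()) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- stage_paths(config)
  need <- function(...) {
    fs <- unlist(list(...))
    miss <- fs[!file.exists(fs)]
    if (length(miss) > 0L) {
      stop("missing input(s) for stage '", stage, "': ",
           paste(basename(miss), collapse = ", "), call. = FALSE)
    }
    fs
  }
  out <- switch(
    stage,
    "simulate" = {
      study <- simulate_study(config$sim)
      write_count_table(study$counts, paths$counts, seed = config$seed)
      write_probe_table(study$signals, paths$probes, seed = config$seed)
      write_fasta(study$mirnas, paths$mirnas)
      ut <- study$utrs
      write_fasta(data.frame(id = paste0(ut$transcript, "|", ut$gene),
                             seq = ut$seq), paths$utrs)
      truth_df <- rbind(
        data.frame(id = study$truth$enriched_mirnas, label = "enriched_mirna"),
        data.frame(id = study$truth$depleted_mirnas, label = "depleted_mirna"),
        data.frame(id = study$truth$target_genes, label = "target_gene"))
      write_tsv_report(truth_df, paths$truth, seed = config$seed)
      write_manifest(config, stage)
      paths[c("counts", "probes", "mirnas", "utrs", "truth")]
    },
    "mirna-enrich" = {
      need(paths$counts)
      fit <- mirna_enrichment(read_count_table(paths$counts),
                              pseudocount = config$pseudocount,
                              alpha = config$alpha_mirna)
      write_mirna_enrichment(fit, paths$mirna_enrich, seed = config$seed)
      write_manifest(config, stage, paths$counts)
      paths["mirna_enrich"]
    },
    "target-enrich" = {
      need(paths$probes)
      fit <- target_enrichment(read_probe_table(paths$probes),
                               alpha = config$alpha_gene,
                               min_reliable = config$min_reliable)
      write_target_enrichment(fit, paths$gene_enrich, seed = config$seed)
      write_manifest(config, stage, paths$probes)
      paths["gene_enrich"]
    },
    "seed-scan" = {
      need(paths$gene_enrich, paths$utrs, paths$mirnas)
      genes <- read_tsv_report(paths$gene_enrich)
      fa <- read_fasta(paths$utrs)
      split_id <- strsplit(fa$id, "|", fixed = TRUE)
      utrs <- data.frame(transcript = vapply(split_id, `[`, "", 1L),
                         gene = vapply(split_id, `[`, "", 2L),
                         seq = fa$seq, stringsAsFactors = FALSE)
      sites <- seed_site(read_fasta(paths$mirnas)$seq)
      enriched <- gene_set("enriched", genes$gene[genes$enriched %in% c(TRUE, "TRUE")])
      testable <- gene_set("testable", genes$gene)
      rep_df <- seed_report(list(enriched, testable), utrs, sites,
                            reference = testable)
      write_tsv_report(as.data.frame(rep_df), paths$seed_scan,
                       seed = config$seed)
      write_manifest(config, stage, c(paths$gene_enrich, paths$utrs,
                                      paths$mirnas))
      paths["seed_scan"]
    },
    "overlap" = {
      need(paths$gene_enrich, paths$truth)
      genes <- read_tsv_report(paths$gene_enrich)
      truth <- read_tsv_report(paths$truth)
      enriched <- gene_set("enriched", genes$gene[genes$enriched %in% c(TRUE, "TRUE")])
      planted <- gene_set("planted_targets",
                          truth$id[truth$label == "target_gene"])
      universe <- gene_set("testable", genes$gene)
      res <- hypergeom_overlap(enriched, planted, universe)
      write_tsv_report(res, paths$overlap, seed = config$seed)
      write_manifest(config, stage, c(paths$gene_enrich, paths$truth))
      paths["overlap"]
    },
    "report" = {
      for (s in c("simulate", "mirna-enrich", "target-enrich", "seed-scan",
                  "overlap")) {
        run_stage(s, config)
      }
      genes <- read_tsv_report(paths$gene_enrich)
      mir <- read_tsv_report(paths$mirna_enrich)
      grDevices::pdf(paths$report, width = 8, height = 4)
      graphics::par(mfrow = c(1, 2))
      graphics::hist(mir$delta_log2, breaks = 40, col = "grey80",
                     main = "miRNA log2 fold (IP vs Total)", xlab = "log2 fold")
      graphics::hist(genes$mean_rank, breaks = 40, col = "grey80",
                     main = "gene mean percent rank", xlab = "percent rank")
      grDevices::dev.off()
      write_manifest(config, stage)
      paths
    })
  invisible(out)
}
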