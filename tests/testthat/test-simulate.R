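test_that("generators are deterministic given the config seed", {
  cfg <- small_config(seed = 5)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$signals, s2$signals)
  expect_identical(s1$utrs, s2$utrs)
  expect_identical(s1$truth, s2$truth)
  s3 <- gen_mirna_counts(small_config(seed = 6))
  expect_false(identical(unclass(s3$counts), unclass(s1$counts)))
})

test_that("count generator honours dimensions, pairing and library balance", {
  cfg <- sim_config(seed = 2, n_mirnas = 100)
  sim <- gen_mirna_counts(cfg)
  expect_equal(nrow(sim$counts), 100L)
  expect_equal(sort(colnames(sim$counts)),
               sort(c(sprintf("IP_%d", 1:4), sprintf("TOTAL_%d", 1:4))))
  depth <- colSums(sim$counts)
  expect_lt(max(depth) / min(depth), 2)
  expect_equal(length(intersect(sim$truth$enriched_mirnas,
                                sim$truth$depleted_mirnas)), 0L)
  expect_true(all(unclass(sim$counts) >= 0))
  expect_true(all(unclass(sim$counts) %% 1 == 0))
})

test_that("planted miRNA effects show the expected direction", {
  cfg <- sim_config(seed = 3, n_mirnas = 300, frac_enriched = 0.1,
                    frac_depleted = 0.1, effect_log2 = 2)
  sim <- gen_mirna_counts(cfg)
  fit <- mirna_enrichment(sim$counts)
  tab <- fit$table
  d_enr <- tab$delta_log2[tab$mirna %in% sim$truth$enriched_mirnas]
  d_dep <- tab$delta_log2[tab$mirna %in% sim$truth$depleted_mirnas]
  d_bg <- tab$delta_log2[!tab$mirna %in% c(sim$truth$enriched_mirnas,
                                           sim$truth$depleted_mirnas)]
  expect_gt(mean(d_enr), mean(d_bg) + 1)
  expect_lt(mean(d_dep), mean(d_bg) - 1)
})

test_that("array generator emits two platforms with the right probe structure", {
  cfg <- small_config(seed = 4)
  sim <- gen_microarray(cfg)
  ps <- sim$signals
  expect_equal(ps$platform, c(rep("P1", 4), "P2"))
  p2_rows <- startsWith(ps$info$probe, "B_")
  # platform 2: exactly one probe per gene
  expect_equal(sum(p2_rows), cfg$n_genes)
  expect_equal(anyDuplicated(ps$info$gene[p2_rows]), 0L)
  # platform-2 probes carry data only in the platform-2 column
  expect_true(all(is.na(ps$ip[p2_rows, 1:4])))
  expect_true(all(!is.na(ps$ip[p2_rows, 5])))
  expect_true(all(is.na(ps$ip[!p2_rows, 5])))
})

test_that("full detection dropout yields zero testable genes downstream", {
  sim <- gen_microarray(small_config(seed = 7, detect_dropout = 1))
  fit <- suppressMessages(target_enrichment(sim$signals))
  expect_equal(nrow(fit$genes), 0L)
})

test_that("planted target genes carry the planted number of exact sites", {
  cfg <- small_config(seed = 8, planted_sites_per_target = 3)
  mirnas <- gen_mirna_seqs(cfg)
  truth <- list(target_genes = sprintf("g%05d", 1:20),
                enriched_mirnas = mirnas$id[1:5])
  ut <- gen_utrs(cfg, mirnas, truth)
  sites <- seed_site(mirnas$seq[1:5])
  per_gene <- ut$utrs[match(paste0(truth$target_genes, ".t1"),
                            ut$utrs$transcript), ]
  counts <- count_matches(per_gene$seq, sites)
  expect_true(all(counts >= 3))
  expect_equal(sort(names(ut$truth$planted_sites)),
               sort(truth$target_genes))
  expect_true(all(lengths(ut$truth$planted_sites) == 3))
  # planted positions contain a real site
  g <- truth$target_genes[1]
  seq1 <- ut$utrs$seq[ut$utrs$transcript == paste0(g, ".t1")]
  for (pos in ut$truth$planted_sites[[g]]) {
    expect_true(substr(seq1, pos, pos + 6) %in% sites)
  }
})

test_that("empty target set receives no planted sites", {
  cfg <- small_config(seed = 9)
  mirnas <- gen_mirna_seqs(cfg)
  ut <- gen_utrs(cfg, mirnas, list(target_genes = character(0)))
  expect_equal(length(ut$truth$planted_sites), 0L)
})

test_that("target-set site density exceeds background across seeds", {
  for (s in 1:5) {
    cfg <- small_config(seed = s, planted_sites_per_target = 2)
    mirnas <- gen_mirna_seqs(cfg)
    truth <- list(target_genes = sprintf("g%05d", 1:20),
                  enriched_mirnas = mirnas$id[1:8])
    ut <- gen_utrs(cfg, mirnas, truth)
    sites <- seed_site(mirnas$seq[1:8])
    rep <- suppressMessages(density_report(
      gene_set("targets", truth$target_genes), ut$utrs, sites,
      reference = unique(ut$utrs$gene)))
    expect_gt(rep$relative_density, 1)
  }
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(frac_enriched = 0.7, frac_depleted = 0.5), "<= 1")
  expect_error(sim_config(detect_dropout = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  expect_error(sim_config(probes_per_gene = c(3, 1)), "range")
})
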