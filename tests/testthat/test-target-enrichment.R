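test_that("testable entities need reliable signal in enough replicates", {
  det <- rbind(c(TRUE, TRUE, FALSE, FALSE),
               c(TRUE, FALSE, FALSE, FALSE),
               c(FALSE, FALSE, FALSE, FALSE),
               c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(testable_entities(det), c(TRUE, FALSE, FALSE, TRUE))
  # reliability must hold in both channels of the same replicate
  det_total <- rbind(c(FALSE, TRUE, TRUE, FALSE),
                     c(TRUE, TRUE, TRUE, TRUE),
                     c(TRUE, TRUE, TRUE, TRUE),
                     c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(testable_entities(det, det_total),
               c(FALSE, FALSE, FALSE, TRUE))
})

test_that("percent ranks follow (r - 0.5)/n with average ties", {
  expect_equal(percent_rank(c(3, 1, 2)), c(2.5, 0.5, 1.5) / 3)
  expect_equal(percent_rank(c(2, 2, 1)), c(2, 2, 0.5) / 3)
  set.seed(31)
  x <- rlnorm(501)
  pr <- percent_rank(x)
  expect_equal(mean(pr), 0.5, tolerance = 1e-12)
  expect_true(all(pr > 0 & pr < 1))
  # no ties: the multiset of ranks is exactly {(i - 0.5)/n}
  expect_equal(sort(pr), (seq_along(x) - 0.5) / length(x))
  expect_error(percent_rank(2), ">= 2")
  expect_error(percent_rank(c(1, -2)), "positive")
})

test_that("gene p-values agree with one-tailed Welch t.test", {
  set.seed(32)
  half <- runif(2500)
  bg <- c(half, 1 - half)  # symmetric background, mean exactly 0.5
  flat <- c(0.5, 0.5, 0.5, 0.5)
  expect_gte(gene_pvalue(flat, bg), 0.45)
  high <- c(0.99, 0.98, 0.99, 0.97)
  expect_lt(gene_pvalue(high, bg), 0.001)
  low <- c(0.1, 0.1, 0.12, 0.1)
  expect_gt(gene_pvalue(low, bg), 0.99)
  for (i in 1:10) {
    e <- runif(4)
    ref <- t.test(e, bg, alternative = "greater")$p.value
    expect_equal(gene_pvalue(e, bg), ref, tolerance = 1e-9)
  }
  expect_error(gene_pvalue(c(0.4, NA, NA, NA), bg), ">= 2")
})

test_that("probe collapsing keeps the minimum-p probe with documented ties", {
  rec <- data.frame(
    probe = c("p1", "p2", "p3", "p4", "p5"),
    transcript = c("t1", "t1", "t2", "t3", "t4"),
    gene = c("gA", "gA", "gA", "gB", "gC"),
    mean_rank = c(0.7, 0.9, 0.8, 0.5, 0.6),
    p = c(0.5, 0.01, 0.10, 0.2, 0.2),
    stringsAsFactors = FALSE)
  out <- collapse_probes(rec)
  expect_equal(out$probe[out$gene == "gA"], "p2")
  expect_equal(out$probe[out$gene == "gB"], "p4")  # single probe unchanged
  # tie on p: larger mean rank wins
  tie <- data.frame(probe = c("pa", "pb"), transcript = c("t", "t"),
                    gene = "g", mean_rank = c(0.6, 0.8), p = c(0.05, 0.05))
  expect_equal(collapse_probes(tie)$probe, "pb")
  # tie on p and rank: lexicographic probe id
  tie2 <- data.frame(probe = c("pz", "pa"), transcript = c("t", "t"),
                     gene = "g", mean_rank = 0.6, p = 0.05)
  expect_equal(collapse_probes(tie2)$probe, "pa")
  # idempotence
  expect_equal(collapse_probes(out), out)
})

test_that("platform merge appends the extra rank and recomputes p", {
  set.seed(33)
  bg <- runif(4000)
  rec <- data.frame(gene = c("g1", "g2"),
                    r1 = c(0.80, 0.6), r2 = c(0.85, 0.55),
                    r3 = c(0.90, 0.65), r4 = c(0.95, 0.6),
                    stringsAsFactors = FALSE)
  rec$mean_rank <- rowMeans(rec[, c("r1", "r2", "r3", "r4")])
  rec$p <- c(gene_pvalue(as.numeric(rec[1, 2:5]), bg),
             gene_pvalue(as.numeric(rec[2, 2:5]), bg))
  p_before <- rec$p
  merged <- merge_platform(rec, c(g1 = 0.99), bg)
  # g1: 5th high rank appended, p strictly lowered
  expect_equal(merged$r5, c(0.99, NA_real_))
  expect_lt(merged$p[1], p_before[1])
  expect_equal(merged$p[1],
               gene_pvalue(c(0.80, 0.85, 0.90, 0.95, 0.99), bg),
               tolerance = 1e-12)
  # g2 absent from platform 2: record unchanged
  expect_equal(merged$p[2], p_before[2])
  expect_equal(merged$mean_rank[2], rec$mean_rank[2])
  # orphan platform-2 gene is dropped with a log entry
  expect_message(merge_platform(rec, c(g9 = 0.5), bg), "dropped")
})

test_that("enriched calls use a strict threshold", {
  rec <- data.frame(gene = c("a", "b", "c"), p = c(0.0009, 0.001, NA))
  expect_equal(suppressMessages(call_enriched(rec, alpha = 0.001)), "a")
  empty <- data.frame(gene = character(0), p = numeric(0))
  expect_equal(length(suppressMessages(call_enriched(empty))), 0L)
})

test_that("the array stage recovers planted targets and stays classed", {
  cfg <- sim_config(seed = 34, n_genes = 800, frac_targets = 0.05,
                    effect_log2 = 1.5)
  sim <- gen_microarray(cfg)
  fit <- suppressMessages(target_enrichment(sim$signals))
  expect_s3_class(fit, "target_enrichment")
  g <- fit$genes
  expect_true(all(g$p >= 0 & g$p <= 1, na.rm = TRUE))
  expect_true(all(g$enriched == (g$p < fit$alpha), na.rm = TRUE))
  called <- g$gene[g$enriched]
  recall <- mean(sim$truth$target_genes %in% called)
  expect_gt(recall, 0.6)
  # every percent-rank column lies strictly inside (0, 1)
  rk <- as.matrix(g[, grep("^r[0-9]+$", names(g))])
  expect_true(all(rk > 0 & rk < 1, na.rm = TRUE))
  expect_output(print(fit), "testable genes")
  f <- tempfile(fileext = ".tsv")
  write_target_enrichment(fit, f)
  expect_equal(nrow(read_tsv <- utils::read.delim(f, comment.char = "#")),
               nrow(g))
})
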