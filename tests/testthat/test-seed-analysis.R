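test_that("seed sites are the reverse complement of miRNA nt 2-8", {
  expect_equal(seed_site("UAAGGCACGCGGUGAAUGCCA"), "GTGCCTT")
  expect_equal(seed_site("AAAAAAAA"), "TTTTTTT")
  expect_error(seed_site("ACGTACG"), "shorter than 8")
  # control recovers nt 2-8 in DNA form, and is an involution
  expect_equal(control_site("GTGCCTT"), "AAGGCAC")
  expect_equal(control_site("AACGCGT"), "ACGCGTT")
  set.seed(41)
  sites <- seed_site(vapply(rep(22, 10), random_dna, character(1)))
  expect_equal(control_site(control_site(sites)), sites)
  # seed_site then control_site recovers miRNA nt 2-8 exactly
  m <- "TCGATTTGGCAATTTTAGAGC"
  expect_equal(control_site(seed_site(m)), substr(m, 2, 8))
})

test_that("match counting is overlapping, per-site, and N-safe", {
  expect_equal(count_matches("AAAAAAAA", "AAAAAAA"), 2L)
  expect_equal(count_matches("ACGTACGTACG", "TTTTTTT"), 0L)
  expect_equal(count_matches("GTGCCTT", "GTGCCTT"), 1L)
  # a position matching two distinct sites counts twice
  expect_equal(count_matches("AAAAAAATTTTTTT", c("AAAAAAA", "TTTTTTT")), 2L)
  expect_equal(count_matches("AANAAAAAAA", "AAAAAAA"), 1L)
  # duplicate sites in the query are not double counted
  expect_equal(count_matches("GTGCCTT", c("GTGCCTT", "GTGCCTT")), 1L)
})

test_that("match counting equals the naive per-position oracle", {
  set.seed(42)
  for (i in 1:60) {
    utr <- random_dna(sample(20:120, 1))
    sites <- unique(vapply(rep(7, sample(1:4, 1)), random_dna, character(1)))
    expect_equal(count_matches(utr, sites), naive_count(utr, sites))
  }
  # low-complexity stress case where overlaps abound
  utr <- paste(sample(c("A", "T"), 300, replace = TRUE), collapse = "")
  sites <- c("ATATATA", "TATATAT", "AAAAAAA")
  expect_equal(count_matches(utr, sites), naive_count(utr, sites))
})

test_that("density reports aggregate counts, lengths and controls", {
  utrs <- data.frame(
    transcript = c("t1.1", "t2.1", "t3.1", "t3.2"),
    gene = c("g1", "g2", "g3", "g3"),
    seq = c(paste0(strrep("C", 500), "GTGCCTT", strrep("C", 493)),
            strrep("A", 1000),
            paste0(strrep("G", 250), "GTGCCTT", "GTGCCTT", strrep("C", 236)),
            strrep("T", 100)),  # shorter alt transcript must be ignored
    stringsAsFactors = FALSE)
  rep <- density_report(gene_set("all", c("g1", "g2", "g3")), utrs,
                        sites = "GTGCCTT", reference = c("g1", "g2", "g3"))
  expect_equal(rep$n_genes, 3L)
  expect_equal(rep$total_utr_nt, 2500L)
  expect_equal(rep$total_matches, 3L)
  expect_equal(rep$density_per_kb, 1000 * 3 / 2500)
  expect_equal(rep$frac_with_site, 2 / 3)
  expect_equal(rep$relative_density, 1)  # set == reference
  expect_equal(rep$median_utr_len, 1000)
  # 5 matches over 2000 nt -> 2.5 per kb
  expect_equal(1000 * 5 / 2000, 2.5)
  # duplicate ids and order do not change the report
  rep2 <- density_report(gene_set("dup", c("g3", "g1", "g2", "g1")), utrs,
                         sites = "GTGCCTT", reference = c("g2", "g3", "g1"))
  expect_equal(rep2$density_per_kb, rep$density_per_kb)
  expect_equal(rep2$total_utr_nt, rep$total_utr_nt)
  # gene with no UTR is excluded with a message; empty set errors
  expect_message(
    r3 <- density_report(gene_set("x", c("g1", "g9")), utrs, "GTGCCTT",
                         reference = c("g1", "g2", "g3")), "no UTR")
  expect_equal(r3$n_genes, 1L)
  expect_error(suppressMessages(
    density_report(gene_set("y", "g9"), utrs, "GTGCCTT", reference = "g1")),
    "no genes with UTRs")
})

test_that("the quantile grid is linear-interpolated and identity at n = 400", {
  x <- sort(rlnorm(400, 5, 0.5))
  res <- median_utr_test(x, x + 0, n_points = 400)
  expect_equal(res$p, 1)
  # grid of a 400-point vector is the sorted vector itself
  q <- quantile(x, probs = (1:400) / 400, type = 4, names = FALSE)
  expect_equal(q, x)
})

test_that("the median test separates shifted distributions and not identical ones", {
  identical_res <- median_utr_test(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(identical_res$p, 1)
  for (s in 1:5) {
    set.seed(s)
    a <- runif(1000, 0, 1)
    b <- runif(1000, 0.5, 1.5)
    res <- median_utr_test(a, b)
    expect_lt(res$p, 0.001)
    expect_lt(res$median_a, res$median_b)
  }
  # null: same distribution should usually not reject
  set.seed(99)
  res0 <- median_utr_test(runif(1000), runif(1000))
  expect_gt(res0$p, 0.001)
  expect_warning(median_utr_test(rep(5, 10), rep(5, 12)), "constant")
})

test_that("median test agrees with a hand-built chi-square on its 2x2 table", {
  set.seed(43)
  a <- rlnorm(2000, 5, 0.6)
  b <- rlnorm(2000, 5.2, 0.6)
  res <- median_utr_test(a, b)
  tab <- res$table
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  expect_equal(res$p, ref)
  expect_equal(sum(tab), 800)
})
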