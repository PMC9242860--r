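test_that("empirical_p applies the add-one correction and respects sides", {
  expect_equal(empirical_p(-5, rnorm(1000) + 10, "less"), 1 / 1001)  # floor
  expect_equal(empirical_p(0, c(-1, 0, 1), "less"), 3 / 4)           # #{<=0}=2
  expect_equal(empirical_p(99, 1:10, "less"), 1)                     # above all
  expect_equal(empirical_p(99, 1:10, "greater"), 1 / 11)
  expect_error(empirical_p(0, numeric(0)), "empty")
  # never 0, never > 1, monotone in the observed statistic
  null <- rnorm(500)
  ps <- vapply(seq(-3, 3, by = 0.5), function(o) empirical_p(o, null, "less"), 1)
  expect_true(all(ps > 0 & ps <= 1))
  expect_true(all(diff(ps) >= 0))
})

test_that("region_screen_test: degenerate screens, determinism, extreme hit", {
  # all constructs identical -> every p = 1 under side=less with add-one
  lib <- simple_library(setNames(rep(c("rA", "rB"), each = 2),
                                 c("rA_c1", "rA_c2", "rB_c1", "rB_c2")))
  fc <- make_fc(c("rA_c1", "rA_c2", "rB_c1", "rB_c2"), "s1", rep(-0.3, 4))
  res <- suppressWarnings(
    region_screen_test(fc, lib, score_config(), perm_config(50, seed = 1)))
  expect_equal(res$empirical_p, c(1, 1))

  # single region -> error
  lib1 <- simple_library(setNames(rep("rA", 2), c("rA_c1", "rA_c2")))
  fc1 <- make_fc(c("rA_c1", "rA_c2"), "s1", c(-1, -2))
  expect_error(suppressWarnings(
    region_screen_test(fc1, lib1, score_config(), perm_config(50, seed = 1))),
    ">= 2 region")

  # one truly depleting region among 50 null regions attains the p floor
  n_reg <- 50
  ids <- sprintf("r%02d_c%d", rep(1:n_reg, each = 4), 1:4)
  lib2 <- simple_library(setNames(sprintf("r%02d", rep(1:n_reg, each = 4)), ids))
  vals <- rep(0, length(ids))
  vals[1:4] <- -3
  fc2 <- make_fc(ids, "s1", vals)
  res2 <- region_screen_test(fc2, lib2, score_config(), perm_config(2000, seed = 9))
  # the planted region is the unambiguous top hit at (or within ties of) the
  # estimator floor 1/2001; ties arise when a permutation reassigns >= 2 of
  # the depleted constructs to the planted label (prob ~ 0.002 per draw), so
  # exact attainment of the floor is seed luck, not a guarantee
  p_hit <- res2$empirical_p[res2$target_id == "r01"]
  expect_gte(p_hit, 1 / 2001)
  expect_lte(p_hit, 10 / 2001)
  expect_equal(which.min(res2$empirical_p), match("r01", res2$target_id))
  expect_true(all(res2$empirical_p[res2$target_id != "r01"] > 0.4))
  # same seed -> bit-identical; different seed -> same observed scores
  res2b <- region_screen_test(fc2, lib2, score_config(), perm_config(2000, seed = 9))
  expect_identical(res2, res2b)
  res2c <- region_screen_test(fc2, lib2, score_config(), perm_config(200, seed = 10))
  expect_equal(res2c$score, res2$score)
})

test_that("tss_window_enrichment counts match a brute-force double loop", {
  # spec'd toy case: one gene at 1 Mb, one peak inside and one outside 500 kb
  tss <- data.frame(gene = c("g1", "far"), chrom = "chr1",
                    tss = c(1000000, 90e6), stringsAsFactors = FALSE)
  peaks <- intervals_bed0(c("chr1", "chr1"), c(999000, 2600000), c(999500, 2600400))
  res <- tss_window_enrichment(peaks, tss, "g1", 500000,
                               perm_config(100, seed = 1))
  expect_equal(res$observed_count, 1)

  # empty peak list -> 0 and p = 1
  res0 <- tss_window_enrichment(GenomicRanges::GRanges(), tss, "g1", 500000,
                                perm_config(100, seed = 1))
  expect_equal(res0$observed_count, 0)
  expect_equal(res0$empirical_p, 1)

  # gene_set = all genes -> degenerate null, p = 1
  resall <- tss_window_enrichment(peaks, tss, tss$gene, 500000,
                                  perm_config(100, seed = 1))
  expect_equal(resall$empirical_p, 1)

  # missing TSS -> error listing the gene
  expect_error(tss_window_enrichment(peaks, tss, c("g1", "ghost")), "ghost")

  # randomized instance vs quadratic oracle
  set.seed(21)
  ann <- simulate_genome_annotation(n_genes = 40, n_peaks = 150,
                                    chrom_lengths = c(chr1 = 20e6, chr2 = 20e6),
                                    gene_set_size = 8, enrichment = 0.3,
                                    window_bp = 3e5, seed = 77)
  got <- tss_window_enrichment(ann$peaks, ann$tss, ann$gene_set, 3e5,
                               perm_config(10, seed = 2))$observed_count
  w <- 3e5
  st <- GenomicRanges::start(ann$peaks) - 1; en <- GenomicRanges::end(ann$peaks)
  ch <- as.character(GenomicRanges::seqnames(ann$peaks))
  brute <- 0
  for (i in seq_along(ann$peaks)) {
    hit <- FALSE
    for (g in ann$gene_set) {
      row <- ann$tss[ann$tss$gene == g, ]
      lo <- row$tss - w; hi <- row$tss + w  # inclusive window bases
      if (ch[i] == row$chrom && st[i] <= hi && en[i] - 1 >= lo) hit <- TRUE
    }
    brute <- brute + hit
  }
  expect_equal(got, brute)
})

test_that("interval_overlap_fisher matches closed forms and the hypergeometric oracle", {
  # construct a universe with known membership counts (30, 70, 20, 180)
  n <- 300
  uni <- intervals_bed0("chr1", seq(0, by = 1000, length.out = n),
                        seq(0, by = 1000, length.out = n) + 100)
  a_idx <- 1:100            # |A| = 100: 30 shared + 70 A-only
  b_idx <- c(1:30, 101:120) # |B| = 50: 30 shared + 20 B-only
  res <- interval_overlap_fisher(uni[a_idx], uni[b_idx], uni)
  expect_equal(unname(as.vector(res$table)), c(30, 20, 70, 180))
  expect_equal(res$odds_ratio, (30 * 180) / (70 * 20), tolerance = 1e-12)
  expect_equal(res$p_value, oracle_fisher_greater(30, 70, 20, 180), tolerance = 1e-10)
  expect_false(res$haldane_corrected)

  # independence-ish table: OR 1, p >= 0.5
  uni2 <- uni[1:100]
  res2 <- interval_overlap_fisher(uni2[1:50], uni2[c(1:25, 51:75)], uni2)
  expect_equal(res2$odds_ratio, 1)
  expect_gte(res2$p_value, 0.5)

  # A = B = universe -> degenerate, flagged, Haldane-corrected CI
  res3 <- interval_overlap_fisher(uni2, uni2, uni2)
  expect_true(res3$degenerate)
  expect_true(res3$haldane_corrected)

  # overlap-mode membership: a shifted copy of the universe still matches
  shifted <- GenomicRanges::shift(uni2[1:10], 50)
  res4 <- interval_overlap_fisher(shifted, uni2[1:10], uni2, mode = "overlap")
  expect_equal(res4$table["in_A", "in_B"], 10)
})

test_that("library Fisher p agrees with hypergeometric summation on small tables", {
  # sweep of small tables incl. zero cells
  for (a in 0:4) for (b in 0:3) for (c_ in 0:3) for (d in 0:3) {
    if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0) next
    p_lib <- fisher.test(matrix(c(a, c_, b, d), 2), alternative = "greater")$p.value
    expect_equal(p_lib, oracle_fisher_greater(a, b, c_, d), tolerance = 1e-10)
  }
})

test_that("set_overlap canonicalizes and deduplicates", {
  expect_equal(set_overlap(paste0("p", 1:5), paste0("p", 4:8)),
               c(n_a = 5L, n_b = 5L, n_shared = 2L))
  expect_equal(unname(set_overlap(c("a", "A ", " a"), c("b"))[1]), 1L)
  x <- c("TP53", "  pax8", "Hif2A")
  expect_equal(unname(set_overlap(x, x)[3]), 3L)
})

test_that("peak co-binding fraction matches a quadratic all-pairs oracle", {
  a <- intervals_bed0("chr1", c(0, 100, 200, 300), c(50, 150, 250, 350))
  b <- intervals_bed0("chr1", c(40, 140), c(60, 160))
  expect_equal(peak_cobinding_fraction(a, b), 0.5)
  expect_equal(peak_cobinding_fraction(a, GenomicRanges::GRanges()), 0)
  expect_error(peak_cobinding_fraction(GenomicRanges::GRanges(), b), "empty")

  set.seed(5)
  ra <- sort(sample(0:5000, 60))
  rb <- sort(sample(0:5000, 40))
  A <- intervals_bed0("chrT", ra, ra + sample(10:80, 60, replace = TRUE))
  B <- intervals_bed0("chrT", rb, rb + sample(10:80, 40, replace = TRUE))
  sa <- GenomicRanges::start(A); ea <- GenomicRanges::end(A)
  sb <- GenomicRanges::start(B); eb <- GenomicRanges::end(B)
  brute <- mean(vapply(seq_along(A), function(i)
    any(sa[i] <= eb & ea[i] >= sb), logical(1)))
  expect_equal(peak_cobinding_fraction(A, B), brute)
})

test_that("neutral-screen region p-values are approximately uniform (mini calibration)", {
  sim <- simulate_screen(sim_config(n_targets = 60, n_depleting = 0, seed = 12,
                                    depth = 2e5, bottleneck_size = 2e4,
                                    n_units_per_group = 3))
  fc <- centered_fc_from_sim(sim)
  res <- region_screen_test(fc, sim$library, score_config(),
                            perm_config(400, seed = 3))
  ks <- suppressWarnings(stats::ks.test(res$empirical_p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(res$empirical_p >= 1 / 401 & res$empirical_p <= 1))
})
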