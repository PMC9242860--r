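make_cm <- function(counts, roles = NULL) {
  n_s <- ncol(counts)
  if (is.null(roles)) roles <- c("reference", rep("endpoint", n_s - 1))
  samples <- data.frame(
    sample_id = colnames(counts), role = roles,
    unit_id = colnames(counts),
    group_id = ifelse(roles == "endpoint", "g1", ""),
    reference_id = ifelse(roles == "endpoint", colnames(counts)[1], ""),
    stringsAsFactors = FALSE)
  count_matrix(counts, samples)
}

test_that("normalize_counts matches the hand arithmetic and always sums to 1e6", {
  cm <- make_cm(matrix(c(1L, 1L, 3L, 1L), 2,
                       dimnames = list(c("c1", "c2"), c("s1", "s2"))))
  ab <- normalize_counts(cm, score_config(pseudocount = 0.5))
  expect_equal(unname(ab[, "s1"]), c(5e5, 5e5))
  expect_equal(unname(ab[, "s2"]), c(7e5, 3e5))  # (3.5/5, 1.5/5) * 1e6
  expect_equal(unname(colSums(ab)), c(1e6, 1e6), tolerance = 1e-6)

  # all-zero sample: uniform under pseudocount, error without
  cm0 <- make_cm(matrix(c(0L, 0L, 0L, 0L), 2,
                        dimnames = list(c("c1", "c2"), c("s1", "s2"))))
  expect_equal(unname(normalize_counts(cm0, score_config(pseudocount = 0.5))[, 1]),
               c(5e5, 5e5))
  expect_error(normalize_counts(cm0, score_config(pseudocount = 0)), "all-zero")
})

test_that("guide_log2fc computes endpoint/reference ratios", {
  ab <- matrix(c(7e5, 3e5, 3.5e5, 6e5), 2,
               dimnames = list(c("c1", "c2"), c("ref", "end")))
  samples <- data.frame(sample_id = c("ref", "end"), role = c("reference", "endpoint"),
                        unit_id = c("u0", "u1"), group_id = c("", "g1"),
                        reference_id = c("", "ref"), stringsAsFactors = FALSE)
  fc <- guide_log2fc(ab, samples)
  expect_equal(fc$log2fc[fc$construct_id == "c1"], -1)       # 3.5e5 vs 7e5
  expect_equal(fc$log2fc[fc$construct_id == "c2"], 1)        # 2x
  expect_equal(fc$linear_fc, 2^fc$log2fc, tolerance = 1e-12)
  expect_false(attr(fc, "centered"))
})

test_that("control_center subtracts the control centre per sample", {
  lib <- simple_library(c(gA_c1 = "gA"), class = "gene", n_ctrl = 3)
  fc <- make_fc(c("gA_c1", "ntc_1", "ntc_2", "ntc_3"), "s1",
                c(-1.4, -0.4, -0.4, -0.4), centered = FALSE)
  out <- control_center(fc, lib, score_config())
  expect_equal(out$log2fc, c(-1.0, 0, 0, 0))
  expect_true(attr(out, "centered"))

  # controls already at 0 -> unchanged
  fc0 <- make_fc(c("gA_c1", "ntc_1", "ntc_2", "ntc_3"), "s1",
                 c(-1, 0.1, 0, -0.1), centered = FALSE)
  expect_equal(control_center(fc0, lib, score_config())$log2fc, fc0$log2fc)

  # single control maps exactly to 0
  lib1 <- simple_library(c(gA_c1 = "gA"), class = "gene", n_ctrl = 1)
  fc1 <- make_fc(c("gA_c1", "ntc_1"), "s1", c(-2, 0.7), centered = FALSE)
  expect_equal(control_center(fc1, lib1, score_config())$log2fc[2], 0)

  # no controls -> instructive error
  expect_error(control_center(make_fc("gA_c1", "s1", -1),
                              simple_library(c(gA_c1 = "gA"), "gene", n_ctrl = 0)),
               "non-targeting controls")
})

test_that("gene sensitivity score is log2 of the mean of the top-k depleted guides", {
  lib <- simple_library(setNames(rep("gA", 4), paste0("gA_c", 1:4)), class = "gene")
  fc <- make_fc(paste0("gA_c", 1:4), "rep1", log2(c(0.25, 0.5, 1.0, 2.0)))
  sc <- gene_sensitivity_score(fc, lib, score_config(k_gene = 3))
  expect_equal(sc$score, log2(mean(c(0.25, 0.5, 1.0))), tolerance = 1e-12)  # -0.7776
  expect_equal(sc$n_constructs_used, 3L)

  # all guides at fold change 1 -> score 0
  fc1 <- make_fc(paste0("gA_c", 1:4), "rep1", rep(0, 4))
  expect_equal(gene_sensitivity_score(fc1, lib, score_config())$score, 0)

  # fewer constructs than k -> use all, record n
  lib2 <- simple_library(c(gB_c1 = "gB", gB_c2 = "gB"), class = "gene")
  fc2 <- make_fc(c("gB_c1", "gB_c2"), "rep1", c(-2, -1))
  sc2 <- gene_sensitivity_score(fc2, lib2, score_config(k_gene = 3))
  expect_equal(sc2$n_constructs_used, 2L)
  expect_equal(sc2$score, log2(mean(c(0.25, 0.5))), tolerance = 1e-12)

  # replicate averaging: per-replicate scores then mean
  fc3 <- bind_fc(make_fc(paste0("gA_c", 1:4), "rep1", c(-2, -2, -2, 0)),
                 make_fc(paste0("gA_c", 1:4), "rep2", c(-1, -1, -1, 0)))
  sc3 <- gene_sensitivity_score(fc3, lib, score_config(k_gene = 3))
  expect_equal(sc3$score, mean(c(-2, -1)))
  expect_equal(sc3[["unit.rep1"]], -2)
})

test_that("region depletion score averages groups of the top-m construct means", {
  lib <- simple_library(setNames(rep("rA", 3), paste0("rA_c", 1:3)))
  fc <- make_fc(paste0("rA_c", 1:3), "s1", c(-3, -2, -0.5))
  sc <- region_depletion_score(fc, lib, score_config(m_region = 2))
  expect_equal(sc$score, -2.5)  # mean of two lowest

  # all zero -> 0
  fc0 <- make_fc(paste0("rA_c", 1:3), "s1", rep(0, 3))
  expect_equal(region_depletion_score(fc0, lib, score_config())$score, 0)

  # two groups -3 and -2 -> combined -2.5; per-group columns exposed
  fc2 <- bind_fc(make_fc(paste0("rA_c", 1:3), "s1", c(-3, -3, -3), group_id = "left"),
                 make_fc(paste0("rA_c", 1:3), "s2", c(-2, -2, -2), group_id = "right"))
  sc2 <- region_depletion_score(fc2, lib, score_config(m_region = 2))
  expect_equal(sc2$score, -2.5)
  expect_equal(sc2[["group.left"]], -3)
  expect_equal(sc2[["group.right"]], -2)

  # construct log2fc are averaged across a group's units before ranking
  fc3 <- bind_fc(make_fc(paste0("rA_c", 1:3), "t1", c(-4, 0, 0), group_id = "g"),
                 make_fc(paste0("rA_c", 1:3), "t2", c(0, -2, 0), group_id = "g"))
  # per-construct group means: -2, -1, 0 -> top-2 mean = -1.5
  expect_equal(region_depletion_score(fc3, lib, score_config())$score, -1.5)
})

test_that("top-k selection equals the exhaustive k-subset oracle", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    k <- sample(1:3, 1)
    vals <- round(rnorm(n), 3)
    lib <- simple_library(setNames(rep("tX", n), sprintf("tX_c%02d", 1:n)))
    fc <- make_fc(sprintf("tX_c%02d", 1:n), "s1", vals)
    got <- region_depletion_score(fc, lib, score_config(m_region = k))$score
    expect_equal(got, oracle_top_k_mean(vals, k), tolerance = 1e-12)
    # gene path under mean_of_logs agrees with the same oracle
    libg <- simple_library(setNames(rep("gX", n), sprintf("gX_c%02d", 1:n)), "gene")
    fcg <- make_fc(sprintf("gX_c%02d", 1:n), "s1", vals)
    gotg <- gene_sensitivity_score(fcg, libg,
                                   score_config(k_gene = k, fc_space = "mean_of_logs"))$score
    expect_equal(gotg, oracle_top_k_mean(vals, k), tolerance = 1e-12)
  }
})

test_that("scale invariance: rescaling a sample's counts leaves log2fc unchanged", {
  set.seed(4)
  counts <- matrix(rpois(20, 100), 10, 2,
                   dimnames = list(sprintf("c%02d", 1:10), c("ref", "end")))
  cm1 <- make_cm(counts)
  counts2 <- counts; counts2[, "end"] <- counts2[, "end"] * 10L
  cm2 <- make_cm(counts2)
  # pseudocount scaled with the sample so the invariance is exact
  fc1 <- guide_log2fc(normalize_counts(cm1, score_config(pseudocount = 0.5)), cm1$samples)
  ab2 <- cm2$counts + rep(c(0.5, 5), each = 10)
  ab2 <- sweep(ab2, 2, colSums(ab2), "/") * 1e6
  fc2 <- guide_log2fc(ab2, cm2$samples)
  expect_equal(fc1$log2fc, fc2$log2fc, tolerance = 1e-12)
})

test_that("monotonicity: lowering a construct's endpoint count cannot raise its score", {
  base <- matrix(c(rep(100L, 6), c(80L, 90L, 100L, 50L, 100L, 100L)), 6, 2,
                 dimnames = list(c(sprintf("rA_c%d", 1:4), "ntc_1", "ntc_2"),
                                 c("ref", "end")))
  lib <- simple_library(setNames(rep("rA", 4), sprintf("rA_c%d", 1:4)))
  score_of <- function(counts) {
    cm <- make_cm(counts)
    fc <- control_center(guide_log2fc(normalize_counts(cm), cm$samples), lib)
    region_depletion_score(fc, lib)$score
  }
  s0 <- score_of(base)
  for (drop_to in c(70L, 30L, 5L, 0L)) {
    mod <- base
    mod["rA_c1", "end"] <- drop_to
    expect_lte(score_of(mod), s0 + 1e-12)
  }
})

test_that("fc_space options agree exactly when all selected guides are equal", {
  lib <- simple_library(setNames(rep("gA", 3), paste0("gA_c", 1:3)), "gene")
  fc <- make_fc(paste0("gA_c", 1:3), "s1", rep(-1.3, 3))
  s_lin <- gene_sensitivity_score(fc, lib, score_config(fc_space = "linear_then_log"))$score
  s_log <- gene_sensitivity_score(fc, lib, score_config(fc_space = "mean_of_logs"))$score
  expect_equal(s_lin, s_log, tolerance = 1e-12)
  expect_equal(s_lin, -1.3)
})
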