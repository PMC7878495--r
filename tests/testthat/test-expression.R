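test_that("FPKM follows its defining arithmetic and is linear in counts", {
  cm <- make_cm(
    matrix(c(100L, 0L, 5L, 37L), nrow = 2, byrow = TRUE,
           dimnames = list(c("gA", "gB"), c("s1", "s2"))),
    lengths = c(1000, 1234),
    groups = c("indica", "japonica"),
    totals = c(1e6, 2345678)
  )
  f <- compute_fpkm(cm)
  expect_equal(f["gA", "s1"], 100)  # 100 reads, 1 kb, 1e6 mapped
  expect_equal(f["gA", "s2"], 0)
  expect_equal(f["gB", "s2"], 37 * 1e9 / (1234 * 2345678))
  expect_equal(f["gB", "s2"], 12.782, tolerance = 1e-4)

  # doubling one count doubles exactly that FPKM entry
  cm2 <- cm
  cm2$counts["gB", "s1"] <- 10L
  expect_equal(compute_fpkm(cm2)["gB", "s1"], 2 * f["gB", "s1"])

  cm$samples$total_reads[2] <- 0
  expect_error(compute_fpkm(cm), "s2")
})

test_that("expressed-gene partition applies the 2-reads-in-2-samples rule", {
  counts <- rbind(
    g_both = c(5L, 5L, 5L, 5L),
    g_ind = c(2L, 2L, 0L, 0L),
    g_one_sample = c(1000L, 0L, 0L, 0L),
    g_jap = c(0L, 0L, 3L, 2L),
    g_none = c(1L, 1L, 1L, 1L)
  )
  colnames(counts) <- c("i1", "i2", "j1", "j2")
  cm <- make_cm(counts)
  sets <- expressed_gene_sets(cm)
  expect_equal(
    setNames(sets$status, sets$gene_id),
    c(g_both = "both", g_ind = "indica_only",
      g_one_sample = "not_expressed", g_jap = "japonica_only",
      g_none = "not_expressed")
  )

  # double-bookkeeping oracle on a random matrix
  set.seed(5)
  rc <- matrix(rnbinom(20 * 8, mu = 2, size = 1), nrow = 20)
  colnames(rc) <- sprintf("s%d", 1:8)
  cm <- make_cm(rc)
  sets <- expressed_gene_sets(cm)
  for (g in seq_len(20)) {
    ind <- sum(rc[g, 1:4] >= 2) >= 2
    jap <- sum(rc[g, 5:8] >= 2) >= 2
    want <- if (ind && jap) "both" else if (ind) "indica_only" else {
      if (jap) "japonica_only" else "not_expressed"
    }
    expect_equal(sets$status[g], want)
  }
})

test_that("read-count filter honours default and strict semantics", {
  counts <- rbind(
    g_low = c(19L, 10L, 5L, 0L),
    g_burst = c(25L, 0L, 0L, 0L),
    g_high = c(30L, 40L, 50L, 60L)
  )
  colnames(counts) <- sprintf("s%d", 1:4)
  cm <- make_cm(counts)
  expect_setequal(rownames(filter_min_reads(cm)$counts),
                  c("g_burst", "g_high"))
  expect_setequal(rownames(filter_min_reads(cm, strict = TRUE)$counts),
                  "g_high")

  # loop oracle on a random matrix, both modes
  set.seed(6)
  rc <- matrix(rnbinom(50 * 6, mu = 15, size = 2), nrow = 50)
  colnames(rc) <- sprintf("s%d", 1:6)
  cm <- make_cm(rc)
  keep_default <- sum(vapply(1:50, function(g) max(rc[g, ]) >= 20, logical(1)))
  keep_strict <- sum(vapply(1:50, function(g) min(rc[g, ]) >= 20, logical(1)))
  expect_equal(nrow(filter_min_reads(cm)$counts), keep_default)
  expect_equal(nrow(filter_min_reads(cm, strict = TRUE)$counts), keep_strict)
})

test_that("NB test recovers planted DEGs and reports them by direction", {
  cfg <- sim_config(n_genes = 800, n_true_deg = 60, deg_log2fc = 2,
                    nb_dispersion = 0.1, seed = 19)
  sim <- simulate_counts(cfg)
  de <- nb_de_test(filter_min_reads(sim$counts))
  called <- de$gene_id[de$deg]
  truth <- sim$truth$true_deg_ids
  expect_gt(mean(truth %in% called), 0.8)
  expect_lt(mean(!called %in% truth), 0.15)
  # direction matches the planted sign
  planted <- sim$truth$planted_log2fc
  hits <- de[de$deg & de$gene_id %in% truth, ]
  sign_planted <- sign(planted$log2fc[match(hits$gene_id, planted$gene_id)])
  expect_true(all(sign(hits$log2fc) == sign_planted))
  expect_true(all(hits$direction[sign_planted > 0] == "up_in_indica"))

  # the FDR column is exactly the BH step-up of the raw p-values
  expect_equal(de$fdr, oracle_bh(de$p_value))
  expect_true(all(de$fdr <= 1))
})

test_that("NB test raw p-values are roughly uniform under the null", {
  fr <- vapply(1:5, function(s) {
    cfg <- sim_config(n_genes = 400, n_true_deg = 1, deg_log2fc = 0,
                      nb_dispersion = 0.1, seed = 100 + s)
    cm <- simulate_counts(cfg)$counts
    de <- nb_de_test(filter_min_reads(cm))
    mean(de$p_value < 0.05, na.rm = TRUE)
  }, numeric(1))
  n_tests <- 5 * 400
  expect_lt(abs(mean(fr) - 0.05), 3 * sqrt(0.05 * 0.95 / n_tests) + 0.005)
})

test_that("DE results are invariant to sample order and flag boundary genes", {
  cfg <- sim_config(n_genes = 120, n_true_deg = 20, seed = 23)
  cm <- simulate_counts(cfg)$counts
  de1 <- nb_de_test(cm)
  perm <- sample(ncol(cm$counts))
  cm2 <- count_matrix(cm$counts[, perm], cm$genes$length,
                      cm$samples$group[perm], cm$samples$total_reads[perm])
  de2 <- nb_de_test(cm2)
  expect_equal(de1, de2)

  # a gene silent in one group gets the infinite fold-change sentinel
  counts <- cm$counts
  counts[1, cm$samples$group == "japonica"] <- 0L
  counts[1, cm$samples$group == "indica"] <- 50L
  cm3 <- count_matrix(counts, cm$genes$length, cm$samples$group)
  de3 <- nb_de_test(cm3)
  expect_true(de3$boundary[1])
  expect_equal(de3$log2fc[1], Inf)
  expect_true(is.finite(de3$p_value[1]))
})

test_that("Welch t matches the textbook computation and its invariances", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
  # hand computation: means 2 and 3, variances 1 and 2.5
  se2 <- 1 / 3 + 2.5 / 5
  t_hand <- (2 - 3) / sqrt(se2)
  df_hand <- se2^2 / ((1 / 3)^2 / 2 + (2.5 / 5)^2 / 4)
  res <- welch_ttest(a, b)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)

  # identical samples and scale invariance
  expect_equal(welch_ttest(b, b)$statistic, 0)
  expect_equal(welch_ttest(b, b)$p_value, 1)
  expect_equal(welch_ttest(10 * a, 10 * b)$statistic, res$statistic)

  # degenerate constant vectors
  expect_equal(welch_ttest(c(2, 2), c(2, 2))$p_value, 1)
  expect_equal(welch_ttest(c(3, 3), c(2, 2))$p_value, 0)
})

test_that("Pearson validation behaves on proportional, inverted and toy data", {
  x <- c(1, 2, 4, 8, 16)
  expect_equal(pearson_validation(3 * x, x), 1)
  expect_equal(pearson_validation(rev(x), x), -1)

  # toy 5-pair vector against the covariance-formula computation
  y <- c(2, 5, 3, 9, 12)
  lx <- log2(x); ly <- log2(y)
  r_hand <- sum((lx - mean(lx)) * (ly - mean(ly))) /
    sqrt(sum((lx - mean(lx))^2) * sum((ly - mean(ly))^2))
  expect_equal(pearson_validation(x, y), r_hand, tolerance = 1e-12)

  expect_error(pearson_validation(c(1, 1, 1), y[1:3]), "variance")
})
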