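test_that("size factors: identical samples get 1, scaled samples scale", {
  m <- matrix(rpois(200, 50), 100, 2,
              dimnames = list(sprintf("f%d", 1:100), c("s1", "s2")))
  m[, 2] <- m[, 1]
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1, 1))

  m2 <- cbind(s1 = m[, 1] + 1, s2 = 2 * (m[, 1] + 1))
  sf2 <- size_factors(m2)
  expect_equal(unname(sf2[2] / sf2[1]), 2)
})

test_that("size factors match a literal median-of-ratios hand calculation", {
  set.seed(13)
  m <- matrix(rnbinom(200, mu = 80, size = 10), 50, 4,
              dimnames = list(sprintf("f%d", 1:50), sprintf("s%d", 1:4)))
  pos <- rowSums(m > 0) == 4
  geo <- exp(rowMeans(log(m[pos, ])))
  want <- apply(m[pos, ], 2, function(col) median(col / geo))
  expect_equal(size_factors(m), want)

  # all-zero-containing matrix needs the pseudo-reference flag
  z <- m; z[cbind(1:50, rep(1:4, length.out = 50))] <- 0
  expect_error(size_factors(z), "pseudo_reference")
  expect_silent(size_factors(z, pseudo_reference = TRUE))
})

test_that("BH adjustment matches hand-computed step-up and the literal oracle", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(17)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  # NA entries propagate and are excluded from m
  p <- c(0.01, NA, 0.04)
  got <- bh_adjust(p)
  expect_true(is.na(got[2]))
  expect_equal(got[c(1, 3)], oracle_bh(c(0.01, 0.04)))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("RPKM follows its closed form and is depth-invariant", {
  m <- matrix(c(100, 50), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  m["g2", 1] <- 1e7 - 100 # sample total 1e7
  expect_equal(rpkm(m, c(g1 = 1000, g2 = 1e6))["g1", 1], 10)
  set.seed(19)
  m2 <- matrix(rpois(60, 100), 20, 3,
               dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:3)))
  len <- setNames(sample(500:2000, 20), rownames(m2))
  expect_equal(rpkm(2 * m2, len), rpkm(m2, len))
  # elementwise scalar formula
  want <- m2 * 1e9 / outer(len, colSums(m2))
  expect_equal(rpkm(m2, len), want)
})

test_that("null features give log2fc 0 and all-zero features are untestable", {
  # every feature has identical counts in both groups (equal-depth samples),
  # so every fold change is exactly 0 and no feature approaches significance
  set.seed(2)
  col <- rpois(30, 80)
  col[2] <- 0
  m <- matrix(rep(col, 6), 30, 6,
              dimnames = list(sprintf("f%02d", 1:30),
                              c(paste0("a_rep", 1:3), paste0("b_rep", 1:3))))
  cm <- count_matrix(m, setNames(rep(c("A", "B"), each = 3), colnames(m)))
  r <- nb_wald_test(cm, "A", "B", refine_norm = FALSE)
  expect_equal(r$log2fc[1], 0, tolerance = 1e-9)
  expect_gt(r$p[1], 0.9)
  expect_equal(r$status[2], "untestable")
  expect_equal(r$log2fc[2], 0)
  expect_equal(r$p[2], 1)
})

test_that("raw p-values are calibrated on the simulator's own null model", {
  cfg <- sim_config(seed = 1, n_per_class = c(null = 2000))
  cm <- simulate_counts(cfg)$counts
  r <- nb_wald_test(cm, "nt", "dual")
  frac <- mean(r$p <= 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("log2fc does not decrease when group-B counts increase", {
  cm <- toy_counts(n = 40)
  r1 <- nb_wald_test(cm, "A", "B", refine_norm = FALSE)
  cm2 <- cm
  cm2$counts[5, 4:6] <- cm2$counts[5, 4:6] + 50
  r2 <- nb_wald_test(cm2, "A", "B", refine_norm = FALSE)
  expect_gte(r2$log2fc[5], r1$log2fc[5])
})

test_that("differential calls respect inclusive boundaries and the FDR gate", {
  de <- fake_de(c("a", "b", "c"),
                log2fc = c(log2(1.5), 3, 0.3),
                padj = c(0.05, 0.2, 0.01))
  cd <- call_differential(de)
  expect_true(cd$induced[1])  # FC exactly 1.5, padj exactly 0.05
  expect_false(cd$induced[2]) # strong FC but padj 0.2
  expect_false(cd$induced[3]) # significant but FC < 1.5
  # repressed is symmetric
  de2 <- fake_de("d", log2fc = -log2(1.5), padj = 0.05)
  expect_true(call_differential(de2)$repressed)
  # called sets are nested in the FDR level
  set.seed(23)
  de3 <- fake_de(sprintf("g%d", 1:100), log2fc = runif(100, 0, 2),
                 padj = runif(100))
  strict <- call_differential(de3, analysis_thresholds(padj_max = 0.02))
  loose <- call_differential(de3, analysis_thresholds(padj_max = 0.1))
  expect_true(all(loose$induced[strict$induced]))
})

test_that("induced-gene recovery meets sensitivity and FDR bounds at effect 4", {
  cfg <- sim_config(seed = 1, effect_single = 4,
                    n_per_class = c(null = 1500, gluc_only = 150))
  sim <- simulate_counts(cfg)
  de <- call_differential(nb_wald_test(sim$counts, "nt", "gluc"))
  truth <- sim$truth$class == "gluc_only"
  sens <- sum(de$induced & truth) / sum(truth)
  fdr <- sum(de$induced & !truth) / max(sum(de$induced), 1)
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.1)
})

test_that("log2fc estimates agree with DESeq2 on shared input", {
  skip_if_not_installed("DESeq2")
  cfg <- sim_config(seed = 3, n_per_class = c(null = 400, cort_only = 100))
  cm <- simulate_counts(cfg)$counts
  sel <- names(cm$conditions)[cm$conditions %in% c("nt", "cort")]
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      cm$counts[, sel],
      S4Vectors::DataFrame(cond = factor(cm$conditions[sel],
                                         levels = c("nt", "cort"))),
      ~cond)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- DESeq2::results(dds)
  })
  mine <- nb_wald_test(cm, "nt", "cort")
  expect_gt(cor(mine$log2fc, ref$log2FoldChange), 0.98)
  strong <- abs(ref$log2FoldChange) > 1
  expect_equal(sign(mine$log2fc[strong]), sign(ref$log2FoldChange[strong]))
})
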