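test_that("antagonism needs induction against both the control and the dual", {
  ids <- c("g1", "g2", "g3")
  # g1: induced gluc-vs-nt AND gluc-vs-dual -> antagonized by cort
  # g2: induced gluc-vs-nt only -> not antagonized
  # g3: induced only in cort-vs-nt -> in neither set
  gluc_nt <- fake_de(ids, c(2, 2, 0), c(0.001, 0.001, 0.9))
  gluc_dual <- fake_de(ids, c(1.5, 0, 0), c(0.001, 0.9, 0.9))
  cort_nt <- fake_de(ids, c(0, 0, 2), c(0.9, 0.9, 0.001))
  cort_dual <- fake_de(ids, c(0, 0, 0.1), c(0.9, 0.9, 0.5))
  res <- classify_antagonism(gluc_nt, gluc_dual, cort_nt, cort_dual)
  expect_equal(res$antag_by_cort, "g1")
  expect_equal(res$antag_by_gluc, character(0))

  bad <- fake_de(c("g1", "gX", "g3"), c(0, 0, 0), c(1, 1, 1))
  expect_error(classify_antagonism(gluc_nt, gluc_dual, cort_nt, bad),
               "universes")
})

test_that("synergy requires all three inductions plus a strict sum excess", {
  ids <- c("g1", "g2", "g3")
  de <- function(...) fake_de(ids, c(...), rep(0.001, 3))
  des <- list(de(2, 2, 2), de(1.2, 1, 1), de(1.2, 1, 1))
  rmeans <- rbind(g1 = c(nt = 10, gluc = 20, cort = 20, dual = 45),
                  g2 = c(nt = 10, gluc = 20, cort = 20, dual = 30),
                  g3 = c(nt = 10, gluc = 20, cort = 20, dual = 40))
  # all genes pass the three DE gates; the sum criterion is strict, so an
  # exact tie with the sum of single-treatment values is NOT synergistic
  res_d <- classify_synergy(des[[1]], des[[2]], des[[3]], rmeans,
                            sum_rule = "delta")
  expect_equal(res_d$synergistic, c("g1", "g3")) # g2: 20 == 10+10 fails
  res_r <- classify_synergy(des[[1]], des[[2]], des[[3]], rmeans,
                            sum_rule = "raw")
  expect_equal(res_r$synergistic, "g1") # g3: 40 == 20+20 fails

  expect_error(classify_synergy(des[[1]], des[[2]], des[[3]],
                                rmeans[, 1:3]), "columns")
})

test_that("synergy and antagonism calls are disjoint by construction", {
  # same gene universe, random gates: the two classifications can never
  # share a gene because they require opposite dual-vs-single directions
  set.seed(29)
  ids <- sprintf("g%02d", 1:60)
  rand_de <- function() fake_de(ids, runif(60, -2, 3), runif(60, 0, 0.2))
  for (i in 1:5) {
    gluc_nt <- rand_de(); cort_nt <- rand_de()
    dual_gluc <- rand_de(); dual_cort <- rand_de(); dual_nt <- rand_de()
    # gluc_vs_dual is the mirrored dual_vs_gluc contrast
    gluc_dual <- dual_gluc; gluc_dual$log2fc <- -gluc_dual$log2fc
    cort_dual <- dual_cort; cort_dual$log2fc <- -cort_dual$log2fc
    rmeans <- matrix(runif(240, 1, 100), 60, 4,
                     dimnames = list(ids, c("nt", "gluc", "cort", "dual")))
    an <- classify_antagonism(gluc_nt, gluc_dual, cort_nt, cort_dual)
    sy <- classify_synergy(dual_nt, dual_gluc, dual_cort, rmeans)
    expect_length(intersect(sy$synergistic,
                            c(an$antag_by_cort, an$antag_by_gluc)), 0)
  }
})

test_that("planted antagonized genes are recovered, wrong-hormone genes are not", {
  cfg <- sim_config(seed = 2, n_per_class = c(null = 1000, gluc_only = 100,
                                              cort_only = 100,
                                              antag_by_cort = 100))
  sim <- simulate_counts(cfg)
  cm <- sim$counts
  res <- classify_antagonism(
    nb_wald_test(cm, "nt", "gluc"), nb_wald_test(cm, "dual", "gluc"),
    nb_wald_test(cm, "nt", "cort"), nb_wald_test(cm, "dual", "cort"))
  truth <- sim$truth$id[sim$truth$class == "antag_by_cort"]
  sens <- length(intersect(res$antag_by_cort, truth)) / length(truth)
  expect_gte(sens, 0.8)
  # cort-only genes must not land in either antagonism set
  cort_only <- sim$truth$id[sim$truth$class == "cort_only"]
  expect_length(intersect(res$antag_by_cort, cort_only), 0)
})

test_that("k-means puts identical profiles together and beats random labels", {
  set.seed(33)
  base <- matrix(runif(20, 1, 10), 5, 4)
  profiles <- base[rep(1:5, each = 6), ] + 0
  rownames(profiles) <- sprintf("g%02d", 1:30)
  colnames(profiles) <- c("nt", "gluc", "cort", "dual")
  km <- kmeans_patterns(profiles, k = 5, seed = 9)
  for (grp in split(names(km$labels), rep(1:5, each = 6))) {
    expect_length(unique(km$labels[grp]), 1)
  }
  km2 <- kmeans_patterns(profiles, k = 5, seed = 9)
  expect_identical(km$labels, km2$labels)
  # objective beats a random assignment of the same z-scored data
  z <- t(apply(profiles, 1, function(x) (x - mean(x)) / sd(x)))
  set.seed(1)
  rand_lab <- sample(1:5, 30, replace = TRUE)
  rand_ss <- sum(sapply(1:5, function(k) {
    rows <- z[rand_lab == k, , drop = FALSE]
    if (!nrow(rows)) return(0)
    sum(sweep(rows, 2, colMeans(rows))^2)
  }))
  expect_lte(km$withinss, rand_ss)
  expect_error(kmeans_patterns(profiles[1:3, ], k = 5), "fewer genes")
})

test_that("planted synergistic genes concentrate in the dual-maximal cluster", {
  cfg <- sim_config(seed = 4, n_per_class = c(null = 400, gluc_only = 80,
                                              cort_only = 80, additive = 80,
                                              synergistic = 80,
                                              antag_by_cort = 80,
                                              antag_by_gluc = 80))
  sim <- simulate_counts(cfg)
  cm <- sim$counts
  th <- analysis_thresholds()
  induced <- Reduce(`|`, lapply(list(nb_wald_test(cm, "nt", "gluc"),
                                     nb_wald_test(cm, "nt", "cort"),
                                     nb_wald_test(cm, "nt", "dual")),
                                function(d) call_differential(d, th)$induced))
  cmeans <- condition_means(sweep(cm$counts, 2, size_factors(cm), "/"),
                            cm$conditions)
  km <- kmeans_patterns(cmeans[induced, , drop = FALSE], k = 5, seed = 1)
  # the cluster whose centroid peaks in dual with low singles captures the
  # majority of planted synergistic genes
  dualness <- km$centroids[, "dual"] -
    pmax(km$centroids[, "gluc"], km$centroids[, "cort"])
  target <- which.max(dualness)
  syn <- intersect(names(km$labels),
                   sim$truth$id[sim$truth$class == "synergistic"])
  expect_gt(mean(km$labels[syn] == target), 0.5)
})

test_that("overlap summaries reproduce the printed counting and rounding", {
  universe <- sprintf("g%04d", 1:5000)
  a <- universe[1:165]
  b <- c(universe[1:92], universe[1000:1500])
  ov <- overlap_summary(a, b, universe)
  expect_equal(ov$n_overlap, 92)
  expect_equal(ov$pct_label, 56)

  a2 <- universe[1:1035]
  b2 <- c(universe[1:1031], universe[2000:2500])
  ov2 <- overlap_summary(a2, b2, universe)
  expect_equal(ov2$pct_label, 99.6)

  ident <- overlap_summary(a, a, universe)
  expect_equal(ident$pct_label, 100)
  expect_lt(ident$p_hyper, 1e-100)
  expect_error(overlap_summary(c(a, "missing"), b, universe), "subsets")
})
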