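test_that("config validation rejects impossible settings", {
  expect_error(sim_config(synergy_factor = 1), "synergy_factor")
  expect_error(sim_config(antagonism_residual = 1), "antagonism_residual")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(cluster_span = 1000, unit_length = 400,
                          units_per_cluster_range = c(2, 4)),
               "infeasible packing")
})

test_that("class mean formulas follow the planted interaction definitions", {
  cfg <- sim_config(baseline_mean = 100, effect_single = 3,
                    synergy_factor = 1.5, antagonism_residual = 0.1)
  m <- class_condition_means(cfg)
  expect_equal(unname(m["null", ]), rep(100, 4))
  expect_equal(unname(m["gluc_only", ]), c(100, 300, 100, 300))
  expect_equal(unname(m["additive", "dual"]), 100 + 200 + 200)
  expect_equal(unname(m["synergistic", "dual"]), 100 + 1.5 * 400) # = 700
  expect_equal(unname(m["antag_by_cort", ]), c(100, 300, 100, 120))

  # degenerate no-effect config: all conditions identical for every class
  m0 <- class_condition_means(sim_config(effect_single = 1))
  expect_true(all(m0 == m0[, "nt"]))
})

test_that("identical configs give bit-identical counts, genome and tracks", {
  cfg <- sim_config(seed = 77, n_per_class = c(null = 50, synergistic = 20),
                    n_assisted = 4, n_unassisted = 4, n_inactive = 2)
  a <- simulate_counts(cfg); b <- simulate_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  ga <- simulate_genome(cfg); gb <- simulate_genome(cfg)
  expect_identical(ga$sequence, gb$sequence)
  expect_identical(ga$annotation, gb$annotation)
  ta <- simulate_coverage(ga, "dual", "GR", 1)
  tb <- simulate_coverage(gb, "dual", "GR", 1)
  expect_identical(ta$values, tb$values)
  # a different replicate stream differs
  tc <- simulate_coverage(ga, "dual", "GR", 2)
  expect_false(identical(ta$values, tc$values))
})

test_that("simulated null counts match the NB mean-variance relationship", {
  cfg <- sim_config(seed = 6, n_per_class = c(null = 2000), dispersion = 0.05)
  cm <- simulate_counts(cfg)$counts
  mu <- cfg$baseline_mean
  means <- rowMeans(cm$counts)
  vars <- apply(cm$counts, 1, var)
  expect_lt(abs(mean(means) - mu) / mu, 0.1)
  expect_lt(abs(mean(vars) - (mu + 0.05 * mu^2)) / (mu + 0.05 * mu^2), 0.1)
})

test_that("unit-count range collapse gives exactly that many units everywhere", {
  cfg <- sim_config(seed = 8, units_per_cluster_range = c(2, 2),
                    n_assisted = 5, n_unassisted = 5, n_inactive = 5)
  g <- simulate_genome(cfg)
  counts <- table(sub("_[0-9]+$", "", g$annotation$dhs$name))
  expect_true(all(counts == 2))
  # conservation: every planted site is classified exactly once
  expect_equal(sort(as.integer(table(g$truth$site_class))), c(5, 5, 5))
  expect_equal(length(g$truth$site_class), nrow(g$annotation$grbs))
})

test_that("planted weak GREs score below strong GREs and rescan in place", {
  cfg <- sim_config(seed = 9, n_assisted = 6, n_unassisted = 6,
                    n_inactive = 2)
  g <- simulate_genome(cfg)
  pm <- g$truth$planted_motifs
  gre <- pm[pm$pwm == "gre", ]
  weak <- gre$logodds[g$truth$site_class[gre$site] == "assisted"]
  strong <- gre$logodds[g$truth$site_class[gre$site] == "unassisted"]
  expect_true(max(weak) < min(strong))
  # round trip: rescanning every planted interval recovers the planted
  # position and strand at the planted score
  for (i in seq_len(nrow(pm))) {
    s <- substr(g$sequence[[pm$chrom[i]]], pm$start[i] + 1, pm$end[i])
    hits <- pwm_logodds_scan(s, g$pwms[[pm$pwm[i]]], offset0 = pm$start[i])
    hit <- hits[hits$strand == pm$strand[i], ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$start, pm$start[i])
    expect_equal(hit$score, pm$logodds[i], tolerance = 1e-9)
  }
})

test_that("coverage obeys the assay rule table and Poisson totals", {
  cfg <- sim_config(seed = 10, n_assisted = 10, n_unassisted = 10,
                    n_inactive = 5)
  g <- simulate_genome(cfg)
  L <- cfg$genome_length
  # GR in nt: pure background
  tr_nt <- simulate_coverage(g, "nt", "GR", 1)
  expect_lt(abs(tr_nt$total_tags - cfg$background_rate * L) /
              (cfg$background_rate * L), 0.05)
  expect_error(simulate_coverage(g, "nt", "ATAC", 1), "unknown assay")
  expect_error(simulate_coverage(g, "fasted", "GR", 1), "unknown condition")

  # track totals match background + planted peak mass within 5% over seeds
  plan <- synergyseq:::coverage_plan(g, "dual", "GR")
  expected <- cfg$background_rate * L + sum(plan$height * plan$halfwidth)
  totals <- sapply(1:10, function(r) {
    simulate_coverage(g, "dual", "GR", r)$total_tags
  })
  expect_lt(abs(mean(totals) - expected) / expected, 0.05)

  # assisted sites: dual coverage beats cort in nearly all windows
  assisted <- g$annotation$grbs[
    g$truth$site_class[g$annotation$grbs$name] == "assisted", ]
  cort <- quantify_tags(assisted, simulate_coverage(g, "cort", "GR", 1), 200)
  dual <- quantify_tags(assisted, simulate_coverage(g, "dual", "GR", 1), 200)
  expect_gte(mean(dual > cort), 0.95)
})

test_that("simulation inputs round-trip through the on-disk formats", {
  cfg <- sim_config(seed = 12, n_per_class = c(null = 20, synergistic = 5),
                    n_assisted = 3, n_unassisted = 3, n_inactive = 2)
  sc <- simulate_counts(cfg)
  g <- simulate_genome(cfg)
  d <- withr::local_tempdir()
  write_simulation(sc, g, d)
  cm2 <- read_counts(file.path(d, "counts.tsv"))
  expect_equal(cm2$counts, sc$counts$counts)
  expect_equal(cm2$conditions, sc$counts$conditions)
  grbs2 <- read_bed(file.path(d, "grbs.bed"))
  expect_equal(grbs2$start, g$annotation$grbs$start)
  cfg2 <- read_sim_config(file.path(d, "config.yaml"))
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$n_per_class, cfg$n_per_class)
})
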