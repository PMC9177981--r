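test_that("cluster membership follows the center-to-center window rule", {
  focal <- gintervals("chr1", 49800, 50201, name = "site_1") # center 50000
  dhs <- gintervals("chr1",
                    c(49900, 44000, 37300, 70000),
                    c(50100, 44400, 37700, 70400)) # centers 5e4, 44200, 37500, 70200
  cl <- detect_clusters(focal, dhs, cluster_window = 12500, min_units = 2)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$n_units, 3) # 70200 is 20.2 kb away
  expect_equal(sum(cl$units$contains_focal), 1)

  # a DHS centered exactly 12,500 bp away is included (inclusive boundary)
  dhs_edge <- gintervals("chr1", c(49900, 62400), c(50100, 62600))
  cl2 <- detect_clusters(focal, dhs_edge)
  expect_equal(cl2$clusters$n_units, 2)

  # focal site with its only DHS out of range is excluded and counted
  lone <- gintervals("chr1", 200000, 200400, name = "site_2")
  cl3 <- detect_clusters(rbind(focal, lone), dhs)
  expect_equal(cl3$n_excluded_no_units, 1)

  # one unit in range with min_units = 2 -> excluded but tallied separately
  cl4 <- detect_clusters(focal, dhs[1, , drop = FALSE])
  expect_equal(cl4$n_excluded_below_min, 1)
  expect_equal(nrow(cl4$clusters), 0)
})

test_that("cluster detection recovers exactly the planted unit counts", {
  cfg <- sim_config(seed = 14, n_assisted = 8, n_unassisted = 8,
                    n_inactive = 4)
  g <- simulate_genome(cfg)
  cl <- detect_clusters(g$annotation$grbs, g$annotation$dhs)
  planted <- table(sub("^dhs_([0-9]+)_.*$", "\\1", g$annotation$dhs$name))
  got <- setNames(cl$clusters$n_units,
                  sub("^site_", "", cl$clusters$cluster_id))
  expect_equal(unname(got[names(planted)]), unname(as.integer(planted)))
})

test_that("cluster membership is invariant under genome translation", {
  focal <- gintervals("chr1", 30000, 30400, name = "f")
  dhs <- gintervals("chr1", c(25000, 30100, 41000), c(25400, 30500, 41400))
  shift <- 12345
  cl1 <- detect_clusters(focal, dhs)
  focal2 <- focal; focal2$start <- focal2$start + shift
  focal2$end <- focal2$end + shift
  dhs2 <- dhs; dhs2$start <- dhs2$start + shift; dhs2$end <- dhs2$end + shift
  cl2 <- detect_clusters(focal2, dhs2)
  expect_equal(cl1$clusters$n_units, cl2$clusters$n_units)
  expect_equal(cl2$units$start - cl1$units$start,
               rep(shift, nrow(cl1$units)))
})

test_that("co-occurrence scans only accessible units and gains from the cluster", {
  g <- gre_pwm(); cr <- cre_pwm()
  set.seed(71)
  genome <- list(chrS = random_dna(40000))
  # focal unit with a GRE; CRE only BETWEEN units (inaccessible)
  cg <- consensus_seq(g); cc <- consensus_seq(cr)
  substr(genome$chrS, 20001, 20000 + nchar(cg)) <- cg
  substr(genome$chrS, 21001, 21000 + nchar(cc)) <- cc # inter-unit gap
  focal <- gintervals("chrS", 19900, 20300, name = "site_1")
  dhs <- gintervals("chrS", c(19900, 22000), c(20300, 22400))
  cl <- detect_clusters(focal, dhs)
  co <- cluster_co_occurrence(cl, genome, g, cr)
  expect_equal(co$fraction, 0) # the CRE is not inside any unit

  # planting the CRE inside the sibling unit flips the cluster positive
  substr(genome$chrS, 22101, 22100 + nchar(cc)) <- cc
  co2 <- cluster_co_occurrence(cl, genome, g, cr)
  expect_equal(co2$fraction, 1)
  # but the focal unit alone still lacks it
  cof <- cluster_co_occurrence(cl, genome, g, cr, focal_only = TRUE)
  expect_equal(cof$fraction, 0)
  expect_gte(co2$fraction, cof$fraction)
})

test_that("assisted clusters out-co-occur unassisted clusters on planted data", {
  cfg <- sim_config(seed = 15, n_assisted = 15, n_unassisted = 15,
                    n_inactive = 5)
  g <- simulate_genome(cfg)
  by_class <- function(cls) {
    sel <- g$annotation$grbs[
      g$truth$site_class[g$annotation$grbs$name] == cls, ]
    cluster_co_occurrence(detect_clusters(sel, g$annotation$dhs),
                          g$sequence, g$pwms$gre, g$pwms$cre)$fraction
  }
  expect_gt(by_class("assisted"), by_class("unassisted"))
})

test_that("cluster signal quantifies units and focal exclusion shrinks them", {
  focal <- gintervals("chr1", 10000, 10400, name = "f1")
  dhs <- gintervals("chr1", c(10000, 15000, 20000),
                    c(10400, 15400, 20400))
  cl <- detect_clusters(focal, dhs)
  tr <- coverage_track(list(chr1 = rep(2, 40000)))
  sig <- cluster_signal(cl, tr, halfwidth = 500, normalize = FALSE)
  expect_equal(sig$per_unit$tags, rep(2000, 3)) # uniform track
  sig2 <- cluster_signal(cl, tr, halfwidth = 500, exclude_focal_unit = TRUE,
                         normalize = FALSE)
  expect_equal(sig2$per_cluster$n_units_used,
               sig$per_cluster$n_units_used - 1)
  expect_false(sig2$per_cluster$empty)

  # a cluster reduced to nothing is flagged empty
  cl1 <- detect_clusters(focal, dhs[1, , drop = FALSE], min_units = 1)
  sig3 <- cluster_signal(cl1, tr, exclude_focal_unit = TRUE)
  expect_true(sig3$per_cluster$empty)
})

test_that("glucagon elevates assisted-cluster acetylation beyond the focal unit", {
  cfg <- sim_config(seed = 16, n_assisted = 12, n_unassisted = 12,
                    n_inactive = 4)
  g <- simulate_genome(cfg)
  assisted <- g$annotation$grbs[
    g$truth$site_class[g$annotation$grbs$name] == "assisted", ]
  cl <- detect_clusters(assisted, g$annotation$dhs)
  nt <- cluster_signal(cl, simulate_coverage(g, "nt", "H3K27ac", 1),
                       exclude_focal_unit = TRUE)
  gl <- cluster_signal(cl, simulate_coverage(g, "gluc", "H3K27ac", 1),
                       exclude_focal_unit = TRUE)
  ratio <- gl$per_cluster$mean_signal / nt$per_cluster$mean_signal
  expect_gt(mean(gl$per_cluster$mean_signal), mean(nt$per_cluster$mean_signal))
  expect_gte(mean(ratio > 1), 0.9)
})
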