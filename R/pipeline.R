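#' Run the full crosstalk + assisted-loading pipeline on simulated data
#'
#' Generates a four-condition count matrix and a synthetic genome from one
#' config, then runs every analysis stage: the seven pairwise NB contrasts,
#' antagonism and synergy classification, k-means induction patterns, GR
#' differential binding with assisted/unassisted classification, enhancer
#' cluster detection, cluster-level motif co-occurrence and H3K27ac cluster
#' signal. Everything downstream of the config is deterministic: the same
#' config (and its seed) reproduces every table byte for byte.
#'
#' @param config a [sim_config()].
#' @param thresholds an [analysis_thresholds()].
#' @param outdir optional directory; when given, all result tables are
#'   written as TSV.
#' @return list with the simulated inputs (\code{counts}, \code{genome}),
#'   DE results (\code{de}), \code{crosstalk} (antagonism/synergy calls,
#'   k-means), \code{binding} (site contrasts + GRBS classes) and
#'   \code{clusters} (detection, co-occurrence, signal).
#' @export
run_pipeline <- function(config, thresholds = analysis_thresholds(),
                         outdir = NULL) {
  sim <- simulate_counts(config)
  cm <- sim$counts

  de <- list(
    gluc_vs_nt = nb_wald_test(cm, "nt", "gluc"),
    cort_vs_nt = nb_wald_test(cm, "nt", "cort"),
    dual_vs_nt = nb_wald_test(cm, "nt", "dual"),
    gluc_vs_dual = nb_wald_test(cm, "dual", "gluc"),
    cort_vs_dual = nb_wald_test(cm, "dual", "cort"),
    dual_vs_gluc = nb_wald_test(cm, "gluc", "dual"),
    dual_vs_cort = nb_wald_test(cm, "cort", "dual")
  )

  r <- rpkm(cm)
  rmeans <- condition_means(r, cm$conditions)
  antag <- classify_antagonism(de$gluc_vs_nt, de$gluc_vs_dual,
                               de$cort_vs_nt, de$cort_vs_dual, thresholds)
  syn <- classify_synergy(de$dual_vs_nt, de$dual_vs_gluc, de$dual_vs_cort,
                          rmeans, thresholds)
  induced_any <- Reduce(`|`, lapply(de[c("gluc_vs_nt", "cort_vs_nt",
                                         "dual_vs_nt")], function(d) {
    call_differential(d, thresholds)$induced
  }))
  km <- NULL
  if (sum(induced_any) >= thresholds$k) {
    cmeans <- condition_means(sweep(cm$counts, 2, size_factors(cm), "/"),
                              cm$conditions)
    km <- kmeans_patterns(cmeans[induced_any, , drop = FALSE],
                          k = thresholds$k, seed = config$seed)
  }

  genome <- simulate_genome(config)
  gr_counts <- simulate_site_counts(genome, assay = "GR",
                                    halfwidth = thresholds$tf_halfwidth)
  binding <- list(
    cort_vs_nt = differential_binding(gr_counts, "nt", "cort", thresholds),
    gluc_vs_nt = differential_binding(gr_counts, "nt", "gluc", thresholds),
    dual_vs_cort = differential_binding(gr_counts, "cort", "dual", thresholds)
  )
  grbs_cls <- classify_grbs(binding$cort_vs_nt, binding$dual_vs_cort,
                            thresholds)

  focal <- genome$annotation$grbs
  focal_cls <- grbs_cls$table$class[match(focal$name, grbs_cls$table$id)]
  active <- focal[focal_cls %in% c("assisted", "unassisted"), , drop = FALSE]
  clusters <- detect_clusters(active, genome$annotation$dhs,
                              cluster_window = thresholds$cluster_window,
                              min_units = thresholds$min_units)
  cooc <- cluster_co_occurrence(clusters, genome$sequence,
                                genome$pwms$gre, genome$pwms$cre,
                                thresholds$logodds_offset)
  k27 <- list(
    nt = cluster_signal(clusters,
                        simulate_coverage(genome, "nt", "H3K27ac", 1),
                        halfwidth = thresholds$k27_halfwidth),
    gluc = cluster_signal(clusters,
                          simulate_coverage(genome, "gluc", "H3K27ac", 1),
                          halfwidth = thresholds$k27_halfwidth)
  )

  res <- list(counts = sim, genome = genome, de = de,
              crosstalk = list(antagonism = antag, synergy = syn,
                               kmeans = km, rpkm_means = rmeans),
              binding = c(binding, list(grbs = grbs_cls)),
              clusters = list(detection = clusters, co_occurrence = cooc,
                              h3k27ac = k27))
  if (!is.null(outdir)) write_pipeline(res, outdir)
  res
}

#' Write pipeline result tables as TSV
#'
#' @param res result of [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_pipeline <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (nm in names(res$de)) {
    wt(format(as.data.frame(res$de[[nm]]), digits = 10),
       paste0("de_", nm, ".tsv"))
  }
  wt(res$crosstalk$antagonism$calls, "antagonism_calls.tsv")
  wt(res$crosstalk$synergy$calls, "synergy_calls.tsv")
  if (!is.null(res$crosstalk$kmeans)) {
    wt(data.frame(id = names(res$crosstalk$kmeans$labels),
                  cluster = res$crosstalk$kmeans$labels), "kmeans_labels.tsv")
  }
  wt(res$binding$grbs$table, "grbs_classes.tsv")
  wt(res$clusters$detection$clusters, "clusters.tsv")
  wt(res$clusters$detection$units, "cluster_units.tsv")
  wt(data.frame(cluster_id = res$clusters$detection$clusters$cluster_id,
                co_occurrence = res$clusters$co_occurrence$per_cluster),
     "cluster_cooccurrence.tsv")
  for (cc in names(res$clusters$h3k27ac)) {
    wt(format(res$clusters$h3k27ac[[cc]]$per_cluster, digits = 10),
       paste0("cluster_signal_", cc, ".tsv"))
  }
  invisible(outdir)
}
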