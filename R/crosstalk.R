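#' Classify hormone antagonism
#'
#' A gene is antagonized by hormone 2 when it is induced by hormone 1 both
#' relative to the untreated control and relative to the dual treatment
#' (i.e. adding hormone 2 dampens the induction). Both classes are computed:
#' glucagon-induced genes antagonized by corticosterone
#' (\code{antag_by_cort}) and the reciprocal (\code{antag_by_gluc}). Each
#' contrast must be oriented so that its log2 fold change is the inducing
#' single treatment over the comparator.
#'
#' @param de_gluc_vs_nt,de_gluc_vs_dual,de_cort_vs_nt,de_cort_vs_dual
#'   \code{de_result} objects (log2fc = single treatment over nt / dual).
#' @param thresholds an [analysis_thresholds()].
#' @return list with character vectors \code{antag_by_cort} and
#'   \code{antag_by_gluc}, plus the per-gene logical table \code{calls}.
#' @export
classify_antagonism <- function(de_gluc_vs_nt, de_gluc_vs_dual,
                                de_cort_vs_nt, de_cort_vs_dual,
                                thresholds = analysis_thresholds()) {
  des <- list(de_gluc_vs_nt, de_gluc_vs_dual, de_cort_vs_nt, de_cort_vs_dual)
  ids <- des[[1]]$id
  for (d in des[-1]) {
    if (!identical(d$id, ids)) {
      stop("classify_antagonism: contrasts computed on different feature ",
           "universes")
    }
  }
  ind <- lapply(des, function(d) call_differential(d, thresholds)$induced)
  calls <- data.frame(
    id = ids,
    antag_by_cort = ind[[1]] & ind[[2]],
    antag_by_gluc = ind[[3]] & ind[[4]],
    stringsAsFactors = FALSE
  )
  list(antag_by_cort = ids[calls$antag_by_cort],
       antag_by_gluc = ids[calls$antag_by_gluc],
       calls = calls)
}

#' Classify synergistic induction
#'
#' A synergistically induced gene must satisfy four criteria: it is induced
#' in the dual treatment relative to (a) the untreated control, (b) the
#' glucagon single treatment and (c) the corticosterone single treatment
#' (each at the full fold-change and adjusted-p gates); and (d) its
#' expression increase in the dual treatment is strictly higher than the sum
#' of the increases of the two single treatments, on mean RPKM. Two variants
#' of (d) are provided: \code{"delta"} compares baseline-subtracted
#' increases, \code{(dual - nt) > (gluc - nt) + (cort - nt)};
#' \code{"raw"} compares absolute levels, \code{dual > gluc + cort}.
#'
#' @param de_dual_vs_nt,de_dual_vs_gluc,de_dual_vs_cort \code{de_result}
#'   objects oriented dual over comparator.
#' @param rpkm_means matrix features x conditions of replicate-mean RPKM,
#'   with columns \code{nt}, \code{gluc}, \code{cort}, \code{dual}.
#' @param thresholds an [analysis_thresholds()].
#' @param sum_rule \code{"delta"} (default) or \code{"raw"}.
#' @return list with \code{synergistic} (gene ids) and the per-gene table
#'   \code{calls} carrying the three DE criteria, the deltas and the sum
#'   test.
#' @export
classify_synergy <- function(de_dual_vs_nt, de_dual_vs_gluc, de_dual_vs_cort,
                             rpkm_means, thresholds = analysis_thresholds(),
                             sum_rule = c("delta", "raw")) {
  sum_rule <- match.arg(sum_rule)
  des <- list(de_dual_vs_nt, de_dual_vs_gluc, de_dual_vs_cort)
  ids <- des[[1]]$id
  for (d in des[-1]) {
    if (!identical(d$id, ids)) {
      stop("classify_synergy: contrasts computed on different feature ",
           "universes")
    }
  }
  need <- c("nt", "gluc", "cort", "dual")
  if (!all(need %in% colnames(rpkm_means))) {
    stop("classify_synergy: rpkm_means must have columns ",
         paste(need, collapse = ", "))
  }
  if (!all(ids %in% rownames(rpkm_means))) {
    stop("classify_synergy: rpkm_means missing some genes")
  }
  r <- rpkm_means[ids, , drop = FALSE]
  ind <- lapply(des, function(d) call_differential(d, thresholds)$induced)
  delta_gluc <- r[, "gluc"] - r[, "nt"]
  delta_cort <- r[, "cort"] - r[, "nt"]
  delta_dual <- r[, "dual"] - r[, "nt"]
  sum_pass <- if (sum_rule == "delta") {
    delta_dual > delta_gluc + delta_cort
  } else {
    r[, "dual"] > r[, "gluc"] + r[, "cort"]
  }
  calls <- data.frame(id = ids,
                      induced_dual_vs_nt = ind[[1]],
                      induced_dual_vs_gluc = ind[[2]],
                      induced_dual_vs_cort = ind[[3]],
                      delta_gluc = unname(delta_gluc),
                      delta_cort = unname(delta_cort),
                      delta_dual = unname(delta_dual),
                      sum_pass = unname(sum_pass),
                      stringsAsFactors = FALSE)
  calls$synergistic <- ind[[1]] & ind[[2]] & ind[[3]] & sum_pass
  list(synergistic = ids[calls$synergistic], calls = calls,
       sum_rule = sum_rule)
}

#' k-means clustering of induction patterns
#'
#' Clusters the 4-condition expression profiles of induced genes. Each
#' gene's profile (mean per condition) is z-scored across the four
#' conditions, then partitioned by k-means (fixed seed, \code{nstart}
#' restarts) so the same input and seed always yield the same labels.
#'
#' @param profiles matrix genes x conditions (e.g. normalized condition
#'   means for the union of induced genes).
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @return list with \code{labels} (named integer vector), \code{centroids}
#'   (k x conditions, z-score units) and \code{withinss}.
#' @export
kmeans_patterns <- function(profiles, k = 5, seed = 1, nstart = 10) {
  stopifnot(is.matrix(profiles))
  if (nrow(profiles) < k) stop("kmeans_patterns: fewer genes than clusters")
  mu <- rowMeans(profiles)
  sd <- apply(profiles, 1, stats::sd)
  z <- (profiles - mu) / ifelse(sd > 0, sd, 1)
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = nstart, iter.max = 100)
  labels <- km$cluster
  names(labels) <- rownames(profiles)
  list(labels = labels, centroids = km$centers, withinss = km$tot.withinss)
}

#' Overlap between two feature sets with hypergeometric enrichment
#'
#' Exact overlap counts plus a one-sided hypergeometric enrichment p-value
#' for drawing \code{|A intersect B|} or more of A when sampling \code{|B|}
#' features from the universe. The overlap percentage (of A found in B) is
#' printed to the nearest integer, except with one decimal place when it
#' reaches 99\%.
#'
#' @param set_a,set_b character vectors of feature ids.
#' @param universe character vector containing both sets.
#' @return list with \code{n_a}, \code{n_b}, \code{n_overlap},
#'   \code{a_only}, \code{b_only}, \code{p_hyper}, \code{pct_a_in_b},
#'   \code{pct_label}.
#' @export
overlap_summary <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("overlap_summary: sets must be subsets of the universe")
  }
  k <- length(intersect(set_a, set_b))
  n_a <- length(set_a); n_b <- length(set_b); n_u <- length(universe)
  p <- stats::phyper(k - 1, n_a, n_u - n_a, n_b, lower.tail = FALSE)
  pct <- 100 * k / n_a
  list(n_a = n_a, n_b = n_b, n_overlap = k,
       a_only = n_a - k, b_only = n_b - k,
       p_hyper = p, pct_a_in_b = pct, pct_label = format_pct(pct))
}
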