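#' Detect enhancer clusters around focal binding sites
#'
#' For each focal site (e.g. a GR binding site), the member enhancer units
#' are the DNase-hypersensitive intervals whose centers lie within
#' \code{+/- cluster_window} bp of the focal center (boundary inclusive,
#' center-to-center). Focal sites with no unit in the window are excluded
#' (and counted); sites with at least \code{min_units} units form clusters.
#' The unit physically containing the focal center is flagged so that
#' cluster-level analyses can exclude it.
#'
#' @param focal_sites interval data.frame (names used as cluster ids).
#' @param dhs interval data.frame of enhancer units.
#' @param cluster_window half-window in bp.
#' @param min_units minimum units for cluster status.
#' @return list of class \code{enhancer_clusters}: \code{clusters} (focal id,
#'   chrom, focal center, n_units), \code{units} (cluster id, unit interval,
#'   \code{contains_focal} flag), \code{n_excluded_no_units},
#'   \code{n_excluded_below_min}, \code{unit_count_distribution} (table over
#'   all focal sites with >= 1 unit).
#' @export
detect_clusters <- function(focal_sites, dhs, cluster_window = 12500,
                            min_units = 2) {
  validate_intervals(focal_sites, "focal_sites")
  validate_intervals(dhs, "dhs")
  fc <- interval_center(focal_sites)
  dc <- interval_center(dhs)
  ids <- if (all(focal_sites$name != ".")) focal_sites$name else
    sprintf("focal_%d", seq_len(nrow(focal_sites)))
  units <- list(); clusters <- list()
  n_units_all <- integer(nrow(focal_sites))
  for (i in seq_len(nrow(focal_sites))) {
    j <- which(dhs$chrom == focal_sites$chrom[i] &
                 abs(dc - fc[i]) <= cluster_window)
    n_units_all[i] <- length(j)
    if (length(j) < min_units) next
    u <- dhs[j, c("chrom", "start", "end"), drop = FALSE]
    u$cluster_id <- ids[i]
    u$contains_focal <- u$start <= fc[i] & fc[i] < u$end
    units[[length(units) + 1]] <- u
    clusters[[length(clusters) + 1]] <- data.frame(
      cluster_id = ids[i], chrom = focal_sites$chrom[i],
      focal_center = fc[i], n_units = length(j),
      stringsAsFactors = FALSE)
  }
  structure(list(
    clusters = if (length(clusters)) do.call(rbind, clusters) else
      data.frame(cluster_id = character(), chrom = character(),
                 focal_center = numeric(), n_units = integer()),
    units = if (length(units)) do.call(rbind, units) else
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 cluster_id = character(), contains_focal = logical()),
    n_excluded_no_units = sum(n_units_all == 0),
    n_excluded_below_min = sum(n_units_all > 0 & n_units_all < min_units),
    unit_count_distribution = table(n_units_all[n_units_all > 0])
  ), class = "enhancer_clusters")
}

#' @export
print.enhancer_clusters <- function(x, ...) {
  cat(sprintf(paste0("enhancer_clusters: %d clusters (%d units); ",
                     "%d focal sites excluded with no units, ",
                     "%d below the unit minimum\n"),
              nrow(x$clusters), nrow(x$units), x$n_excluded_no_units,
              x$n_excluded_below_min))
  invisible(x)
}

#' Motif co-occurrence across enhancer clusters
#'
#' A cluster is positive when both motifs hit somewhere in the union of its
#' member-unit intervals; intermediate inaccessible sequence between units
#' is never scanned. Because every cluster scans at least as much sequence
#' as its focal unit alone, the cluster-level percentage can only be larger
#' than or equal to the focal-unit-level percentage.
#'
#' @param clusters an \code{enhancer_clusters} object.
#' @param genome named list of chromosome sequences.
#' @param motif_a,motif_b \code{pwm} objects.
#' @param threshold_offset log-odds relaxation as in [pwm_logodds_scan()].
#' @param focal_only if TRUE, scan only the unit containing the focal site
#'   (for the single-enhancer comparison).
#' @return list with \code{per_cluster} (logical), \code{fraction},
#'   \code{percent}.
#' @export
cluster_co_occurrence <- function(clusters, genome, motif_a, motif_b,
                                  threshold_offset = 3, focal_only = FALSE) {
  stopifnot(inherits(clusters, "enhancer_clusters"))
  if (!nrow(clusters$clusters)) stop("cluster_co_occurrence: no clusters")
  both <- vapply(clusters$clusters$cluster_id, function(cid) {
    u <- clusters$units[clusters$units$cluster_id == cid, , drop = FALSE]
    if (focal_only) u <- u[u$contains_focal, , drop = FALSE]
    if (!nrow(u)) return(FALSE)
    hit <- c(a = FALSE, b = FALSE)
    for (k in seq_len(nrow(u))) {
      s <- substr(genome[[u$chrom[k]]], u$start[k] + 1, u$end[k])
      if (!hit["a"] &&
          nrow(pwm_logodds_scan(s, motif_a, threshold_offset)) > 0) {
        hit["a"] <- TRUE
      }
      if (!hit["b"] &&
          nrow(pwm_logodds_scan(s, motif_b, threshold_offset)) > 0) {
        hit["b"] <- TRUE
      }
      if (all(hit)) break
    }
    all(hit)
  }, TRUE)
  frac <- mean(both)
  list(per_cluster = unname(both), fraction = frac,
       percent = format_pct(100 * frac))
}

#' Quantify signal over enhancer-cluster units
#'
#' Tag quantification (center +/- halfwidth) for every member unit of every
#' cluster, with optional exclusion of the unit containing the focal site
#' (to test whether activation spans the cluster rather than the focal
#' enhancer alone). Clusters left with no units after the exclusion are
#' reported empty and flagged.
#'
#' @param clusters an \code{enhancer_clusters} object.
#' @param track a \code{coverage_track}.
#' @param halfwidth quantification half-window in bp (500 for H3K27ac,
#'   200 for TF/DNase).
#' @param exclude_focal_unit drop units flagged \code{contains_focal}.
#' @param normalize normalize to tags per 1e7 (default TRUE: cluster signal
#'   is compared across conditions).
#' @return list with \code{per_unit} (units table + \code{tags}) and
#'   \code{per_cluster} (cluster id, n_units_used, mean unit signal, flag
#'   \code{empty}).
#' @export
cluster_signal <- function(clusters, track, halfwidth = 500,
                           exclude_focal_unit = FALSE, normalize = TRUE) {
  stopifnot(inherits(clusters, "enhancer_clusters"))
  u <- clusters$units
  if (exclude_focal_unit) u <- u[!u$contains_focal, , drop = FALSE]
  u$tags <- if (nrow(u)) {
    quantify_tags(u, track, halfwidth, normalize = normalize)
  } else {
    numeric(0)
  }
  per_cluster <- do.call(rbind, lapply(clusters$clusters$cluster_id,
                                       function(cid) {
    tu <- u$tags[u$cluster_id == cid]
    data.frame(cluster_id = cid, n_units_used = length(tu),
               mean_signal = if (length(tu)) mean(tu) else NA_real_,
               empty = length(tu) == 0, stringsAsFactors = FALSE)
  }))
  rownames(per_cluster) <- NULL
  list(per_unit = u, per_cluster = per_cluster)
}
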