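#' Simplified local-Poisson peak caller
#'
#' A deliberately simple sliding-window caller for synthetic or desk-scale
#' coverage: the genome is tiled with non-overlapping windows, each window's
#' tag count is tested against a Poisson null whose rate is the maximum of
#' the genome-wide background, the local background estimated in 1 kb and
#' 10 kb flanks, and (when given) a control track's rate. Window p-values
#' are BH-adjusted; significant adjacent windows are merged into peaks whose
#' summit is the maximum-coverage position.
#'
#' @param track a \code{coverage_track}.
#' @param control optional control \code{coverage_track}.
#' @param window window width in bp.
#' @param padj_max BH-adjusted significance cutoff.
#' @return interval data.frame of peaks with \code{score} = -log10(padj of
#'   the best window), and a \code{summit} column (0-based position).
#' @export
call_peaks <- function(track, control = NULL, window = 200,
                       padj_max = 0.05) {
  stopifnot(window > 0)
  peaks <- list()
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    L <- length(v)
    if (L < window) next
    nw <- L %/% window
    idx <- rep(seq_len(nw), each = window)
    counts <- as.numeric(tapply(v[seq_len(nw * window)], idx, sum))
    genome_rate <- sum(v) / L * window
    # local lambda from flanking windows (1 kb and 10 kb each side)
    lam_flank <- function(flank_bp) {
      k <- max(1L, round(flank_bp / window))
      cs <- c(0, cumsum(counts))
      lo <- pmax(seq_len(nw) - k, 1L); hi <- pmin(seq_len(nw) + k, nw)
      tot <- cs[hi + 1] - cs[lo]
      n <- hi - lo + 1
      (tot - counts) / pmax(n - 1, 1)
    }
    lambda <- pmax(genome_rate, lam_flank(1000), lam_flank(10000))
    if (!is.null(control)) {
      cv <- control$values[[ch]]
      if (!is.null(cv)) {
        scale <- track$total_tags / max(control$total_tags, 1)
        ctl_rate <- sum(cv) / length(cv) * window * scale
        lambda <- pmax(lambda, ctl_rate)
      }
    }
    p <- stats::ppois(counts - 1, lambda, lower.tail = FALSE)
    padj <- bh_adjust(p)
    sig <- padj <= padj_max
    if (!any(sig)) next
    runs <- rle(sig)
    pos <- cumsum(c(1, runs$lengths))
    for (r in which(runs$values)) {
      w0 <- pos[r]; w1 <- pos[r + 1] - 1
      start <- (w0 - 1) * window
      end <- min(w1 * window, L)
      seg <- v[(start + 1):end]
      peaks[[length(peaks) + 1]] <- data.frame(
        chrom = ch, start = start, end = end, name = ".",
        score = -log10(max(min(padj[w0:w1]), 1e-300)), strand = ".",
        summit = start + which.max(seg) - 1, stringsAsFactors = FALSE)
    }
  }
  if (!length(peaks)) {
    out <- gintervals(character(), integer(), integer())[0, ]
    out$summit <- integer()
    return(out)
  }
  out <- do.call(rbind, peaks)
  out$name <- sprintf("peak_%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Replicate-reproducible sites
#'
#' Merges per-replicate peak sets and keeps merged sites supported by at
#' least \code{min_support} replicates; sites overlapping a blacklist
#' interval are removed.
#'
#' @param peak_sets named list of interval data.frames, one per replicate.
#' @param min_support minimum number of supporting replicates.
#' @param blacklist optional interval data.frame of excluded regions.
#' @return merged interval data.frame with a \code{support} column.
#' @export
reproducible_sites <- function(peak_sets, min_support = 2,
                               blacklist = NULL) {
  if (length(peak_sets) < 2) stop("reproducible_sites: need >= 2 replicates")
  if (is.null(names(peak_sets))) {
    names(peak_sets) <- paste0("rep", seq_along(peak_sets))
  }
  merged <- merge_sites(peak_sets)
  merged$support <- merged$n_sources
  merged <- merged[merged$support >= min_support, , drop = FALSE]
  if (!is.null(blacklist) && nrow(blacklist) && nrow(merged)) {
    bad <- vapply(seq_len(nrow(merged)), function(i) {
      any(blacklist$chrom == merged$chrom[i] &
            blacklist$start < merged$end[i] &
            blacklist$end > merged$start[i])
    }, TRUE)
    merged <- merged[!bad, , drop = FALSE]
  }
  rownames(merged) <- NULL
  merged
}

#' Window counts at sites across a panel of coverage tracks
#'
#' Builds a site-by-sample \code{count_matrix} by summing tags in
#' \code{center +/- halfwidth} for each sample's track. Input counts stay
#' raw (integer); depth normalization is delegated to the test's
#' \code{norm = "total_tags"} option.
#'
#' @param sites interval data.frame (one row per site; names used as ids).
#' @param tracks named list of \code{coverage_track}, one per sample.
#' @param conditions named condition map over the track names.
#' @param halfwidth quantification half-window in bp.
#' @return a \code{count_matrix}; per-sample library sizes (total track
#'   tags) are attached as attribute \code{"lib_sizes"}.
#' @export
site_count_matrix <- function(sites, tracks, conditions, halfwidth = 200) {
  ids <- if (all(sites$name != ".")) sites$name else
    sprintf("site_%d", seq_len(nrow(sites)))
  m <- vapply(tracks, function(tr) {
    round(quantify_tags(sites, tr, halfwidth))
  }, numeric(nrow(sites)))
  rownames(m) <- ids
  cm <- count_matrix(m, conditions)
  attr(cm, "lib_sizes") <- vapply(tracks, function(tr) tr$total_tags, 0)
  cm
}

#' Differential binding at sites
#'
#' Negative-binomial Wald contrast on site window counts with total-tag
#' normalization (the TF-ChIP convention: site counts are scaled by each
#' sample's total sequencing depth, not by median-of-ratios size factors,
#' because most of a TF track is background). A site is increased when it
#' passes the standard fold-change and adjusted-p gates.
#'
#' @param site_counts a \code{count_matrix} from [site_count_matrix()].
#' @param condition_a,condition_b contrast (log2fc = B over A).
#' @param thresholds an [analysis_thresholds()].
#' @param norm normalization mode passed to [nb_wald_test()].
#' @return \code{de_result} with \code{induced} / \code{repressed} columns
#'   (from [call_differential()]); \code{increased} is an alias for induced.
#' @export
differential_binding <- function(site_counts, condition_a, condition_b,
                                 thresholds = analysis_thresholds(),
                                 norm = "total_tags") {
  lib <- attr(site_counts, "lib_sizes")
  de <- if (norm == "total_tags" && !is.null(lib)) {
    # normalize by full-track sequencing depth, not by window-count totals
    nb_wald_test(site_counts, condition_a, condition_b, sf_override = lib)
  } else {
    nb_wald_test(site_counts, condition_a, condition_b, norm = norm)
  }
  de <- call_differential(de, thresholds)
  de$increased <- de$induced
  de
}

#' Classify GR binding sites as assisted or unassisted
#'
#' Assisted sites show a significant increase in binding under the dual
#' treatment compared to the single corticosterone treatment. Unassisted
#' sites are corticosterone-increased sites (vs untreated) that are
#' \emph{not} further increased by the dual treatment. All remaining sites
#' are \code{other}. The classes are disjoint and exhaustive.
#'
#' @param de_cort_vs_nt,de_dual_vs_cort \code{de_result} objects on the same
#'   site universe, oriented cort over nt and dual over cort.
#' @param thresholds an [analysis_thresholds()].
#' @return list with \code{table} (site id, class, supporting calls),
#'   \code{assisted}, \code{unassisted} (id vectors) and \code{summary}
#'   (counts plus the unassisted percentage among cort-increased sites,
#'   formatted by the package's rounding convention).
#' @export
classify_grbs <- function(de_cort_vs_nt, de_dual_vs_cort,
                          thresholds = analysis_thresholds()) {
  if (!identical(de_cort_vs_nt$id, de_dual_vs_cort$id)) {
    stop("classify_grbs: contrasts on different site universes")
  }
  inc_cort <- call_differential(de_cort_vs_nt, thresholds)$induced
  inc_dual <- call_differential(de_dual_vs_cort, thresholds)$induced
  class <- ifelse(inc_dual, "assisted",
                  ifelse(inc_cort, "unassisted", "other"))
  tab <- data.frame(id = de_cort_vs_nt$id, class = class,
                    increased_cort_vs_nt = inc_cort,
                    increased_dual_vs_cort = inc_dual,
                    stringsAsFactors = FALSE)
  n_cort_inc <- sum(inc_cort)
  n_unassisted <- sum(class == "unassisted")
  pct <- if (n_cort_inc > 0) 100 * n_unassisted / n_cort_inc else NA_real_
  list(table = tab,
       assisted = tab$id[class == "assisted"],
       unassisted = tab$id[class == "unassisted"],
       summary = list(n_assisted = sum(class == "assisted"),
                      n_unassisted = n_unassisted,
                      n_other = sum(class == "other"),
                      n_cort_increased = n_cort_inc,
                      pct_unassisted_of_cort_increased = pct,
                      pct_label = format_pct(pct)))
}

#' Promoter-proximal site annotation
#'
#' A site is promoter proximal when its center falls within the
#' strand-oriented window (default -1,000 to +100 bp) around any TSS;
#' negative offsets are upstream of the TSS in the gene's orientation.
#'
#' @param sites interval data.frame.
#' @param tss stranded interval data.frame of transcription start sites (the
#'   TSS position is the interval start for + genes and \code{end - 1} for -
#'   genes).
#' @param window c(upstream, downstream) signed offsets in bp.
#' @return list with \code{proximal} (logical per site),
#'   \code{fraction_proximal} and \code{fraction_remote}.
#' @export
promoter_proximal <- function(sites, tss, window = c(-1000, 100)) {
  validate_intervals(sites, "sites")
  validate_intervals(tss, "tss")
  if (any(tss$strand == ".")) {
    stop("promoter_proximal: TSS must be stranded")
  }
  pos <- ifelse(tss$strand == "+", tss$start, tss$end - 1)
  lo <- ifelse(tss$strand == "+", pos + window[1], pos - window[2])
  hi <- ifelse(tss$strand == "+", pos + window[2], pos - window[1])
  centers <- interval_center(sites)
  prox <- vapply(seq_len(nrow(sites)), function(i) {
    any(tss$chrom == sites$chrom[i] & centers[i] >= lo & centers[i] <= hi)
  }, TRUE)
  list(proximal = prox, fraction_proximal = mean(prox),
       fraction_remote = 1 - mean(prox))
}

#' Nearest gene per site with class composition
#'
#' Assigns each site to the gene with the nearest TSS (center distance, ties
#' to the smaller coordinate) and summarizes what fraction of sites have a
#' nearest gene in each supplied gene class.
#'
#' @param sites interval data.frame.
#' @param tss interval data.frame with gene ids in \code{name}.
#' @param gene_classes optional named character vector gene id -> class.
#' @return list with \code{assignment} (per-site nearest gene and distance)
#'   and, when classes are given, \code{composition} (fractions summing
#'   to 1 over assigned sites).
#' @export
nearest_gene <- function(sites, tss, gene_classes = NULL) {
  nd <- nearest_distance(sites, tss)
  out <- list(assignment = data.frame(site = seq_len(nrow(sites)),
                                      gene = nd$nearest,
                                      distance = nd$distance,
                                      stringsAsFactors = FALSE))
  if (!is.null(gene_classes)) {
    cls <- gene_classes[nd$nearest]
    cls[is.na(cls)] <- "unclassified"
    comp <- table(cls) / sum(!is.na(nd$nearest))
    out$composition <- as.list(comp)
  }
  out
}
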