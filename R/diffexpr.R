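#' Analysis thresholds
#'
#' The fixed cutoffs used throughout the pipeline. Defaults follow the
#' study's conventions: differential calls require linear fold change >= 1.5
#' and BH-adjusted p <= 0.05; k-means uses k = 5; enhancer clusters are
#' searched +/- 12,500 bp around focal sites and require >= 2 DNase units;
#' motif scanning relaxes the PWM threshold by 3 log-odds units; promoter
#' windows span -1,000 to +100 bp of the TSS; tag quantification uses
#' +/- 200 bp for TF/DNase and +/- 500 bp for H3K27ac; aggregate profiles use
#' +/- 4,000 bp in 10 bp bins.
#'
#' @param fc_min minimum linear fold change.
#' @param padj_max maximum BH-adjusted p.
#' @param k number of k-means clusters.
#' @param cluster_window enhancer-cluster search half-window, bp.
#' @param min_units minimum DNase units for cluster status.
#' @param logodds_offset motif-threshold relaxation, log-odds units.
#' @param promoter_window c(upstream, downstream) of the TSS, bp (signed).
#' @param tf_halfwidth,k27_halfwidth tag-quantification half-windows, bp.
#' @param profile_halfwidth,profile_bin aggregate-profile geometry, bp.
#' @return list of class \code{analysis_thresholds}.
#' @export
analysis_thresholds <- function(fc_min = 1.5, padj_max = 0.05, k = 5,
                                cluster_window = 12500, min_units = 2,
                                logodds_offset = 3,
                                promoter_window = c(-1000, 100),
                                tf_halfwidth = 200, k27_halfwidth = 500,
                                profile_halfwidth = 4000, profile_bin = 10) {
  stopifnot(fc_min > 1, padj_max > 0, padj_max < 1, k >= 1,
            cluster_window > 0, min_units >= 1, tf_halfwidth > 0,
            k27_halfwidth > 0, promoter_window[1] < promoter_window[2])
  structure(list(fc_min = fc_min, padj_max = padj_max, k = k,
                 cluster_window = cluster_window, min_units = min_units,
                 logodds_offset = logodds_offset,
                 promoter_window = promoter_window,
                 tf_halfwidth = tf_halfwidth, k27_halfwidth = k27_halfwidth,
                 profile_halfwidth = profile_halfwidth,
                 profile_bin = profile_bin),
            class = "analysis_thresholds")
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over features of the ratio between that
#' sample's count and the feature's geometric mean across samples, computed
#' on features with all-positive counts. Identical samples get factor 1.
#'
#' @param x a \code{count_matrix} or integer matrix.
#' @param pseudo_reference if TRUE, fall back to adding 0.5 to all counts
#'   when no feature is positive in every sample.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(x, pseudo_reference = FALSE) {
  m <- if (inherits(x, "count_matrix")) x$counts else x
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    if (!pseudo_reference) {
      stop("size_factors: no feature has positive counts in every sample; ",
           "re-run with pseudo_reference = TRUE to use a 0.5-count fallback")
    }
    m <- m + 0.5
    pos <- rep(TRUE, nrow(m))
  }
  mp <- m[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(mp)))
  apply(mp, 2, function(col) stats::median(col / geo))
}

# Pooled method-of-moments dispersion per feature:
# Var(y/s) ~ mu * mean(1/s) + alpha * mu^2 within each group.
mom_dispersion <- function(m, sf, group) {
  v_pool <- numeric(nrow(m))
  shot <- numeric(nrow(m))
  m2 <- numeric(nrow(m))
  for (g in unique(group)) {
    j <- which(group == g)
    if (length(j) < 2) next
    z <- sweep(m[, j, drop = FALSE], 2, sf[j], "/")
    mu <- rowMeans(z)
    v <- rowSums((z - mu)^2) / (length(j) - 1)
    w <- length(j) - 1
    v_pool <- v_pool + w * v
    shot <- shot + w * mu * mean(1 / sf[j])
    m2 <- m2 + w * mu^2
  }
  pmax((v_pool - shot) / pmax(m2, 1e-12), 1e-8)
}

# Newton fit (on log scale) of one NB group mean with offsets sf and fixed
# per-feature dispersion alpha; vectorized over features. Returns the log
# mean and the Fisher information of the log-mean coefficient.
nb_fit_group <- function(m, sf, alpha) {
  zero <- rowSums(m) == 0
  init <- rowMeans(sweep(m, 2, sf, "/"))
  init[zero] <- 0.5 / sum(sf) # continuity correction for empty groups
  lq <- log(init)
  for (it in 1:40) {
    mu <- exp(lq) %o% sf
    denom <- 1 + alpha * mu
    score <- rowSums((m - mu) / denom)
    info <- rowSums(mu / denom)
    step <- pmin(pmax(score / pmax(info, 1e-12), -2), 2)
    step[zero] <- 0 # hold corrected estimate for all-zero groups
    lq <- lq + step
    if (max(abs(step)) < 1e-12) break
  }
  mu <- exp(lq) %o% sf
  list(lq = lq, info = rowSums(mu / (1 + alpha * mu)))
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' Per-feature NB generalized linear model with log link and a two-group
#' design. Dispersions are gene-wise method-of-moments estimates shrunk (in
#' log space) toward a parametric mean-dispersion trend
#' \eqn{\alpha(\mu) = a_0 + a_1/\mu}; with the default shrinkage weight the
#' per-feature estimate sits close to the trend, so the Wald statistic on
#' the log2 fold change is referred to a t distribution with moderated
#' degrees of freedom \code{4 * (m - 2)} (the residual df plus prior df
#' contributed by the genome-wide trend), which calibrates the test at
#' small replicate numbers.
#'
#' With median-of-ratios normalization, a second pass re-estimates the size
#' factors on features that look non-differential in the first pass
#' (p > 0.2). When a large fraction of features responds in one direction,
#' the plain median ratio is pulled off the non-differential mode and fold
#' changes are biased toward zero; restricting to apparent nulls removes
#' that contamination (the same concern DESeq2's \code{controlGenes} and
#' edgeR's trimming address).
#'
#' @param x a \code{count_matrix}.
#' @param condition_a,condition_b condition labels; the reported log2 fold
#'   change is B over A.
#' @param norm \code{"size_factors"} (median-of-ratios) or
#'   \code{"total_tags"} (per-sample totals, the TF-ChIP convention).
#' @param shrink_weight weight of the trend in the log-space dispersion
#'   shrinkage (0 = pure gene-wise, 1 = pure trend).
#' @param sf_override optional named per-sample normalization factors (e.g.
#'   full-track library sizes for site window counts); overrides \code{norm}.
#' @param refine_norm re-estimate size factors on apparent null features
#'   (only applies to \code{norm = "size_factors"}).
#' @return data.frame (class \code{de_result}): \code{id},
#'   \code{base_mean} (mean of normalized counts over the contrast's
#'   samples), \code{log2fc}, \code{p}, \code{padj}, \code{status}
#'   (\code{"ok"} or \code{"untestable"} for all-zero features, which get
#'   log2fc 0 and p 1).
#' @export
nb_wald_test <- function(x, condition_a, condition_b,
                         norm = c("size_factors", "total_tags"),
                         shrink_weight = 0.9, sf_override = NULL,
                         refine_norm = TRUE) {
  stopifnot(inherits(x, "count_matrix"))
  norm <- match.arg(norm)
  sel <- names(x$conditions)[x$conditions %in% c(condition_a, condition_b)]
  if (length(sel) < 4) stop("nb_wald_test: need >= 2 replicates per condition")
  m <- x$counts[, sel, drop = FALSE]
  group <- x$conditions[sel]
  if (sum(group == condition_a) < 2 || sum(group == condition_b) < 2) {
    stop("nb_wald_test: need >= 2 replicates per condition")
  }
  sf <- if (!is.null(sf_override)) {
    tot <- sf_override[sel]
    tot / exp(mean(log(pmax(tot, 1))))
  } else if (norm == "total_tags") {
    tot <- colSums(m)
    tot / exp(mean(log(pmax(tot, 1))))
  } else {
    size_factors(m, pseudo_reference = TRUE)
  }
  res <- nb_fit_contrast(m, group, condition_a, condition_b, sf,
                         shrink_weight)
  if (refine_norm && norm == "size_factors" && is.null(sf_override)) {
    nulls <- which(res$p > 0.2)
    if (length(nulls) >= 50) {
      sf2 <- try(size_factors(m[nulls, , drop = FALSE],
                              pseudo_reference = TRUE), silent = TRUE)
      if (!inherits(sf2, "try-error")) {
        res <- nb_fit_contrast(m, group, condition_a, condition_b, sf2,
                               shrink_weight)
      }
    }
  }
  attr(res, "contrast") <- c(A = condition_a, B = condition_b)
  class(res) <- c("de_result", "data.frame")
  res
}

# Core fit for one contrast given fixed size factors.
nb_fit_contrast <- function(m, group, condition_a, condition_b, sf,
                            shrink_weight) {
  base_mean <- rowMeans(sweep(m, 2, sf, "/"))
  a_gene <- mom_dispersion(m, sf, group)
  # parametric trend alpha(mu) = a0 + a1/mu on informative features
  ok <- base_mean > 1
  trend <- rep(if (any(ok)) stats::median(a_gene[ok]) else
    stats::median(a_gene), nrow(m))
  if (sum(ok) > 10) {
    fit <- try(stats::lm(a_gene[ok] ~ I(1 / base_mean[ok])), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      co <- pmax(stats::coef(fit), 0)
      trend <- pmax(co[1] + co[2] / pmax(base_mean, 1e-8), 1e-8)
    }
  }
  alpha <- exp((1 - shrink_weight) * log(a_gene) + shrink_weight * log(trend))
  ja <- group == condition_a
  fa <- nb_fit_group(m[, ja, drop = FALSE], sf[ja], alpha)
  fb <- nb_fit_group(m[, !ja, drop = FALSE], sf[!ja], alpha)
  log2fc <- (fb$lq - fa$lq) / log(2)
  se <- sqrt(1 / pmax(fa$info, 1e-12) + 1 / pmax(fb$info, 1e-12)) / log(2)
  df <- 4 * (ncol(m) - 2)
  p <- 2 * stats::pt(-abs(log2fc / se), df = df)
  untestable <- rowSums(m) == 0
  log2fc[untestable] <- 0
  p[untestable] <- 1
  res <- data.frame(id = rownames(m), base_mean = base_mean,
                    log2fc = log2fc, p = p,
                    padj = bh_adjust(replace(p, untestable, NA)),
                    status = ifelse(untestable, "untestable", "ok"),
                    stringsAsFactors = FALSE, row.names = NULL)
  res$padj[untestable] <- 1
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, capped at 1, order-preserving on the original
#' index. NA entries propagate as NA and are excluded from the number of
#' tests.
#'
#' @param p numeric vector of p-values in [0, 1] (NAs allowed).
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("bh_adjust: p outside [0,1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Call differential features from a test result
#'
#' Induced means linear fold change >= \code{fc_min} and padj <=
#' \code{padj_max} (both boundaries inclusive, as printed); repressed is the
#' symmetric condition with fold change <= 1/\code{fc_min}.
#'
#' @param de a \code{de_result} from [nb_wald_test()].
#' @param thresholds an [analysis_thresholds()] object.
#' @return the input with logical columns \code{induced} and
#'   \code{repressed}; attribute \code{"thresholds"} records the gates.
#' @export
call_differential <- function(de, thresholds = analysis_thresholds()) {
  fc <- 2^de$log2fc
  eps <- 1e-9
  de$induced <- fc >= thresholds$fc_min - eps &
    de$padj <= thresholds$padj_max + eps & de$status == "ok"
  de$repressed <- fc <= 1 / thresholds$fc_min + eps &
    de$padj <= thresholds$padj_max + eps & de$status == "ok"
  attr(de, "thresholds") <- thresholds
  de
}
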