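#' Per-base coverage tracks
#'
#' A coverage track stores, per chromosome, the number of sequencing tags
#' covering each base (a plain numeric vector; position \code{i} of the
#' vector is the 0-based base \code{i - 1}). \code{total_tags} is the sum
#' over all chromosomes and is used for depth normalization.
#'
#' @param values named list of non-negative numeric vectors, one per
#'   chromosome.
#' @return An object of class \code{coverage_track}.
#' @export
coverage_track <- function(values) {
  stopifnot(is.list(values), length(names(values)) == length(values))
  for (v in values) {
    if (any(v < 0)) stop("coverage_track: negative coverage value")
  }
  structure(list(values = values,
                 total_tags = sum(vapply(values, sum, 0))),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$values), "chromosome(s),",
      format(x$total_tags, big.mark = ","), "total tags\n")
  invisible(x)
}

#' Read / write bedGraph coverage
#'
#' Plain 4-column bedGraph (chrom, start, end, value; 0-based half-open).
#' \code{read_bedgraph} needs the chromosome lengths to allocate the dense
#' per-base vectors; bases not covered by any record are 0.
#'
#' @param path file path.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @rdname bedgraph_io
#' @export
read_bedgraph <- function(path, chrom_lengths) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  vals <- lapply(names(chrom_lengths), function(ch) {
    v <- numeric(chrom_lengths[[ch]])
    rows <- df[df$chrom == ch, ]
    for (i in seq_len(nrow(rows))) {
      v[(rows$start[i] + 1):rows$end[i]] <- rows$value[i]
    }
    v
  })
  names(vals) <- names(chrom_lengths)
  coverage_track(vals)
}

#' @param track a \code{coverage_track}.
#' @rdname bedgraph_io
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$values)) {
    r <- rle(track$values[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                         format(r$values[keep], trim = TRUE,
                                scientific = FALSE)), con)
    }
  }
  invisible(path)
}

#' Tag counts in fixed windows around site centers
#'
#' Sums coverage in \code{[center - halfwidth, center + halfwidth)} for each
#' site, clipping at chromosome edges. Sites on chromosomes absent from the
#' track get 0 with a warning.
#'
#' @param sites interval data.frame.
#' @param track a \code{coverage_track}.
#' @param halfwidth window half-width in bp (e.g. 200 for TF ChIP, 500 for
#'   H3K27ac).
#' @param normalize if TRUE, scale counts to tags per 1e7 total tags
#'   (cross-condition comparability); default FALSE returns raw sums.
#' @return numeric vector, one value per site.
#' @export
quantify_tags <- function(sites, track, halfwidth, normalize = FALSE) {
  validate_intervals(sites, "sites")
  stopifnot(halfwidth > 0)
  centers <- interval_center(sites)
  out <- numeric(nrow(sites))
  missing_chrom <- setdiff(unique(sites$chrom), names(track$values))
  if (length(missing_chrom)) {
    warning("quantify_tags: chromosome(s) absent from track: ",
            paste(missing_chrom, collapse = ", "), " (counts set to 0)")
  }
  for (ch in intersect(unique(sites$chrom), names(track$values))) {
    v <- track$values[[ch]]
    cs0 <- c(0, cumsum(v))
    idx <- which(sites$chrom == ch)
    lo <- pmax(centers[idx] - halfwidth, 0)        # 0-based inclusive
    hi <- pmin(centers[idx] + halfwidth, length(v)) # 0-based exclusive
    out[idx] <- ifelse(hi > lo, cs0[hi + 1] - cs0[lo + 1], 0)
  }
  if (normalize && track$total_tags > 0) {
    out <- out * 1e7 / track$total_tags
  }
  out
}

#' Aggregate tag-density profile around anchors
#'
#' Mean coverage per fixed-width bin across all anchors, over the window
#' \code{[center - halfwidth, center + halfwidth)}. Minus-strand anchors are
#' flipped so that bins run 5' to 3'. Anchors near a chromosome edge
#' contribute only the bins they cover.
#'
#' @param anchors interval data.frame (strand used for flipping).
#' @param track a \code{coverage_track}.
#' @param halfwidth window half-width in bp; must be divisible by \code{bin}.
#' @param bin bin width in bp.
#' @return data.frame with \code{offset} (bin start relative to center) and
#'   \code{mean_tags} (mean tags per bin across anchors).
#' @export
aggregate_profile <- function(anchors, track, halfwidth = 4000, bin = 10) {
  validate_intervals(anchors, "anchors")
  if (!nrow(anchors)) stop("aggregate_profile: no anchors")
  if (halfwidth %% bin != 0) stop("halfwidth must be divisible by bin")
  nb <- 2 * halfwidth / bin
  centers <- interval_center(anchors)
  strand <- if ("strand" %in% names(anchors)) anchors$strand else
    rep(".", nrow(anchors))
  sums <- numeric(nb)
  counts <- numeric(nb)
  for (i in seq_len(nrow(anchors))) {
    v <- track$values[[anchors$chrom[i]]]
    if (is.null(v)) next
    L <- length(v)
    starts <- centers[i] - halfwidth + (seq_len(nb) - 1) * bin # 0-based
    ends <- starts + bin
    ok <- starts >= 0 & ends <= L
    if (!any(ok)) next
    cs0 <- c(0, cumsum(v))
    binsum <- cs0[ends[ok] + 1] - cs0[starts[ok] + 1]
    slots <- which(ok)
    if (strand[i] == "-") slots <- nb + 1 - slots
    sums[slots] <- sums[slots] + binsum
    counts[slots] <- counts[slots] + 1
  }
  data.frame(offset = -halfwidth + (seq_len(nb) - 1) * bin,
             mean_tags = ifelse(counts > 0, sums / counts, NA_real_))
}
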