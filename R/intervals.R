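#' Construct a set of genomic intervals
#'
#' Intervals follow BED conventions throughout the package: coordinates are
#' 0-based, half-open (\code{[start, end)}), so an interval ending where the
#' next begins does not overlap it. The interval center is
#' \code{start + floor((end - start) / 2)}.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, \code{0 <= start < end}.
#' @param name optional feature names (default \code{"."}).
#' @param score optional numeric scores (default 0).
#' @param strand optional strand, one of \code{"+"}, \code{"-"}, \code{"."}.
#' @return A \code{data.frame} with columns \code{chrom, start, end, name,
#'   score, strand}.
#' @export
gintervals <- function(chrom, start, end, name = ".", score = 0,
                       strand = ".") {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   name = rep_len(as.character(name), n),
                   score = rep_len(as.numeric(score), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "intervals") {
  stop_if_not_cols(df, c("chrom", "start", "end"), what)
  if (any(df$start < 0)) stop(what, ": negative start coordinate", call. = FALSE)
  if (any(df$end <= df$start)) {
    bad <- which(df$end <= df$start)[1]
    stop(sprintf("%s: empty or inverted interval at row %d (start %d, end %d)",
                 what, bad, df$start[bad], df$end[bad]), call. = FALSE)
  }
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", "."))) {
    stop(what, ": strand must be one of '+', '-', '.'", call. = FALSE)
  }
  invisible(df)
}

#' Interval centers
#'
#' @param x interval data.frame.
#' @return integer vector \code{start + floor(length/2)}.
#' @export
interval_center <- function(x) {
  floor(x$start + (x$end - x$start) %/% 2)
}

#' Read / write BED files
#'
#' \code{read_bed} accepts 3--6 column BED; missing name/score/strand columns
#' are filled with \code{"."}, 0 and \code{"."}. Malformed records (negative
#' coordinates, \code{start >= end}, unknown strand) raise an error naming the
#' offending line.
#'
#' @param path file path.
#' @rdname bed_io
#' @return \code{read_bed}: an interval data.frame as from [gintervals()].
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (!length(lines)) {
    return(gintervals(character(), integer(), integer())[0, ])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    stop("BED parse error at line ", which(ncol < 3)[1], ": fewer than 3 columns",
         call. = FALSE)
  }
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  }
  start <- suppressWarnings(as.numeric(get(2, NA)))
  end <- suppressWarnings(as.numeric(get(3, NA)))
  if (anyNA(start) || anyNA(end)) {
    stop("BED parse error at line ", which(is.na(start) | is.na(end))[1],
         ": non-numeric coordinate", call. = FALSE)
  }
  bad <- which(start < 0 | end <= start)
  if (length(bad)) {
    stop("BED parse error at line ", bad[1],
         ": requires 0 <= start < end", call. = FALSE)
  }
  strand <- get(6, ".")
  if (!all(strand %in% c("+", "-", "."))) {
    stop("BED parse error at line ", which(!strand %in% c("+", "-", "."))[1],
         ": unknown strand", call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(get(5, "0")))
  score[is.na(score)] <- 0
  out <- gintervals(get(1, NA), start, end, name = get(4, "."),
                    score = score, strand = strand)
  if (any(ncol > 6)) {
    # narrowPeak and friends: columns beyond 6 are kept opaque
    out$extra <- vapply(fields, function(f) {
      if (length(f) > 6) paste(f[-(1:6)], collapse = "\t") else ""
    }, "")
  }
  out
}

#' @param x interval data.frame.
#' @rdname bed_io
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  x$name <- if ("name" %in% names(x)) x$name else "."
  x$score <- if ("score" %in% names(x)) x$score else 0
  x$strand <- if ("strand" %in% names(x)) x$strand else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, as.integer(x$start),
                   as.integer(x$end), x$name,
                   format(x$score, trim = TRUE, scientific = FALSE),
                   x$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Merge overlapping intervals across one or more sets
#'
#' Collapses any two intervals that overlap by at least 1 bp to their spanning
#' interval (half-open semantics: abutting intervals are kept separate). The
#' merged records carry provenance: which of the input sets contributed to
#' each merged interval.
#'
#' @param ... one or more interval data.frames; name the arguments to get
#'   meaningful provenance labels.
#' @return Sorted, non-overlapping intervals with a \code{sources} column
#'   (comma-separated contributing set names) and \code{n_sources}.
#' @export
merge_sites <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is.data.frame(sets[[1]])) {
    sets <- sets[[1]]
  }
  if (!length(sets)) stop("merge_sites: need at least one interval set")
  nm <- names(sets) %||% rep("", length(sets))
  nm[nm == ""] <- paste0("set", seq_along(sets))[nm == ""]
  all <- do.call(rbind, lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    validate_intervals(s, paste0("merge_sites input '", nm[i], "'"))
    data.frame(chrom = s$chrom, start = s$start, end = s$end,
               src = nm[i], stringsAsFactors = FALSE)
  }))
  if (!nrow(all)) {
    out <- gintervals(character(), integer(), integer())[0, ]
    out$sources <- character()
    out$n_sources <- integer()
    return(out)
  }
  ord <- order(all$chrom, all$start, all$end)
  all <- all[ord, ]
  # sweep: new block when chrom changes or start >= running max end
  runmax <- stats::ave(all$end, all$chrom, FUN = cummax)
  prev_max <- c(-Inf, runmax[-nrow(all)])
  new_block <- all$chrom != c("", all$chrom[-nrow(all)]) | all$start >= prev_max
  block <- cumsum(new_block)
  out <- do.call(rbind, lapply(split(seq_len(nrow(all)), block), function(idx) {
    srcs <- sort(unique(all$src[idx]))
    data.frame(chrom = all$chrom[idx[1]],
               start = min(all$start[idx]),
               end = max(all$end[idx]),
               name = ".", score = 0, strand = ".",
               sources = paste(srcs, collapse = ","),
               n_sources = length(srcs),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$name <- sprintf("merged_%d", seq_len(nrow(out)))
  out
}

#' Signed distance from each query interval to its nearest reference
#'
#' Distances are center-to-center and signed as reference minus query; ties
#' are broken toward the reference with the smaller coordinate. Queries on a
#' chromosome with no reference interval get \code{NA} distance (undefined,
#' not zero).
#'
#' @param query,reference interval data.frames.
#' @return data.frame with one row per query: \code{nearest} (reference name
#'   or row index as character), \code{distance} (signed bp, NA if undefined).
#' @export
nearest_distance <- function(query, reference) {
  validate_intervals(query, "query")
  validate_intervals(reference, "reference")
  if (!nrow(reference)) stop("nearest_distance: empty reference set")
  qc <- interval_center(query)
  rc <- interval_center(reference)
  rname <- if ("name" %in% names(reference) && !all(reference$name == ".")) {
    reference$name
  } else {
    as.character(seq_len(nrow(reference)))
  }
  out <- data.frame(nearest = NA_character_, distance = NA_real_,
                    stringsAsFactors = FALSE)[rep(1, nrow(query)), ]
  rownames(out) <- NULL
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    ri <- which(reference$chrom == ch)
    if (!length(ri)) next
    # sort references; for each query pick min |distance|, tie -> smaller coord
    ord <- ri[order(rc[ri], reference$start[ri], ri)]
    ord <- ord[!duplicated(rc[ord])] # duplicate centers: keep smallest coord
    centers <- rc[ord]
    pos <- findInterval(qc[qi], centers)
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, length(centers))
    dlo <- abs(centers[lo] - qc[qi])
    dhi <- abs(centers[hi] - qc[qi])
    # tie at equal |d| -> smaller coordinate = lo (centers sorted ascending)
    pick <- ifelse(dlo <= dhi, lo, hi)
    sel <- ord[pick]
    out$nearest[qi] <- rname[sel]
    out$distance[qi] <- rc[sel] - qc[qi]
  }
  out
}
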