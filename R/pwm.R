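#' Position weight matrices
#'
#' A PWM is a 4 x L probability matrix over A, C, G, T with a background
#' distribution (default uniform 0.25). Scores are natural-log odds,
#' \eqn{\sum_k \ln(p_{pwm}(b_k) / p_{bg}(b_k))}, summed over the window. The
#' consensus score is the maximum attainable log-odds; a hit's
#' \emph{normalized score} is its log-odds divided by the consensus score, so
#' it equals 1 exactly when the window is the consensus sequence.
#'
#' @param probs 4 x L numeric matrix, rows A, C, G, T; columns must each sum
#'   to 1 (within 1e-9).
#' @param name motif name.
#' @param background length-4 background probabilities (A, C, G, T).
#' @param pseudocount added to probabilities before taking logs (guards
#'   against zero entries).
#' @param threshold optional default log-odds hit threshold; when absent,
#'   scanning uses 0.7 x consensus score.
#' @return An object of class \code{pwm}.
#' @export
pwm <- function(probs, name = "motif", background = rep(0.25, 4),
                pseudocount = 1e-3, threshold = NULL) {
  stopifnot(is.matrix(probs), nrow(probs) == 4)
  if (ncol(probs) < 4) stop("pwm: motif length must be >= 4")
  if (any(abs(colSums(probs) - 1) > 1e-9)) {
    stop("pwm: each column must sum to 1")
  }
  rownames(probs) <- c("A", "C", "G", "T")
  p <- (probs + pseudocount) / (1 + 4 * pseudocount)
  lo <- log(p / background)
  obj <- structure(list(name = name, probs = probs, background = background,
                        pseudocount = pseudocount, logodds = lo,
                        threshold = threshold),
                   class = "pwm")
  if (consensus_score(obj) <= 0) {
    stop("pwm: consensus score must be positive")
  }
  obj
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': length %d, consensus %s (score %.3f)\n",
              x$name, ncol(x$probs), consensus_seq(x), consensus_score(x)))
  invisible(x)
}

#' @rdname pwm
#' @param x a \code{pwm}.
#' @return \code{consensus_score}: maximum attainable log-odds score.
#' @export
consensus_score <- function(x) sum(apply(x$logodds, 2, max))

#' @rdname pwm
#' @export
consensus_seq <- function(x) {
  paste(c("A", "C", "G", "T")[apply(x$logodds, 2, which.max)], collapse = "")
}

#' Read / write PWM text files
#'
#' HOMER-style motif text: a header line \code{>CONSENSUS<tab>name<tab>thresh}
#' (threshold optional) followed by L rows of 4 tab- or space-separated
#' probabilities in A, C, G, T order. Files may contain several motifs.
#'
#' @param path file path.
#' @return \code{read_pwm}: a list of \code{pwm} objects (length-1 list for a
#'   single-motif file).
#' @rdname pwm_io
#' @export
read_pwm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- which(startsWith(lines, ">"))
  if (!length(heads)) stop("read_pwm: no '>' header found")
  ends <- c(heads[-1] - 1, length(lines))
  out <- lapply(seq_along(heads), function(i) {
    hdr <- strsplit(sub("^>", "", lines[heads[i]]), "[\t ]+")[[1]]
    name <- if (length(hdr) >= 2) hdr[2] else hdr[1]
    thr <- if (length(hdr) >= 3) suppressWarnings(as.numeric(hdr[3])) else NULL
    if (!is.null(thr) && is.na(thr)) thr <- NULL
    rows <- lines[(heads[i] + 1):ends[i]]
    m <- t(vapply(strsplit(rows, "[\t ]+"),
                  function(r) as.numeric(r[1:4]), numeric(4)))
    pwm(t(m), name = name, threshold = thr)
  })
  names(out) <- vapply(out, function(p) p$name, "")
  out
}

#' @param pwms a \code{pwm} or list of them.
#' @rdname pwm_io
#' @export
write_pwm <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    thr <- if (is.null(p$threshold)) "" else sprintf("\t%.6g", p$threshold)
    writeLines(sprintf(">%s\t%s%s", consensus_seq(p), p$name, thr), con)
    utils::write.table(format(t(p$probs), digits = 6), con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Reverse-complement a PWM
#' @param x a \code{pwm}.
#' @export
reverse_complement_pwm <- function(x) {
  probs <- x$probs[4:1, ncol(x$probs):1, drop = FALSE]
  pwm(probs, name = x$name, background = x$background,
      pseudocount = x$pseudocount, threshold = x$threshold)
}

# Encode a DNA string as integer codes A=1 C=2 G=3 T=4, N/other = 5.
encode_dna <- function(seq) {
  codes <- integer(256)
  codes[utf8ToInt("A")] <- 1L; codes[utf8ToInt("a")] <- 1L
  codes[utf8ToInt("C")] <- 2L; codes[utf8ToInt("c")] <- 2L
  codes[utf8ToInt("G")] <- 3L; codes[utf8ToInt("g")] <- 3L
  codes[utf8ToInt("T")] <- 4L; codes[utf8ToInt("t")] <- 4L
  x <- codes[utf8ToInt(seq)]
  x[x == 0L] <- 5L
  x
}

#' Reverse complement of a DNA string
#' @param seq DNA string over A, C, G, T, N.
#' @export
reverse_complement <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# Log-odds score of every window start (1-based) on the forward orientation
# of `codes` under the PWM; windows containing N score -Inf.
scan_scores <- function(codes, lo) {
  L <- ncol(lo)
  n <- length(codes) - L + 1
  if (n < 1) return(numeric(0))
  lo5 <- rbind(lo, rep(-Inf, L)) # row 5 = N
  s <- numeric(n)
  for (k in seq_len(L)) {
    s <- s + lo5[cbind(codes[k:(k + n - 1)], k)]
  }
  s
}

#' Scan a sequence for PWM hits on both strands
#'
#' The hit threshold is the PWM's own default threshold (its file-supplied
#' value, or 0.7 x consensus score when none is supplied) \emph{reduced by}
#' \code{threshold_offset} log-odds units, which admits near-consensus
#' matches. Windows containing N are skipped. Overlapping hits on the same
#' strand are deduplicated to the best-scoring position (ties broken toward
#' the smaller coordinate).
#'
#' @param seq DNA string over A, C, G, T, N.
#' @param motif a \code{pwm}.
#' @param threshold_offset log-odds units subtracted from the default
#'   threshold (default 3).
#' @param offset0 0-based coordinate of the first base of \code{seq} on its
#'   chromosome (hit coordinates are reported relative to the chromosome).
#' @return data.frame of hits: \code{start}, \code{end} (0-based half-open),
#'   \code{strand}, \code{score} (log-odds), \code{norm_score}
#'   (score / consensus score).
#' @export
pwm_logodds_scan <- function(seq, motif, threshold_offset = 3, offset0 = 0) {
  stopifnot(inherits(motif, "pwm"))
  L <- ncol(motif$probs)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      strand = character(0), score = numeric(0),
                      norm_score = numeric(0))
  if (nchar(seq) < L) return(empty)
  cons <- consensus_score(motif)
  thr <- (motif$threshold %||% (0.7 * cons)) - threshold_offset
  codes <- encode_dna(seq)
  fwd <- scan_scores(codes, motif$logodds)
  rev <- scan_scores(codes, reverse_complement_pwm(motif)$logodds)
  fi <- which(fwd >= thr)
  ri <- which(rev >= thr)
  hits <- rbind(
    data.frame(start = fi - 1, strand = rep("+", length(fi)),
               score = fwd[fi]),
    data.frame(start = ri - 1, strand = rep("-", length(ri)),
               score = rev[ri])
  )
  if (!nrow(hits)) return(empty)
  # dedupe overlapping same-strand hits: best score first, tie smaller coord
  keep <- logical(nrow(hits))
  for (st in c("+", "-")) {
    idx <- which(hits$strand == st)
    if (!length(idx)) next
    idx <- idx[order(-hits$score[idx], hits$start[idx])]
    taken_start <- numeric(0)
    for (i in idx) {
      if (!length(taken_start) ||
          all(abs(hits$start[i] - taken_start) >= L)) {
        keep[i] <- TRUE
        taken_start <- c(taken_start, hits$start[i])
      }
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  data.frame(start = hits$start + offset0,
             end = hits$start + offset0 + L,
             strand = hits$strand,
             score = hits$score,
             norm_score = hits$score / cons,
             row.names = NULL)
}

#' Fraction of sites containing at least one motif hit
#'
#' Scans each site's own interval (no flanking) in the genome sequence.
#'
#' @param sites interval data.frame (single chromosome genomes: chrom must
#'   match a name in \code{genome}).
#' @param genome named list (or character vector) of chromosome sequences.
#' @param motif a \code{pwm}.
#' @param threshold_offset as in [pwm_logodds_scan()].
#' @return list with \code{has_hit} (logical per site), \code{fraction},
#'   \code{percent} (formatted per package convention).
#' @export
motif_occurrence <- function(sites, genome, motif, threshold_offset = 3) {
  validate_intervals(sites, "sites")
  has <- vapply(seq_len(nrow(sites)), function(i) {
    s <- substr(genome[[sites$chrom[i]]], sites$start[i] + 1, sites$end[i])
    nrow(pwm_logodds_scan(s, motif, threshold_offset)) > 0
  }, TRUE)
  frac <- mean(has)
  list(has_hit = has, fraction = frac, percent = format_pct(100 * frac))
}

#' Mean best normalized motif score across sites
#'
#' For each site with at least one hit, takes the best hit's normalized score
#' (log-odds / consensus score) and averages over sites. Sites without hits
#' are excluded (their count is reported).
#'
#' @inheritParams motif_occurrence
#' @return list with \code{mean_score}, \code{per_site} (NA where no hit),
#'   \code{n_with_hit}, \code{n_without_hit}.
#' @export
mean_motif_score <- function(sites, genome, motif, threshold_offset = 3) {
  validate_intervals(sites, "sites")
  best <- vapply(seq_len(nrow(sites)), function(i) {
    s <- substr(genome[[sites$chrom[i]]], sites$start[i] + 1, sites$end[i])
    h <- pwm_logodds_scan(s, motif, threshold_offset)
    if (nrow(h)) max(h$norm_score) else NA_real_
  }, 0)
  n_hit <- sum(!is.na(best))
  if (n_hit == 0) {
    warning("mean_motif_score: no site has a hit; mean undefined")
    return(list(mean_score = NA_real_, per_site = best, n_with_hit = 0L,
                n_without_hit = length(best)))
  }
  list(mean_score = mean(best, na.rm = TRUE), per_site = best,
       n_with_hit = n_hit, n_without_hit = sum(is.na(best)))
}

#' Distance between the best hits of two motifs within each site
#'
#' For sites carrying at least one hit of each motif, the distance is the
#' absolute difference between the centers of the best-scoring hit of each
#' motif. Sites missing either motif are excluded and counted.
#'
#' @inheritParams motif_occurrence
#' @param motif_a,motif_b \code{pwm} objects.
#' @param breaks histogram bin breaks in bp (passed to [hist()]).
#' @return list with \code{distances} (per qualifying site), \code{n_excluded},
#'   \code{histogram} (counts per bin) and \code{breaks}.
#' @export
inter_motif_distance <- function(sites, genome, motif_a, motif_b,
                                 threshold_offset = 3,
                                 breaks = seq(0, 500, by = 50)) {
  validate_intervals(sites, "sites")
  d <- vapply(seq_len(nrow(sites)), function(i) {
    s <- substr(genome[[sites$chrom[i]]], sites$start[i] + 1, sites$end[i])
    ha <- pwm_logodds_scan(s, motif_a, threshold_offset)
    hb <- pwm_logodds_scan(s, motif_b, threshold_offset)
    if (!nrow(ha) || !nrow(hb)) return(NA_real_)
    ca <- ha$start[which.max(ha$score)] + ncol(motif_a$probs) %/% 2
    cb <- hb$start[which.max(hb$score)] + ncol(motif_b$probs) %/% 2
    abs(ca - cb)
  }, 0)
  ok <- !is.na(d)
  dd <- d[ok]
  br <- unique(c(breaks, max(breaks[length(breaks)], max(dd, 0) + 1)))
  h <- if (length(dd)) hist(dd, breaks = br, plot = FALSE)$counts else
    integer(length(br) - 1)
  list(distances = dd, n_excluded = sum(!ok), histogram = h, breaks = br)
}
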