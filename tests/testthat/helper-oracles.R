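# Brute-force reference implementations, deliberately naive and independent
# of the package's algorithms. Used to pin down the fast paths.

# O(n^2) interval union: repeatedly merge any overlapping pair to fixpoint.
oracle_merge <- function(df) {
  rows <- split(df[, c("chrom", "start", "end")], seq_len(nrow(df)))
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_along(rows)) {
      if (is.null(rows[[i]])) next
      for (j in seq_along(rows)) {
        if (i == j || is.null(rows[[j]])) next
        a <- rows[[i]]; b <- rows[[j]]
        if (a$chrom == b$chrom && a$start < b$end && b$start < a$end) {
          rows[[i]] <- data.frame(chrom = a$chrom,
                                  start = min(a$start, b$start),
                                  end = max(a$end, b$end))
          rows[j] <- list(NULL)
          changed <- TRUE
        }
      }
    }
    rows <- rows[!vapply(rows, is.null, TRUE)]
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start), ]
}

# Exhaustive nearest reference center per query (tie: smaller center, then
# smaller start).
oracle_nearest <- function(query, reference) {
  qc <- interval_center(query)
  rc <- interval_center(reference)
  sapply(seq_len(nrow(query)), function(i) {
    j <- which(reference$chrom == query$chrom[i])
    if (!length(j)) return(NA_real_)
    d <- rc[j] - qc[i]
    best <- j[order(abs(d), rc[j], reference$start[j])][1]
    rc[best] - qc[i]
  })
}

# Per-base window sum.
oracle_quantify <- function(sites, track, halfwidth) {
  centers <- interval_center(sites)
  sapply(seq_len(nrow(sites)), function(i) {
    v <- track$values[[sites$chrom[i]]]
    if (is.null(v)) return(0)
    lo <- max(centers[i] - halfwidth, 0)
    hi <- min(centers[i] + halfwidth, length(v))
    if (hi <= lo) return(0)
    s <- 0
    for (pos in lo:(hi - 1)) s <- s + v[pos + 1]
    s
  })
}

# Literal BH step-up from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(p[ord][i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Naive per-window PWM scan with the documented threshold and dedup rules.
oracle_pwm_scan <- function(seq, motif, threshold_offset = 3) {
  L <- ncol(motif$probs)
  n <- nchar(seq)
  cons <- consensus_score(motif)
  thr <- (if (is.null(motif$threshold)) 0.7 * cons else motif$threshold) -
    threshold_offset
  score_window <- function(w, lo) {
    chars <- strsplit(w, "")[[1]]
    s <- 0
    for (k in seq_len(L)) {
      row <- match(chars[k], c("A", "C", "G", "T"))
      if (is.na(row)) return(-Inf)
      s <- s + lo[row, k]
    }
    s
  }
  lo_f <- motif$logodds
  lo_r <- reverse_complement_pwm(motif)$logodds
  hits <- data.frame(start = numeric(0), strand = character(0),
                     score = numeric(0))
  for (i in seq_len(max(n - L + 1, 0))) {
    w <- substr(seq, i, i + L - 1)
    sf <- score_window(w, lo_f)
    sr <- score_window(w, lo_r)
    if (sf >= thr) hits <- rbind(hits, data.frame(start = i - 1,
                                                  strand = "+", score = sf))
    if (sr >= thr) hits <- rbind(hits, data.frame(start = i - 1,
                                                  strand = "-", score = sr))
  }
  if (!nrow(hits)) return(hits)
  keep <- logical(nrow(hits))
  for (st in c("+", "-")) {
    idx <- which(hits$strand == st)
    idx <- idx[order(-hits$score[idx], hits$start[idx])]
    taken <- numeric(0)
    for (i in idx) {
      if (!length(taken) || all(abs(hits$start[i] - taken) >= L)) {
        keep[i] <- TRUE
        taken <- c(taken, hits$start[i])
      }
    }
  }
  hits <- hits[keep, ]
  hits[order(hits$start, hits$strand), ]
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                             max_len = 500) {
  start <- sample.int(max_pos, n, replace = TRUE)
  gintervals(sample(chroms, n, replace = TRUE), start,
             start + sample.int(max_len, n, replace = TRUE))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A small count_matrix with two conditions for DE tests.
toy_counts <- function(n = 50, reps = 3, mu_a = 100, mu_b = 100,
                       alpha = 0.05, seed = 42) {
  set.seed(seed)
  samples <- c(paste0("a_rep", 1:reps), paste0("b_rep", 1:reps))
  m <- cbind(matrix(rnbinom(n * reps, mu = mu_a, size = 1 / alpha), n),
             matrix(rnbinom(n * reps, mu = mu_b, size = 1 / alpha), n))
  dimnames(m) <- list(sprintf("f%03d", 1:n), samples)
  conds <- rep(c("A", "B"), each = reps)
  names(conds) <- samples
  count_matrix(m, conds)
}

# Hand-built DEResult rows for classifier tests.
fake_de <- function(ids, log2fc, padj) {
  res <- data.frame(id = ids, base_mean = 100, log2fc = log2fc,
                    p = padj, padj = padj, status = "ok",
                    stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  res
}
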