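#' Feature-by-sample count matrix with a condition map
#'
#' The shared container for RNA-seq gene counts and for ChIP tag counts
#' quantified at sites. Counts are non-negative integers; every sample maps
#' to exactly one of the four conditions \code{nt}, \code{gluc}, \code{cort},
#' \code{dual} (other condition labels are allowed for generic two-group
#' use).
#'
#' @param counts integer matrix, features x samples, with rownames (feature
#'   ids) and colnames (sample ids).
#' @param conditions named character vector mapping each sample id to its
#'   condition.
#' @param feature_lengths optional named numeric vector of feature lengths in
#'   bp (needed for RPKM).
#' @return An object of class \code{count_matrix}.
#' @export
count_matrix <- function(counts, conditions, feature_lengths = NULL) {
  stopifnot(is.matrix(counts))
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count_matrix: counts must have row and column names")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("count_matrix: counts must be non-negative integers")
  }
  if (!setequal(names(conditions), colnames(counts))) {
    stop("count_matrix: condition map must cover exactly the sample ids")
  }
  conditions <- conditions[colnames(counts)]
  if (!is.null(feature_lengths)) {
    if (!all(rownames(counts) %in% names(feature_lengths))) {
      stop("count_matrix: feature_lengths missing some features")
    }
    if (any(feature_lengths <= 0)) stop("count_matrix: lengths must be > 0")
    feature_lengths <- feature_lengths[rownames(counts)]
  }
  structure(list(counts = counts, conditions = conditions,
                 feature_lengths = feature_lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s:%d", names(table(x$conditions)),
                            table(x$conditions)), collapse = ", ")))
  invisible(x)
}

#' Read / write count tables
#'
#' TSV with a leading feature-id column and one column per sample. The
#' condition map is recovered from sample names of the form
#' \code{<condition>_rep<k>} unless supplied explicitly.
#'
#' @param path file path.
#' @param conditions optional named condition map (else parsed from sample
#'   names).
#' @rdname counts_io
#' @export
read_counts <- function(path, conditions = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (is.null(conditions)) {
    conditions <- sub("_rep[0-9]+$", "", colnames(m))
    names(conditions) <- colnames(m)
  }
  count_matrix(m, conditions)
}

#' @param x a \code{count_matrix}.
#' @rdname counts_io
#' @export
write_counts <- function(x, path) {
  df <- data.frame(feature = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reads per kilobase per million mapped reads
#'
#' \code{RPKM = count * 1e9 / (length_bp * sample_total)}.
#'
#' @param x a \code{count_matrix} with feature lengths, or an integer matrix.
#' @param feature_lengths named lengths in bp (required when \code{x} is a
#'   bare matrix).
#' @return numeric matrix of RPKM values, same shape as the counts.
#' @export
rpkm <- function(x, feature_lengths = NULL) {
  if (inherits(x, "count_matrix")) {
    m <- x$counts
    feature_lengths <- feature_lengths %||% x$feature_lengths
  } else {
    m <- x
  }
  if (is.null(feature_lengths)) stop("rpkm: feature lengths required")
  len <- feature_lengths[rownames(m)]
  if (any(is.na(len)) || any(len <= 0)) stop("rpkm: lengths must be > 0")
  totals <- colSums(m)
  if (any(totals == 0)) stop("rpkm: zero sample total")
  sweep(m / len, 2, totals, "/") * 1e9
}

#' Mean expression per condition
#'
#' Replicates are summarized by their mean, the package's replicate summary
#' for downstream comparisons.
#'
#' @param values numeric matrix (counts or RPKM), columns = samples.
#' @param conditions named condition map over the columns.
#' @return matrix features x conditions.
#' @export
condition_means <- function(values, conditions) {
  conds <- unique(conditions[colnames(values)])
  out <- vapply(conds, function(cc) {
    rowMeans(values[, names(conditions)[conditions == cc], drop = FALSE])
  }, numeric(nrow(values)))
  colnames(out) <- conds
  out
}
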