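# Internal helpers shared across modules.

# Derive a child RNG seed (< 2^31) from a master seed and a text label.
# Polynomial rolling hash so that streams for different (assay, condition,
# replicate) labels are decoupled: adding one stream never perturbs another.
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L)
  m <- 2147483647 # 2^31 - 1
  h <- master %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Percentage printing convention: nearest integer, except one decimal place
# once the value reaches 99% (so 1031/1035 prints as 99.6, 92/165 as 56).
format_pct <- function(x) {
  ifelse(x >= 99, round(x, 1), round(x, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
}
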