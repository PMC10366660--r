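# Internal helpers: argument checking, seeding, fast column medians.

check_number <- function(x, name, positive = FALSE, nonneg = FALSE,
                         finite = TRUE, len = NULL) {
  if (!is.numeric(x)) {
    abort(sprintf("`%s` must be numeric, not %s.", name, class(x)[1]))
  }
  if (!is.null(len) && length(x) != len) {
    abort(sprintf("`%s` must have length %d, not %d.", name, len, length(x)))
  }
  if (finite && any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite.", name))
  }
  if (positive && any(x <= 0)) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  if (nonneg && any(x < 0)) {
    abort(sprintf("`%s` must be >= 0.", name))
  }
  invisible(x)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
# seed = NULL runs under the current RNG stream.
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Column medians of a matrix; matrixStats when available (it ships with the
# Bioconductor stack), otherwise base apply.
col_medians <- function(m) {
  if (requireNamespace("matrixStats", quietly = TRUE)) {
    matrixStats::colMedians(m)
  } else {
    apply(m, 2L, stats::median)
  }
}

# Tiny stable content hash (FNV-1a, 32-bit) for embedding config/seed
# provenance in output files without a digest dependency.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor into the low byte (h may exceed the 32-bit signed range bitwXor
    # accepts, so do it on the low byte alone)
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    # 32-bit modular multiply by the FNV prime, split to stay within
    # double-precision exact-integer range
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

required_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}
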