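# Internal helpers shared across modules.

# Run `code` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched. All stochastic entry points funnel through this so a
# master seed fully determines every output.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive child seeds from a master seed so each iteration/stage owns an
# independent, individually reproducible substream. Kept below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# tibble() validates and name-repairs on every call, which dominates the
# per-candidate cost of the iteration loop; this skips straight to the
# low-level constructor for internally-built, already-consistent columns.
fast_tibble <- function(...) {
  cols <- list(...)
  tibble::new_tibble(cols, nrow = length(cols[[1]]))
}

assert_fraction <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x < 1)
  if (!ok) abort(sprintf("`%s` must be a fraction in %s", name,
                         if (open) "(0, 1)" else "[0, 1)"))
  invisible(x)
}

assert_binary_labels <- function(labels, arg = "labels") {
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    bad <- which(!(labels %in% c(0, 1)) | is.na(labels))[1]
    abort(sprintf("`%s` must be 0/1; offending entry at position %d (value %s)",
                  arg, bad, as.character(labels[bad])))
  }
  if (length(unique(labels)) < 2L) {
    abort(sprintf("`%s` must contain both classes", arg))
  }
  invisible(as.integer(labels))
}
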