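# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library calls never perturb user-level reproducibility.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic derived seed, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k)) %% 2147483629 + 1)
}

# Canonical label factor used throughout: single first, double second.
crop_labels <- function() c("single", "double")

as_label_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), crop_labels())
  if (length(bad) > 0) {
    stop("unknown intensity label(s): ", paste(bad, collapse = ", "),
         " (expected 'single' or 'double')")
  }
  factor(x, levels = crop_labels())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
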