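#' Derive a reproducible sub-seed for a named pipeline stage
#'
#' All stochastic stages draw from a stream keyed by `(seed, stage)`, so each
#' stage is reproducible on its own: regenerating only the biomarkers, say,
#' gives the same values whether or not the genotype stage ran first.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' stage_seed(1, "genotypes")
stage_seed <- function(seed, stage) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps arithmetic exact in doubles
  h <- abs(seed) %% m
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  as.integer(h %% (m - 2L) + 1)
}

# Evaluate `code` under the RNG state implied by (seed, stage), restoring the
# caller's RNG state afterwards.
with_stage_seed <- function(seed, stage, code) {
  withr::with_seed(stage_seed(seed, stage), code)
}

# Validation helpers ---------------------------------------------------------

check_prob <- function(x, name, open = TRUE) {
  bad <- !is.numeric(x) | !is.finite(x) |
    (if (open) x <= 0 | x >= 1 else x < 0 | x > 1)
  if (any(bad)) {
    abort(sprintf("`%s` must be %s; got %s.", name,
                  if (open) "in the open interval (0, 1)" else "in [0, 1]",
                  paste(utils::head(x[bad], 3), collapse = ", ")))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be an integer >= %s.", name, min))
  }
  invisible(as.integer(x))
}

# Floor used for reported p-values so they are never exactly zero.
P_FLOOR <- 1e-300

two_sided_p <- function(z) {
  pmax(2 * pnorm(-abs(z)), P_FLOOR)
}
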