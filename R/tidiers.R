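#' Tidy an IVW MR fit
#'
#' @param x An `ivw_mr` object.
#' @param exponentiate Report odds ratios instead of log-ORs.
#' @param ... Unused.
#' @return A one-row tibble with `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `p.value`.
#' @export
tidy.ivw_mr <- function(x, exponentiate = FALSE, ...) {
  out <- tibble::tibble(
    term = "exposure (per SD)",
    estimate = x$beta, std.error = x$se,
    conf.low = x$ci_low, conf.high = x$ci_high, p.value = x$p
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' One-line model summary for an IVW MR fit
#' @param x An `ivw_mr` object.
#' @param ... Unused.
#' @return A one-row tibble with instrument count and Cochran Q results.
#' @export
glance.ivw_mr <- function(x, ...) {
  tibble::tibble(n_instruments = x$n_instruments, q_stat = x$q_stat,
                 q_df = x$q_df, q_p = x$q_p)
}

#' Tidy a weighted-median MR fit
#' @inheritParams tidy.ivw_mr
#' @param x A `weighted_median_mr` object.
#' @return A one-row tibble.
#' @export
tidy.weighted_median_mr <- function(x, exponentiate = FALSE, ...) {
  out <- tibble::tibble(
    term = "exposure (per SD)",
    estimate = x$beta, std.error = x$se_boot,
    conf.low = x$ci_low, conf.high = x$ci_high, p.value = x$p
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' One-line summary for a weighted-median MR fit
#' @param x A `weighted_median_mr` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.weighted_median_mr <- function(x, ...) {
  tibble::tibble(n_instruments = x$n_instruments, n_boot = x$n_boot,
                 seed = x$seed)
}

#' Tidy an MR-PheWAS result
#'
#' @param x An `mr_phewas_result`.
#' @param ... Unused.
#' @return The per-phecode results tibble (ratio list-column dropped).
#' @export
tidy.mr_phewas_result <- function(x, ...) {
  dplyr::select(x$results, -"ratios")
}

#' One-line summary of an MR-PheWAS run
#' @param x An `mr_phewas_result`.
#' @param ... Unused.
#' @return A one-row tibble of stage counts.
#' @export
glance.mr_phewas_result <- function(x, ...) {
  m <- x$manifest
  tibble::tibble(
    n_individuals = m$n_individuals, n_retained = m$n_retained,
    n_phecodes_analyzed = m$n_phecodes_analyzed,
    n_significant = m$n_significant,
    fdr_realized_threshold = m$fdr_realized_threshold,
    n_consistent = m$n_consistent,
    n_heterogeneous_excluded = m$n_heterogeneous_excluded
  )
}
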