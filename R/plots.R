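#' Phenome-wide significance plot for an MR-PheWAS run
#'
#' Plots `-log10` of the IVW p-value per phecode, colored by disease
#' category where available, with the realized FDR threshold drawn as a
#' dashed line.
#'
#' @param object An `mr_phewas_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_phewas_result <- function(object, ...) {
  d <- dplyr::select(object$results, -"ratios")
  if (!"category" %in% names(d)) d$category <- "all"
  d$category[is.na(d$category)] <- "unknown"
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$phecode_id, .data$p_ivw),
    y = -log10(.data$p_ivw), colour = .data$category)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "phecode", y = expression(-log[10](italic(p)[IVW])),
                  colour = "category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  thr <- object$manifest$fdr_realized_threshold
  if (is.finite(thr) && thr > 0) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(thr),
                                 linetype = "dashed")
  }
  p
}

#' MR scatter plot for one outcome
#'
#' Per-instrument SNP-exposure versus SNP-outcome associations with +/- 1 SE
#' error bars and the IVW slope through the origin.
#'
#' @param result An `mr_phewas_result`.
#' @param phecode_id Which outcome to plot.
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(result, phecode_id) {
  row <- result$results[result$results$phecode_id == phecode_id, ]
  if (!nrow(row)) abort(paste0("No results for phecode ", phecode_id))
  r <- row$ratios[[1]]
  ggplot2::ggplot(r, ggplot2::aes(x = .data$gamma, y = .data$Gamma)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$Gamma - .data$se_Gamma,
                                        ymax = .data$Gamma + .data$se_Gamma),
                           width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$gamma - .data$se_gamma,
      xmax = .data$gamma + .data$se_gamma), height = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = row$beta_ivw,
                         linetype = "dashed") +
    ggplot2::labs(
      x = "SNP effect on serum iron (SD units)",
      y = "SNP effect on outcome (log OR)",
      title = paste0("Phecode ", phecode_id)) +
    ggplot2::theme_minimal()
}

#' Forest plot of IVW and weighted-median odds ratios
#'
#' @param result An `mr_phewas_result`.
#' @param phecode_ids Outcomes to include; defaults to the FDR-significant
#'   consistent list (or everything when nothing is flagged).
#' @return A ggplot object.
#' @export
plot_mr_forest <- function(result, phecode_ids = NULL) {
  d <- dplyr::select(result$results, -"ratios")
  if (is.null(phecode_ids)) {
    sig <- d$phecode_id[isTRUE_or(d$fdr_significant) & !isTRUE_or(d$heterogeneous)]
    phecode_ids <- if (length(sig)) sig else d$phecode_id
  }
  d <- d[d$phecode_id %in% phecode_ids, ]
  long <- dplyr::bind_rows(
    tibble::tibble(phecode_id = d$phecode_id, estimator = "IVW",
                   or = exp(d$beta_ivw), lo = exp(d$ci_low_ivw),
                   hi = exp(d$ci_high_ivw)),
    tibble::tibble(phecode_id = d$phecode_id, estimator = "Weighted median",
                   or = exp(d$beta_wm), lo = exp(d$ci_low_wm),
                   hi = exp(d$ci_high_wm))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$or, y = .data$phecode_id,
                                     colour = .data$estimator)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "OR per 1 SD serum iron", y = "phecode",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

isTRUE_or <- function(x) !is.na(x) & x
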