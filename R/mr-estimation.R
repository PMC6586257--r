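#' Rescale absolute-unit genetic effects to SD units
#'
#' Converts per-allele effects reported in measurement units (e.g. umol/L of
#' serum iron) to SD units by dividing by the trait SD; standard errors are
#' scaled identically. The default 6.1 umol/L is the serum-iron SD in the
#' GWAS population that supplied the instrument estimates, so MR results are
#' expressed per 1 SD of serum iron.
#'
#' @param beta Numeric vector of per-allele effects in absolute units.
#' @param se Optional standard errors on the same scale.
#' @param sd_serum_iron Trait standard deviation in the same units.
#' @return If `se` is `NULL`, a numeric vector of scaled betas; otherwise a
#'   tibble with columns `beta`, `se`.
#' @export
#' @examples
#' scale_to_sd(6.1)          # 1 SD per allele
#' scale_to_sd(3.05)         # 0.5
scale_to_sd <- function(beta, se = NULL, sd_serum_iron = 6.1) {
  if (!is.numeric(sd_serum_iron) || length(sd_serum_iron) != 1 ||
      !is.finite(sd_serum_iron) || sd_serum_iron <= 0) {
    abort("`sd_serum_iron` must be a single positive number.")
  }
  if (is.null(se)) return(beta / sd_serum_iron)
  tibble::tibble(beta = beta / sd_serum_iron, se = se / sd_serum_iron)
}

#' Harmonize outcome associations with instrument effect alleles
#'
#' Aligns per-SNP outcome log-ORs to the instrument's effect allele. If the
#' outcome's effect allele equals the instrument's other allele, the outcome
#' beta is negated and the allele labels swapped. Incompatible allele pairs
#' are a hard error: no strand-flip inference is attempted (the iron
#' instruments are non-palindromic, so ambiguity indicates a data problem).
#'
#' @param instruments Instrument tibble (see [read_instruments()]).
#' @param associations Outcome association tibble with columns `rsid`,
#'   `effect_allele`, `beta`, `se` (and optionally `other_allele`,
#'   `phecode_id`, counts).
#' @param biomarker Which exposure biomarker's instrument effects to carry
#'   through as the ratio denominator.
#' @return Tibble, one row per rsid, with outcome columns `beta`, `se`
#'   aligned to the instrument effect allele, plus `gamma`, `se_gamma` (the
#'   chosen biomarker associations) and the instrument allele labels.
#' @export
harmonize <- function(instruments, associations, biomarker = "serum_iron") {
  if (!biomarker %in% BIOMARKERS) {
    abort(paste0("Unknown biomarker: ", biomarker))
  }
  bcol <- paste0("beta_", biomarker)
  scol <- paste0("se_", biomarker)
  if (!all(c(bcol, scol) %in% names(instruments))) {
    abort(paste0("Instrument table lacks columns for biomarker ", biomarker))
  }
  miss <- setdiff(associations$rsid, instruments$rsid)
  if (length(miss)) {
    abort(paste0("No instrument entry for rsid(s): ",
                 paste(miss, collapse = ", ")))
  }
  ins <- instruments[match(associations$rsid, instruments$rsid), ]
  out <- tibble::as_tibble(associations)
  has_other <- "other_allele" %in% names(out)
  same <- out$effect_allele == ins$effect_allele
  flipped <- out$effect_allele == ins$other_allele
  if (has_other) {
    same <- same & out$other_allele == ins$other_allele
    flipped <- flipped & out$other_allele == ins$effect_allele
  }
  bad <- !(same | flipped)
  if (any(bad)) {
    abort(paste0("Incompatible allele pair(s) for: ",
                 paste(unique(out$rsid[bad]), collapse = ", "),
                 " (no strand-flip guessing is performed)."))
  }
  out$beta[flipped] <- -out$beta[flipped]
  out$effect_allele <- ins$effect_allele
  if (has_other) out$other_allele <- ins$other_allele
  out$gamma <- ins[[bcol]]
  out$se_gamma <- ins[[scol]]
  out
}

#' Per-instrument ratio (Wald) MR estimates with second-order SEs
#'
#' The causal log-OR per 1 SD of exposure for instrument *j* is the ratio
#' `Gamma_j / gamma_j` of the SNP-outcome and SNP-exposure associations. The
#' standard error uses second-order weights, i.e. the delta expansion
#' retaining the exposure-uncertainty term:
#' `se^2 = se_Gamma^2 / gamma^2 + Gamma^2 se_gamma^2 / gamma^4`
#' (exposure-outcome covariance zero in the two-sample setting).
#'
#' @param gamma,se_gamma SNP-exposure associations (SD units) and SEs.
#' @param Gamma,se_Gamma SNP-outcome log-ORs and SEs.
#' @param rsid Optional labels.
#' @return Tibble `rsid`, `beta_mr`, `se_mr`, `weight` (`1/se_mr^2`).
#' @export
#' @examples
#' ratio_estimate(0.5, 0.05, 0.1, 0.05) # beta 0.2, se ~0.102
ratio_estimate <- function(gamma, se_gamma, Gamma, se_Gamma,
                           rsid = NA_character_) {
  if (any(gamma == 0)) abort("Ratio undefined: SNP-exposure beta is zero.")
  if (any(!is.finite(se_Gamma)) || any(se_Gamma <= 0)) {
    abort("Outcome standard errors must be positive.")
  }
  if (any(!is.finite(se_gamma)) || any(se_gamma < 0)) {
    abort("Exposure standard errors must be nonnegative.")
  }
  beta_mr <- Gamma / gamma
  se_mr <- sqrt(se_Gamma^2 / gamma^2 + Gamma^2 * se_gamma^2 / gamma^4)
  tibble::tibble(rsid = rep_len(as.character(rsid), length(beta_mr)),
                 beta_mr = beta_mr, se_mr = se_mr, weight = 1 / se_mr^2,
                 gamma = gamma, se_gamma = rep_len(se_gamma, length(beta_mr)),
                 Gamma = Gamma, se_Gamma = rep_len(se_Gamma, length(beta_mr)))
}

#' Fixed-effect inverse-variance-weighted meta-analysis of ratio estimates
#'
#' Pools the per-instrument ratio estimates with weights `1/se^2`:
#' `beta = sum(w b) / sum(w)`, `se = 1/sqrt(sum(w))`, 95% CI
#' `beta +/- 1.96 se`, and a two-sided normal p-value. Cochran's Q against
#' the pooled estimate is computed alongside (`df = k - 1`).
#'
#' @param ratios Tibble from [ratio_estimate()] (columns `beta_mr`,
#'   `se_mr`; at least 2 rows).
#' @return An `ivw_mr` object; see [tidy.ivw_mr()].
#' @export
#' @examples
#' r <- ratio_estimate(c(1, 1, 1), 0, c(0.1, 0.2, 0.3), c(0.1, 0.1, 0.1))
#' ivw_meta(r)
ivw_meta <- function(ratios) {
  b <- ratios$beta_mr
  s <- ratios$se_mr
  if (length(b) < 2) abort("IVW pooling needs at least 2 instruments.")
  if (any(!is.finite(s)) || any(s <= 0)) abort("Ratio SEs must be positive.")
  w <- 1 / s^2
  beta <- sum(w * b) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- cochran_q(b, s, beta)
  structure(
    list(beta = beta, se = se,
         ci_low = beta - qnorm(0.975) * se,
         ci_high = beta + qnorm(0.975) * se,
         p = two_sided_p(beta / se),
         q_stat = q$q_stat, q_df = q$q_df, q_p = q$q_p,
         n_instruments = length(b), estimates = ratios),
    class = "ivw_mr"
  )
}

#' @export
print.ivw_mr <- function(x, ...) {
  cat(sprintf("<ivw_mr> %d instruments\n", x$n_instruments))
  cat(sprintf("  OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              exp(x$beta), exp(x$ci_low), exp(x$ci_high), x$p))
  cat(sprintf("  Cochran Q = %.3f (df %d), p = %.3g\n",
              x$q_stat, x$q_df, x$q_p))
  invisible(x)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j (b_j - b_pooled)^2)` with `w_j = 1/se_j^2`, referred to a
#' chi-square with `k - 1` degrees of freedom. Excess heterogeneity across
#' instruments signals possible pleiotropy.
#'
#' @param beta,se Per-instrument estimates and SEs.
#' @param beta_pooled Pooled estimate; defaults to the IVW mean of `beta`.
#' @return List `q_stat`, `q_df`, `q_p`.
#' @export
cochran_q <- function(beta, se, beta_pooled = NULL) {
  w <- 1 / se^2
  if (is.null(beta_pooled)) beta_pooled <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - beta_pooled)^2)
  df <- length(beta) - 1L
  list(q_stat = q, q_df = df,
       q_p = stats::pchisq(q, df, lower.tail = FALSE))
}

# Weighted-median point estimate: order estimates, accumulate normalized
# weights, and linearly interpolate the half-weight point; clamps to the
# extreme estimate when 0.5 falls outside the breakpoints.
weighted_median_point <- function(beta, weight) {
  o <- order(beta)
  b <- beta[o]
  wp <- weight[o] / sum(weight)
  s <- cumsum(wp) - wp / 2
  if (0.5 <= s[1]) return(b[1])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  stats::approx(s, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimate with bootstrap standard error
#'
#' Orders the per-instrument ratio estimates by magnitude, weights them by
#' precision, and takes the (interpolated) median of the weighted order
#' distribution — consistent when instruments carrying more than half of the
#' weight are valid. The standard error is the SD of the estimate over
#' parametric bootstrap resamples: when the ratio components are available
#' (columns `gamma`, `se_gamma`, `Gamma`, `se_Gamma`, as produced by
#' [ratio_estimate()]) both numerator and denominator are redrawn and the
#' ratios and weights recomputed; otherwise the ratio estimates themselves
#' are redrawn as `Normal(beta_j, se_j)`.
#'
#' @param ratios Tibble with `beta_mr`, `se_mr` (and optionally the ratio
#'   components); at least 3 rows.
#' @param n_boot Number of bootstrap resamples (at least 100).
#' @param seed Seed for the bootstrap stream.
#' @return A `weighted_median_mr` object; see [tidy.weighted_median_mr()].
#' @export
weighted_median <- function(ratios, n_boot = 1000, seed = 1) {
  b <- ratios$beta_mr
  s <- ratios$se_mr
  if (length(b) < 3) abort("Weighted median needs at least 3 instruments.")
  if (n_boot < 100) abort("`n_boot` must be at least 100.")
  w <- 1 / s^2
  est <- weighted_median_point(b, w)
  components <- all(c("gamma", "se_gamma", "Gamma", "se_Gamma") %in%
                      names(ratios))
  k <- length(b)
  boots <- with_stage_seed(seed, "weighted-median-boot", {
    vapply(seq_len(n_boot), function(i) {
      if (components) {
        g <- rnorm(k, ratios$gamma, ratios$se_gamma)
        G <- rnorm(k, ratios$Gamma, ratios$se_Gamma)
        if (any(g == 0)) g[g == 0] <- .Machine$double.eps
        bb <- G / g
        ss2 <- ratios$se_Gamma^2 / g^2 + G^2 * ratios$se_gamma^2 / g^4
        weighted_median_point(bb, 1 / ss2)
      } else {
        weighted_median_point(rnorm(k, b, s), w)
      }
    }, numeric(1))
  })
  se_boot <- stats::sd(boots)
  structure(
    list(beta = est, se_boot = se_boot,
         ci_low = est - qnorm(0.975) * se_boot,
         ci_high = est + qnorm(0.975) * se_boot,
         p = two_sided_p(est / se_boot),
         n_boot = n_boot, seed = seed, n_instruments = k),
    class = "weighted_median_mr"
  )
}

#' @export
print.weighted_median_mr <- function(x, ...) {
  cat(sprintf("<weighted_median_mr> %d instruments, %d bootstrap resamples\n",
              x$n_instruments, x$n_boot))
  cat(sprintf("  OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              exp(x$beta), exp(x$ci_low), exp(x$ci_high), x$p))
  invisible(x)
}

#' Rescale MR estimates to a different iron biomarker
#'
#' Recomputes the per-instrument ratio denominators with the chosen
#' biomarker's instrument associations and re-pools, expressing the causal
#' estimate per 1 SD of that biomarker. Because higher transferrin reflects
#' lower iron status (its instrument effects have the opposite sign),
#' transferrin-scaled estimates flip direction relative to iron-scaled ones.
#'
#' @param instruments Instrument tibble with the biomarker's `beta_*`/`se_*`
#'   columns.
#' @param associations Harmonizable outcome association tibble (see
#'   [harmonize()]).
#' @param biomarker One of `"serum_iron"`, `"log10_ferritin"`,
#'   `"transferrin"`, `"transferrin_saturation"`.
#' @return An `ivw_mr` object on the chosen biomarker's SD scale.
#' @export
rescale_to_biomarker <- function(instruments, associations,
                                 biomarker = "log10_ferritin") {
  h <- harmonize(instruments, associations, biomarker = biomarker)
  ivw_meta(ratio_estimate(h$gamma, h$se_gamma, h$beta, h$se, rsid = h$rsid))
}

#' Export scatter data for one outcome
#'
#' Plot-ready per-instrument pairs of SNP-exposure and SNP-outcome
#' associations with standard errors, as used for MR scatter diagnostics.
#'
#' @param harmonized Output of [harmonize()] for one phecode.
#' @return Tibble `rsid`, `gamma`, `se_gamma`, `Gamma`, `se_Gamma`.
#' @export
mr_scatter_data <- function(harmonized) {
  tibble::tibble(rsid = harmonized$rsid,
                 gamma = harmonized$gamma, se_gamma = harmonized$se_gamma,
                 Gamma = harmonized$beta, se_Gamma = harmonized$se)
}
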