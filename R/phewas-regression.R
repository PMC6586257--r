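#' Fit one SNP-phecode logistic regression
#'
#' Maximum-likelihood logistic regression of case status on additive effect
#' allele dosage, adjusting for age, sex, genotyping array, and the first
#' four genetic principal components. The excluded set of the case/control
#' object is omitted entirely. The dosage coefficient is reported as a
#' log-OR per copy of the effect allele with its Wald standard error and a
#' two-sided normal p-value. Non-convergence, (quasi-)separation, or a
#' singular design never raise an error: they return a flagged-failure row
#' so a phenome scan is never aborted by one outcome.
#'
#' @param dosage Either a named numeric vector of effect-allele dosages
#'   (names = person ids) or a two-column tibble `person_id`, `dosage`.
#'   Fractional (imputed) dosages in `[0, 2]` are accepted.
#' @param case_control A [build_case_control()] result.
#' @param covariates Tibble `person_id`, `age`, `sex`, `array`, `pc1`..`pc4`;
#'   must be complete for every case and control.
#' @param rsid,effect_allele Labels copied into the output row.
#' @param include_sex Keep sex as a covariate (dropped automatically in
#'   sex-stratified runs where it is constant).
#' @param firth Use Firth's bias-reduced penalized likelihood instead of
#'   plain MLE (useful for rare outcomes prone to separation).
#' @param maxit,epsilon IRLS iteration cap and coefficient-change tolerance.
#' @return One-row tibble: `rsid`, `phecode_id`, `effect_allele`, `beta`,
#'   `se`, `p`, `n_cases`, `n_controls`, `converged`, `note`.
#' @export
fit_snp_phecode <- function(dosage, case_control, covariates,
                            rsid = NA_character_, effect_allele = NA_character_,
                            include_sex = TRUE, firth = FALSE,
                            maxit = 100, epsilon = 1e-8) {
  stopifnot(inherits(case_control, "case_control_set"))
  if (!length(case_control$case_ids) || !length(case_control$control_ids)) {
    abort("Need at least one case and one control.")
  }
  if (is.data.frame(dosage)) {
    dosage <- stats::setNames(dosage[[2]], as.character(dosage[[1]]))
  }
  ids <- c(case_control$case_ids, case_control$control_ids)
  y <- rep(c(1L, 0L), c(length(case_control$case_ids),
                        length(case_control$control_ids)))
  cov <- covariates[match(ids, covariates$person_id), , drop = FALSE]
  g <- dosage[as.character(ids)]
  if (anyNA(cov$person_id) || anyNA(g)) {
    abort("Covariates and dosages must be complete for all cases and controls.")
  }
  cov_cols <- c("age", if (include_sex) "sex", "array",
                paste0("pc", 1:4))
  if (anyNA(as.matrix(cov[cov_cols]))) {
    abort("Covariates contain missing values for included individuals.")
  }
  X <- cbind(`(Intercept)` = 1, dosage = as.numeric(g),
             as.matrix(cov[cov_cols]))
  # Constant covariate columns (e.g. sex within a stratum) carry no
  # information; drop them rather than failing on a singular design.
  keep <- c(TRUE, TRUE, apply(X[, -(1:2), drop = FALSE], 2,
                              function(v) stats::var(v) > 0))
  X <- X[, keep, drop = FALSE]
  row <- function(beta, se, p, converged, note) {
    tibble::tibble(rsid = rsid, phecode_id = case_control$phecode_id,
                   effect_allele = effect_allele, beta = beta, se = se, p = p,
                   n_cases = length(case_control$case_ids),
                   n_controls = length(case_control$control_ids),
                   converged = converged, note = note)
  }
  if (stats::var(X[, "dosage"]) == 0) {
    return(row(NA_real_, NA_real_, NA_real_, FALSE, "constant dosage"))
  }
  fit <- tryCatch(
    if (firth) {
      firth_logistic(X, y, maxit = maxit, epsilon = epsilon)
    } else {
      f <- suppressWarnings(glm.fit(
        X, y, family = binomial(),
        control = glm.control(epsilon = epsilon, maxit = maxit)))
      p <- f$rank
      if (p < ncol(X)) {
        list(converged = FALSE, note = "singular design")
      } else {
        R <- f$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
        covmat <- chol2inv(R)
        se <- rep(NA_real_, ncol(X))
        se[f$qr$pivot[seq_len(p)]] <- sqrt(diag(covmat))
        list(coef = f$coefficients, se = se,
             converged = f$converged, note = NA_character_)
      }
    },
    error = function(e) list(converged = FALSE, note = conditionMessage(e))
  )
  if (!isTRUE(fit$converged)) {
    return(row(NA_real_, NA_real_, NA_real_, FALSE,
               fit$note %||% "did not converge"))
  }
  j <- match("dosage", colnames(X))
  beta <- unname(fit$coef[j]); se <- unname(fit$se[j])
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 12 || se > 20) {
    return(row(NA_real_, NA_real_, NA_real_, FALSE, "separation suspected"))
  }
  row(beta, se, two_sided_p(beta / se), TRUE, NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Firth bias-reduced logistic regression via IRLS with the hat-diagonal
# score correction (Jeffreys-prior penalty).
firth_logistic <- function(X, y, maxit = 100, epsilon = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    Vinv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(Vinv)) return(list(converged = FALSE, note = "singular design"))
    h <- rowSums((XW %*% Vinv) * XW)
    U <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    delta <- drop(Vinv %*% U)
    # step-halving to keep the penalized likelihood stable
    if (max(abs(delta)) > 5) delta <- delta * 5 / max(abs(delta))
    beta <- beta + delta
    if (max(abs(delta)) < epsilon) {
      return(list(coef = stats::setNames(beta, colnames(X)),
                  se = sqrt(diag(Vinv)), converged = TRUE,
                  note = NA_character_))
    }
  }
  list(converged = FALSE, note = "Firth IRLS did not converge")
}

#' Run a phenome-wide association scan for a set of instrument SNPs
#'
#' Fits [fit_snp_phecode()] for every (SNP, phecode) combination. For
#' sex-stratified runs, individuals of the other sex are removed, the sex
#' covariate is dropped, and the minimum-case filter is re-applied within
#' the stratum (a stratum also needs at least one control).
#'
#' @param genotypes Cohort genotype tibble (`person_id` + one dosage column
#'   per rsid).
#' @param sets Named list of `case_control_set` objects (already filtered by
#'   [filter_min_cases()] for the combined analysis).
#' @param covariates Cohort covariate tibble.
#' @param snps Tibble with at least `rsid`, `effect_allele`,
#'   `other_allele`; every rsid must be a genotype column.
#' @param sex_filter `"all"`, `"male"`, or `"female"` (`sex` coded 1 =
#'   female).
#' @param min_cases Per-stratum minimum case count.
#' @param firth Passed to [fit_snp_phecode()].
#' @return Tibble of association estimates, one row per (SNP, phecode),
#'   including flagged non-converged rows; plus columns `other_allele` and
#'   `sex_stratum`.
#' @export
run_phewas <- function(genotypes, sets, covariates, snps,
                       sex_filter = c("all", "male", "female"),
                       min_cases = 200, firth = FALSE) {
  sex_filter <- match.arg(sex_filter)
  missing <- setdiff(snps$rsid, names(genotypes))
  if (length(missing)) {
    abort(paste0("Genotype columns missing for: ",
                 paste(missing, collapse = ", ")))
  }
  include_sex <- sex_filter == "all"
  if (!include_sex) {
    keep_ids <- covariates$person_id[
      covariates$sex == (if (sex_filter == "female") 1L else 0L)]
    sets <- lapply(sets, function(s) {
      s$case_ids <- intersect(s$case_ids, keep_ids)
      s$control_ids <- intersect(s$control_ids, keep_ids)
      s$excluded_ids <- intersect(s$excluded_ids, keep_ids)
      s
    })
    sets <- Filter(function(s) length(s$case_ids) >= min_cases &&
                     length(s$control_ids) >= 1, sets)
  }
  out <- purrr::map(sets, function(s) {
    purrr::pmap(snps[c("rsid", "effect_allele", "other_allele")],
                function(rsid, effect_allele, other_allele) {
      est <- fit_snp_phecode(
        stats::setNames(genotypes[[rsid]],
                        as.character(genotypes$person_id)),
        s, covariates, rsid = rsid, effect_allele = effect_allele,
        include_sex = include_sex, firth = firth)
      est$other_allele <- other_allele
      est
    })
  })
  res <- dplyr::bind_rows(purrr::flatten(out))
  if (nrow(res)) res$sex_stratum <- sex_filter
  res
}
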