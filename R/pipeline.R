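#' Benjamini-Hochberg false-discovery-rate step-up procedure
#'
#' Orders the p-values, finds the largest index `k` with
#' `p_(k) <= (k/m) q`, and flags the `k` smallest p-values. The realized
#' threshold `(k/m) q` is returned so a scan can report the p-value cutoff
#' its FDR level corresponds to. Benjamini-Yekutieli (an extra `log(m)`-ish
#' penalty valid under arbitrary dependence) is available via `method`.
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @param q Target false discovery rate.
#' @param method `"BH"` (default) or `"BY"`.
#' @return A list: `significant` (logical, input order), `threshold`
#'   (realized p-value cutoff; 0 when nothing is flagged),
#'   `n_significant`, `m`, `q`, `method`.
#' @export
#' @examples
#' bh_fdr(c(0.001, 0.01, 0.2, 0.9), q = 0.05)
bh_fdr <- function(p, q = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (!length(p)) abort("`p` must be non-empty.")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("All p-values must lie in (0, 1].")
  }
  check_prob(q, "q")
  m <- length(p)
  cm <- if (method == "BY") sum(1 / seq_len(m)) else 1
  ps <- sort(p)
  crit <- seq_len(m) / m * q / cm
  ok <- which(ps <= crit)
  k <- if (length(ok)) max(ok) else 0L
  threshold <- if (k > 0) k / m * q / cm else 0
  list(significant = p <= threshold & k > 0, threshold = threshold,
       n_significant = k, m = m, q = q, method = method)
}

#' Split significant outcomes by heterogeneity evidence
#'
#' FDR-significant outcomes whose per-instrument MR estimates show no
#' heterogeneity (Cochran Q p >= `q_alpha`) form the "consistent" list taken
#' forward; significant outcomes with heterogeneity evidence are set aside
#' as possibly driven by pleiotropy.
#'
#' @param rows Tibble with logical `fdr_significant` and numeric `q_p`.
#' @param q_alpha Heterogeneity significance level.
#' @return List: `consistent` and `heterogeneous_excluded` tibbles, plus
#'   `n_consistent`, `n_heterogeneous`.
#' @export
classify_outcomes <- function(rows, q_alpha = 0.05) {
  rows <- dplyr::mutate(rows, heterogeneous = .data$q_p < q_alpha)
  consistent <- dplyr::filter(rows, .data$fdr_significant,
                              !.data$heterogeneous)
  het <- dplyr::filter(rows, .data$fdr_significant, .data$heterogeneous)
  list(consistent = consistent, heterogeneous_excluded = het,
       n_consistent = nrow(consistent), n_heterogeneous = nrow(het))
}

#' Approximate power of an MR test for a binary outcome
#'
#' Advisory normal-approximation power to detect a causal log-OR `beta` per
#' exposure SD at level `alpha`, given the case/control split and the
#' exposure variance explained by the instruments (`r2`). Never used to
#' filter outcomes; the minimum-case rule is the only gate.
#'
#' @param n_cases,n_controls Counts.
#' @param beta Log-OR per exposure SD to detect.
#' @param r2 Instrument R^2 on the exposure.
#' @param alpha Two-sided test level.
#' @return Approximate power in `[0, 1]`.
#' @export
approx_power <- function(n_cases, n_controls, beta, r2 = 0.038,
                         alpha = 0.05) {
  n_eff <- n_cases * n_controls / (n_cases + n_controls)
  pnorm(sqrt(r2 * n_eff) * abs(beta) - qnorm(1 - alpha / 2))
}

#' Pipeline run configuration
#'
#' @param min_cases Minimum case count per phecode (and per sex stratum).
#' @param fdr_q FDR level for the phenome-wide screen.
#' @param q_alpha Cochran Q significance level flagging heterogeneity.
#' @param n_boot Bootstrap resamples for the weighted median.
#' @param seed Master seed.
#' @param sd_serum_iron Serum-iron SD (umol/L) used by [scale_to_sd()] when
#'   instrument effects arrive in absolute units.
#' @param kinship_threshold Relatedness pruning threshold.
#' @param stratify_sex Also run male/female stratified analyses for the
#'   consistent outcomes.
#' @param rescale_biomarkers Biomarkers to rescale consistent outcomes to
#'   (`character(0)` to skip).
#' @param fdr_method `"BH"` or `"BY"`.
#' @param firth Use Firth regression in the PheWAS fits.
#' @return A `run_config` list.
#' @export
run_config <- function(min_cases = 200, fdr_q = 0.05, q_alpha = 0.05,
                       n_boot = 1000, seed = 1, sd_serum_iron = 6.1,
                       kinship_threshold = 0.0884, stratify_sex = FALSE,
                       rescale_biomarkers = c("log10_ferritin", "transferrin",
                                              "transferrin_saturation"),
                       fdr_method = "BH", firth = FALSE) {
  check_count(min_cases, "min_cases", min = 1)
  check_prob(fdr_q, "fdr_q")
  check_prob(q_alpha, "q_alpha")
  structure(
    list(min_cases = min_cases, fdr_q = fdr_q, q_alpha = q_alpha,
         n_boot = n_boot, seed = seed, sd_serum_iron = sd_serum_iron,
         kinship_threshold = kinship_threshold, stratify_sex = stratify_sex,
         rescale_biomarkers = rescale_biomarkers, fdr_method = fdr_method,
         firth = firth),
    class = "run_config"
  )
}

#' Run the full MR-PheWAS pipeline
#'
#' Executes the whole analysis on a cohort: relatedness pruning, ICD-to-
#' phecode mapping, case/control construction with exclusion ranges and the
#' minimum-case filter, per-SNP covariate-adjusted logistic PheWAS,
#' harmonization against the instruments, per-phecode ratio estimates, IVW
#' pooling with Cochran Q, the bootstrap weighted median, phenome-wide BH
#' FDR flags, and the heterogeneity screen. Optionally reruns the
#' FDR-significant homogeneous ("consistent") outcomes sex-stratified and
#' rescaled to the other iron biomarkers. Deterministic for a fixed seed; a
#' run manifest with the configuration and stage-by-stage counts is always
#' attached.
#'
#' @param cohort A `synthetic_cohort` or a list with the same elements
#'   (`genotypes`, `covariates`, `icd_events`, `kinship`, `phecode_map`).
#' @param instruments Instrument tibble; defaults to the packaged synthetic
#'   instruments.
#' @param config A [run_config()].
#' @param phecode_map Optional override of `cohort$phecode_map`.
#' @return An `mr_phewas_result`: list with `results` (one row per analyzed
#'   phecode), `phewas` (per-SNP association estimates), `counts`,
#'   `classification`, `stratified`, `rescaled`, `fdr`, and `manifest`.
#' @export
run_full_pipeline <- function(cohort, instruments = default_instruments(),
                              config = run_config(), phecode_map = NULL) {
  stopifnot(inherits(config, "run_config"))
  instruments <- validate_instruments(instruments)
  map <- phecode_map %||% cohort$phecode_map
  if (is.null(map)) abort("No phecode map supplied.")
  map <- validate_phecode_map(map)
  snps <- instruments[c("rsid", "effect_allele", "other_allele")]

  retained <- prune_related(cohort$covariates$person_id, cohort$kinship,
                            threshold = config$kinship_threshold,
                            seed = config$seed)
  incidence <- map_icd_to_phecodes(cohort$icd_events, map)
  phecodes_seen <- sort(unique(incidence$phecode))
  sets <- build_case_control_sets(incidence, map, retained,
                                  phecodes = phecodes_seen)
  kept <- filter_min_cases(sets, minimum = config$min_cases)

  phewas <- run_phewas(cohort$genotypes, kept, cohort$covariates, snps,
                       sex_filter = "all", min_cases = config$min_cases,
                       firth = config$firth)
  n_fail <- if (nrow(phewas)) sum(!phewas$converged) else 0L

  results <- mr_phewas_table(phewas, instruments, config)
  if (nrow(results)) {
    info <- dplyr::distinct(map[c("phecode", "description", "category")])
    info <- info[!duplicated(info$phecode), ]
    results <- dplyr::left_join(results, info,
                                by = c(phecode_id = "phecode"))
  }
  fdr <- NULL
  classification <- list(consistent = results[0, ],
                         heterogeneous_excluded = results[0, ],
                         n_consistent = 0L, n_heterogeneous = 0L)
  if (nrow(results)) {
    fdr <- bh_fdr(results$p_ivw, q = config$fdr_q,
                  method = config$fdr_method)
    results$fdr_significant <- fdr$significant
    results$heterogeneous <- results$q_p < config$q_alpha
    results$power_approx <- approx_power(
      results$n_cases, results$n_controls, results$beta_ivw,
      r2 = instrument_r2(instruments))
    classification <- classify_outcomes(results, q_alpha = config$q_alpha)
  }

  consistent_ids <- classification$consistent$phecode_id
  stratified <- NULL
  if (config$stratify_sex && length(consistent_ids)) {
    stratified <- dplyr::bind_rows(lapply(c("male", "female"), function(sx) {
      ph <- run_phewas(cohort$genotypes, kept[consistent_ids],
                       cohort$covariates, snps, sex_filter = sx,
                       min_cases = config$min_cases, firth = config$firth)
      mr_phewas_table(ph, instruments, config)
    }))
  }

  rescaled <- NULL
  if (length(config$rescale_biomarkers) && length(consistent_ids)) {
    sub <- phewas[phewas$phecode_id %in% consistent_ids &
                    phewas$converged, , drop = FALSE]
    rescaled <- dplyr::bind_rows(lapply(config$rescale_biomarkers,
                                        function(bm) {
      dplyr::bind_rows(lapply(split(sub, sub$phecode_id), function(d) {
        ivw <- rescale_to_biomarker(instruments, d, biomarker = bm)
        tibble::tibble(phecode_id = d$phecode_id[1], biomarker = bm,
                       beta_ivw = ivw$beta, se_ivw = ivw$se,
                       ci_low = ivw$ci_low, ci_high = ivw$ci_high,
                       p_ivw = ivw$p)
      }))
    }))
  }

  counts <- case_control_counts(kept, map)
  manifest <- list(
    config = unclass(config),
    n_individuals = nrow(cohort$covariates),
    n_retained = length(retained),
    n_icd_events = nrow(cohort$icd_events),
    n_phecodes_mapped = length(phecodes_seen),
    n_phecodes_min_cases = length(kept),
    n_phecodes_dropped_by_filter = length(sets) - length(kept),
    n_fits = nrow(phewas),
    n_fit_failures = n_fail,
    n_phecodes_analyzed = nrow(results),
    n_significant = if (is.null(fdr)) 0L else fdr$n_significant,
    fdr_realized_threshold = if (is.null(fdr)) NA_real_ else fdr$threshold,
    n_consistent = classification$n_consistent,
    n_heterogeneous_excluded = classification$n_heterogeneous
  )
  structure(
    list(results = results, phewas = phewas, counts = counts,
         classification = classification, stratified = stratified,
         rescaled = rescaled, fdr = fdr, manifest = manifest,
         instruments = instruments),
    class = "mr_phewas_result"
  )
}

# Combine per-SNP association estimates into per-phecode MR rows.
mr_phewas_table <- function(phewas, instruments, config) {
  if (!nrow(phewas)) return(empty_results_tibble())
  ok <- phewas[phewas$converged, , drop = FALSE]
  rows <- lapply(split(ok, ok$phecode_id), function(d) {
    if (nrow(d) < 2) return(NULL) # need >= 2 instruments to pool
    h <- harmonize(instruments, d, biomarker = "serum_iron")
    ratios <- ratio_estimate(h$gamma, h$se_gamma, h$beta, h$se, rsid = h$rsid)
    ivw <- ivw_meta(ratios)
    wm <- if (nrow(ratios) >= 3) {
      weighted_median(ratios, n_boot = config$n_boot,
                      seed = stage_seed(config$seed,
                                        paste0("wm-", d$phecode_id[1])))
    }
    tibble::tibble(
      phecode_id = d$phecode_id[1],
      sex_stratum = d$sex_stratum[1],
      n_cases = min(d$n_cases), n_controls = min(d$n_controls),
      n_instruments = nrow(ratios),
      ratios = list(ratios),
      beta_ivw = ivw$beta, se_ivw = ivw$se,
      ci_low_ivw = ivw$ci_low, ci_high_ivw = ivw$ci_high, p_ivw = ivw$p,
      q_stat = ivw$q_stat, q_df = ivw$q_df, q_p = ivw$q_p,
      beta_wm = if (is.null(wm)) NA_real_ else wm$beta,
      se_wm = if (is.null(wm)) NA_real_ else wm$se_boot,
      ci_low_wm = if (is.null(wm)) NA_real_ else wm$ci_low,
      ci_high_wm = if (is.null(wm)) NA_real_ else wm$ci_high,
      p_wm = if (is.null(wm)) NA_real_ else wm$p
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(empty_results_tibble())
  out$or_ivw <- exp(out$beta_ivw)
  out$or_ci_low <- exp(out$ci_low_ivw)
  out$or_ci_high <- exp(out$ci_high_ivw)
  out$fdr_significant <- NA
  out$heterogeneous <- NA
  dplyr::arrange(out, .data$p_ivw)
}

empty_results_tibble <- function() {
  tibble::tibble(phecode_id = character(), sex_stratum = character(),
                 n_cases = integer(), n_controls = integer(),
                 n_instruments = integer(), ratios = list(),
                 beta_ivw = numeric(), se_ivw = numeric(),
                 ci_low_ivw = numeric(), ci_high_ivw = numeric(),
                 p_ivw = numeric(), q_stat = numeric(), q_df = integer(),
                 q_p = numeric(), beta_wm = numeric(), se_wm = numeric(),
                 ci_low_wm = numeric(), ci_high_wm = numeric(),
                 p_wm = numeric(), or_ivw = numeric(),
                 or_ci_low = numeric(), or_ci_high = numeric(),
                 fdr_significant = logical(), heterogeneous = logical())
}

#' @export
print.mr_phewas_result <- function(x, ...) {
  m <- x$manifest
  cat("<mr_phewas_result>\n")
  cat(sprintf("  %d individuals (%d retained after relatedness pruning)\n",
              m$n_individuals, m$n_retained))
  cat(sprintf("  %d phecodes analyzed, %d FDR-significant (threshold %.3g), %d consistent\n",
              m$n_phecodes_analyzed, m$n_significant,
              m$fdr_realized_threshold, m$n_consistent))
  invisible(x)
}

#' Descriptive summaries of a cohort
#'
#' Produces a participant-characteristics table (counts, age, sex, array,
#' biomarker moments) and, when case/control sets and a map are supplied, a
#' per-disease-category table of phenotype counts and case-count
#' min/median/mean/max.
#'
#' @param cohort A `synthetic_cohort`-like list.
#' @param sets Optional named list of `case_control_set` objects.
#' @param phecode_map Optional map for category labels (defaults to
#'   `cohort$phecode_map`).
#' @return List with `characteristics` and `categories` tibbles.
#' @export
summarize_cohort <- function(cohort, sets = NULL, phecode_map = NULL) {
  cv <- cohort$covariates
  chr <- tibble::tibble(
    characteristic = c("N", "Age, years (SD)", "Sex, female (%)",
                       "Genotyping array (%)", "Serum iron, SD units (SD)"),
    value = c(nrow(cv), mean(cv$age), 100 * mean(cv$sex),
              100 * mean(cv$array),
              if (!is.null(cohort$biomarkers)) {
                mean(cohort$biomarkers$serum_iron)
              } else NA_real_),
    spread = c(NA, sd(cv$age), NA, NA,
               if (!is.null(cohort$biomarkers)) {
                 sd(cohort$biomarkers$serum_iron)
               } else NA_real_)
  )
  categories <- NULL
  if (!is.null(sets)) {
    map <- phecode_map %||% cohort$phecode_map
    counts <- case_control_counts(sets, map)
    if (nrow(counts) && "category" %in% names(counts)) {
      categories <- dplyr::summarise(
        dplyr::group_by(counts, .data$category),
        phenotypes = dplyr::n(),
        cases_min = min(.data$n_cases),
        cases_median = stats::median(.data$n_cases),
        cases_mean = mean(.data$n_cases),
        cases_max = max(.data$n_cases),
        .groups = "drop"
      )
    } else {
      categories <- tibble::tibble(category = character(),
                                   phenotypes = integer(),
                                   cases_min = integer(),
                                   cases_median = numeric(),
                                   cases_mean = numeric(),
                                   cases_max = integer())
    }
  }
  list(characteristics = chr, categories = categories)
}

#' Write pipeline result tables and the run manifest
#'
#' Emits tab-delimited `results.tsv`, `phewas.tsv`, `counts.tsv` (plus
#' stratified/rescaled tables when present) and `manifest.json` to `dir`.
#'
#' @param result An `mr_phewas_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "mr_phewas_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- dplyr::select(result$results, -"ratios")
  readr::write_tsv(flat, file.path(dir, "results.tsv"))
  readr::write_tsv(result$phewas, file.path(dir, "phewas.tsv"))
  readr::write_tsv(result$counts, file.path(dir, "counts.tsv"))
  if (!is.null(result$stratified) && nrow(result$stratified)) {
    readr::write_tsv(dplyr::select(result$stratified, -"ratios"),
                     file.path(dir, "stratified.tsv"))
  }
  if (!is.null(result$rescaled) && nrow(result$rescaled)) {
    readr::write_tsv(result$rescaled, file.path(dir, "rescaled.tsv"))
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
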