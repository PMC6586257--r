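#' Describe a synthetic cohort scenario
#'
#' A scenario bundles everything the cohort simulator needs: the instrument
#' SNPs (allele frequencies and per-allele effects on standardized serum
#' iron), the disease scenarios to embed in the hospital-event table, the
#' relatedness structure, and a master seed. Defaults emulate a European
#' biobank-style study: genotypes in Hardy-Weinberg equilibrium, biomarkers
#' standardized to unit variance with instruments jointly explaining about
#' 3.8% of serum-iron variance, 54% female participants aged 40-69, and
#' modest nonzero age/sex effects on disease so covariate adjustment in the
#' downstream regressions is actually exercised.
#'
#' @param n_individuals Number of participants.
#' @param snps Tibble with columns `rsid`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta_iron_sd_units` (per-allele effect on standardized serum
#'   iron). Defaults to the packaged synthetic instruments.
#' @param biomarker_noise_sd Residual SD of serum iron. `NULL` (default)
#'   chooses `sqrt(1 - R2)` so the marginal variance is 1 SD unit.
#' @param phecode_scenarios Tibble of disease scenarios; build rows with
#'   [phecode_scenario()]. May be empty.
#' @param n_related_pairs Number of disjoint related pairs to emit.
#' @param kinship_range Length-2 numeric; kinship coefficients are drawn
#'   uniformly from this range.
#' @param female_fraction Cohort fraction of female participants.
#' @param age_log_or_per_decade,sex_log_or Covariate effects (log odds
#'   ratios) applied to every disease scenario; set to 0 to disable.
#' @param seed Master seed; every stochastic stage derives its own stream
#'   from it via [stage_seed()], so a fixed seed gives byte-identical output.
#' @return A `scenario_config` object (a validated list).
#' @export
#' @examples
#' cfg <- scenario_config(n_individuals = 500, seed = 7)
#' cohort <- simulate_cohort(cfg)
scenario_config <- function(n_individuals = 10000,
                            snps = NULL,
                            biomarker_noise_sd = NULL,
                            phecode_scenarios = NULL,
                            n_related_pairs = 0,
                            kinship_range = c(0.09, 0.25),
                            female_fraction = 0.54,
                            age_log_or_per_decade = 0.3,
                            sex_log_or = 0.2,
                            seed = 1) {
  n_individuals <- check_count(n_individuals, "n_individuals", min = 1)
  if (is.null(snps)) {
    ins <- default_instruments()
    snps <- tibble::tibble(
      rsid = ins$rsid, effect_allele = ins$effect_allele,
      other_allele = ins$other_allele, eaf = ins$eaf,
      beta_iron_sd_units = ins$beta_serum_iron
    )
  }
  check_prob(snps$eaf, "snps$eaf")
  if (is.null(phecode_scenarios)) {
    phecode_scenarios <- phecode_scenario(character(0), numeric(0))
  }
  if (nrow(phecode_scenarios)) {
    check_prob(phecode_scenarios$baseline_prevalence, "baseline_prevalence")
  }
  n_related_pairs <- check_count(n_related_pairs, "n_related_pairs")
  if (n_related_pairs > n_individuals / 2) {
    abort("`n_related_pairs` must not exceed n_individuals / 2 (pairs are disjoint).")
  }
  if (length(kinship_range) != 2 || any(!is.finite(kinship_range)) ||
      any(kinship_range < 0) || kinship_range[1] > kinship_range[2]) {
    abort("`kinship_range` must be a nondecreasing pair of nonnegative numbers.")
  }
  check_prob(female_fraction, "female_fraction")
  r2 <- sum(2 * snps$eaf * (1 - snps$eaf) * snps$beta_iron_sd_units^2)
  if (is.null(biomarker_noise_sd)) {
    if (r2 >= 1) abort("Configured SNP effects imply exposure R^2 >= 1.")
    biomarker_noise_sd <- sqrt(1 - r2)
  }
  if (!is.finite(biomarker_noise_sd) || biomarker_noise_sd < 0) {
    abort("`biomarker_noise_sd` must be a nonnegative finite number.")
  }
  structure(
    list(n_individuals = n_individuals, snps = tibble::as_tibble(snps),
         biomarker_noise_sd = biomarker_noise_sd,
         phecode_scenarios = tibble::as_tibble(phecode_scenarios),
         n_related_pairs = n_related_pairs, kinship_range = kinship_range,
         female_fraction = female_fraction,
         age_log_or_per_decade = age_log_or_per_decade,
         sex_log_or = sex_log_or, seed = seed, r2_serum_iron = r2),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat("  individuals:", x$n_individuals, " seed:", x$seed, "\n")
  cat("  SNPs:", paste(x$snps$rsid, collapse = ", "),
      sprintf("(serum-iron R^2 = %.4f)\n", x$r2_serum_iron))
  cat("  phecode scenarios:", nrow(x$phecode_scenarios),
      " related pairs:", x$n_related_pairs, "\n")
  invisible(x)
}

#' Define one disease scenario for the phenome generator
#'
#' @param phecode_id Phecode identifier(s), e.g. `"280.1"`.
#' @param baseline_prevalence Disease prevalence at covariate means with no
#'   genetic effect.
#' @param causal_log_or_per_sd_iron Causal log odds ratio per 1 SD of serum
#'   iron (0 for a null outcome).
#' @param direct_snp_log_ors Named numeric vector of per-allele direct
#'   (pleiotropic) log-OR effects bypassing serum iron, or `NULL`.
#' @param sex_ratio Target fraction of cases that are female, or `NA` to use
#'   the scenario-wide sex effect.
#' @return A one-row tibble (rows can be `dplyr::bind_rows()`-ed).
#' @export
#' @examples
#' phecode_scenario("280.1", 0.05, causal_log_or_per_sd_iron = log(0.72))
phecode_scenario <- function(phecode_id, baseline_prevalence,
                             causal_log_or_per_sd_iron = 0,
                             direct_snp_log_ors = NULL,
                             sex_ratio = NA_real_) {
  n <- length(phecode_id)
  tibble::tibble(
    phecode_id = as.character(phecode_id),
    baseline_prevalence = rep_len(baseline_prevalence, n),
    causal_log_or_per_sd_iron = rep_len(causal_log_or_per_sd_iron, n),
    direct_snp_log_ors = if (is.null(direct_snp_log_ors)) {
      rep_len(list(NULL), n)
    } else if (is.list(direct_snp_log_ors)) {
      rep_len(direct_snp_log_ors, n)
    } else {
      rep_len(list(direct_snp_log_ors), n)
    },
    sex_ratio = rep_len(sex_ratio, n)
  )
}

#' Draw instrument genotypes under Hardy-Weinberg equilibrium
#'
#' Each SNP column is sampled independently as Binomial(2, EAF) dosages of the
#' effect allele.
#'
#' @param config A [scenario_config()].
#' @return Tibble with `person_id` and one integer dosage column per rsid.
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  check_prob(config$snps$eaf, "eaf")
  n <- config$n_individuals
  with_stage_seed(config$seed, "genotypes", {
    cols <- lapply(config$snps$eaf, function(p) rbinom(n, 2L, p))
  })
  names(cols) <- config$snps$rsid
  dplyr::bind_cols(tibble::tibble(person_id = seq_len(n)),
                   tibble::as_tibble(cols))
}

#' Generate the four standardized iron biomarkers
#'
#' Serum iron is the per-SNP genetic score plus Gaussian noise; log10
#' ferritin, transferrin, and transferrin saturation are fixed linear
#' loadings on serum iron plus independent noise, with the transferrin
#' loading negative, and each biomarker has marginal variance 1 (SD units)
#' when the default residual SD is used.
#'
#' @param genotypes Output of [generate_genotypes()].
#' @param config The matching [scenario_config()].
#' @return Tibble `person_id`, `serum_iron`, `log10_ferritin`,
#'   `transferrin`, `transferrin_saturation`.
#' @export
generate_biomarkers <- function(genotypes, config) {
  stopifnot(inherits(config, "scenario_config"))
  if (!all(config$snps$rsid %in% names(genotypes))) {
    abort("`genotypes` does not contain a column for every configured SNP.")
  }
  if (config$biomarker_noise_sd < 0) abort("Noise SD must be nonnegative.")
  G <- as.matrix(genotypes[config$snps$rsid])
  score <- as.vector(G %*% config$snps$beta_iron_sd_units)
  # centre so biomarkers are mean-zero in expectation
  score <- score - sum(2 * config$snps$eaf * config$snps$beta_iron_sd_units)
  n <- nrow(G)
  with_stage_seed(config$seed, "biomarkers", {
    iron <- score + rnorm(n, 0, config$biomarker_noise_sd)
    others <- lapply(BIOMARKER_LOADINGS, function(l) {
      l * iron + rnorm(n, 0, sqrt(max(1 - l^2, 0)))
    })
  })
  tibble::tibble(
    person_id = genotypes$person_id,
    serum_iron = iron,
    log10_ferritin = others$log10_ferritin,
    transferrin = others$transferrin,
    transferrin_saturation = others$transferrin_saturation
  )
}

#' Generate covariates for a synthetic cohort
#'
#' Age in years (roughly 40-69, mean ~57), binary sex (1 = female),
#' genotyping array indicator, and four standard-normal principal
#' components.
#'
#' @inheritParams generate_biomarkers
#' @return Tibble `person_id`, `age`, `sex`, `array`, `pc1`..`pc4`.
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_individuals
  with_stage_seed(config$seed, "covariates", {
    tibble::tibble(
      person_id = seq_len(n),
      age = pmin(pmax(rnorm(n, 56.8, 8), 40), 69),
      sex = rbinom(n, 1L, config$female_fraction),
      array = rbinom(n, 1L, 0.11),
      pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n), pc4 = rnorm(n)
    )
  })
}

#' Generate hospital ICD events from disease scenarios
#'
#' For each configured phecode, case status is drawn from a logistic model:
#' an intercept calibrated to the baseline prevalence, plus the causal serum
#' iron effect, any direct (pleiotropic) per-SNP effects, and centred
#' age/sex covariate effects. Each case emits one ICD event using a code
#' mapped to the phecode (ICD-10 preferred). Null scenarios (all genetic
#' effects zero) reduce to covariate-only logistic draws.
#'
#' @param genotypes,biomarkers,covariates Cohort tables from the generators
#'   above.
#' @param config The [scenario_config()].
#' @param phecode_map A phecode map tibble (see [read_phecode_map()]); every
#'   scenario phecode must map to at least one ICD code.
#' @return Long tibble `person_id`, `icd_version`, `code`.
#' @export
generate_phenome <- function(genotypes, biomarkers, covariates, config,
                             phecode_map) {
  stopifnot(inherits(config, "scenario_config"))
  sc <- config$phecode_scenarios
  if (!nrow(sc)) {
    return(tibble::tibble(person_id = integer(), icd_version = integer(),
                          code = character()))
  }
  missing <- setdiff(sc$phecode_id, phecode_map$phecode)
  if (length(missing)) {
    abort(paste0("Scenario phecode(s) with no mapped ICD code: ",
                 paste(missing, collapse = ", ")))
  }
  G <- as.matrix(genotypes[config$snps$rsid])
  age_c <- (covariates$age - mean(covariates$age)) / 10
  sex_c <- covariates$sex - mean(covariates$sex)
  events <- with_stage_seed(config$seed, "phenome", {
    purrr::pmap(sc, function(phecode_id, baseline_prevalence,
                             causal_log_or_per_sd_iron, direct_snp_log_ors,
                             sex_ratio) {
      eta <- qlogis(baseline_prevalence) +
        causal_log_or_per_sd_iron * biomarkers$serum_iron +
        config$age_log_or_per_decade * age_c
      b_sex <- if (is.finite(sex_ratio)) {
        qlogis(sex_ratio) - qlogis(config$female_fraction)
      } else {
        config$sex_log_or
      }
      eta <- eta + b_sex * sex_c
      if (!is.null(direct_snp_log_ors) && length(direct_snp_log_ors)) {
        d <- direct_snp_log_ors
        bad <- setdiff(names(d), config$snps$rsid)
        if (length(bad)) {
          abort(paste0("direct_snp_log_ors names not among configured SNPs: ",
                       paste(bad, collapse = ", ")))
        }
        # centre each direct term at its population mean dosage
        for (r in names(d)) {
          j <- match(r, config$snps$rsid)
          eta <- eta + d[[r]] * (G[, j] - 2 * config$snps$eaf[j])
        }
      }
      y <- rbinom(length(eta), 1L, plogis(eta))
      rows <- phecode_map[phecode_map$phecode == phecode_id, , drop = FALSE]
      rows <- rows[order(-rows$icd_version), , drop = FALSE] # prefer ICD-10
      tibble::tibble(person_id = genotypes$person_id[y == 1L],
                     icd_version = rows$icd_version[1],
                     code = rows$icd_code[1])
    })
  })
  dplyr::bind_rows(events)
}

#' Generate a table of related pairs
#'
#' Draws `n_related_pairs` disjoint pairs of participants with kinship
#' coefficients uniform on `kinship_range`. With a range above the 0.0884
#' second-degree-relative threshold every pair triggers downstream pruning;
#' below it, none do.
#'
#' @inheritParams generate_biomarkers
#' @return Tibble `id_a`, `id_b`, `coefficient`; pairs are disjoint.
#' @export
generate_kinship <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  k <- config$n_related_pairs
  if (k > config$n_individuals / 2) {
    abort("Cannot form that many disjoint pairs from the cohort.")
  }
  if (k == 0) {
    return(tibble::tibble(id_a = integer(), id_b = integer(),
                          coefficient = numeric()))
  }
  with_stage_seed(config$seed, "kinship", {
    ids <- sample(config$n_individuals, 2L * k)
    tibble::tibble(
      id_a = ids[seq_len(k)],
      id_b = ids[k + seq_len(k)],
      coefficient = runif(k, config$kinship_range[1], config$kinship_range[2])
    )
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs every generator stage and returns a `synthetic_cohort` object holding
#' the genotype, covariate, biomarker, ICD-event, and kinship tables plus the
#' phecode map and the scenario. Output is byte-identical for a fixed seed.
#'
#' @inheritParams generate_phenome
#' @param phecode_map Map used to emit ICD events; defaults to
#'   [synthetic_phecode_map()] over the scenario phecodes.
#' @return A `synthetic_cohort` list.
#' @export
#' @examples
#' cfg <- scenario_config(n_individuals = 300,
#'   phecode_scenarios = phecode_scenario("280.1", 0.1), seed = 1)
#' cohort <- simulate_cohort(cfg)
#' names(cohort)
simulate_cohort <- function(config, phecode_map = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(phecode_map)) {
    phecode_map <- if (nrow(config$phecode_scenarios)) {
      synthetic_phecode_map(config$phecode_scenarios$phecode_id)
    } else {
      synthetic_phecode_map(character(0))
    }
  }
  genotypes <- generate_genotypes(config)
  covariates <- generate_covariates(config)
  biomarkers <- generate_biomarkers(genotypes, config)
  icd_events <- generate_phenome(genotypes, biomarkers, covariates, config,
                                 phecode_map)
  kinship <- generate_kinship(config)
  structure(
    list(genotypes = genotypes, covariates = covariates,
         biomarkers = biomarkers, icd_events = icd_events,
         kinship = kinship, phecode_map = phecode_map, config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat("  individuals:", nrow(x$covariates),
      " SNPs:", ncol(x$genotypes) - 1L, "\n")
  cat("  ICD events:", nrow(x$icd_events),
      " related pairs:", nrow(x$kinship), "\n")
  invisible(x)
}

#' Build a synthetic phecode map for arbitrary phecodes
#'
#' Creates one ICD-10-style synthetic code (`SYN<digits>`) per phecode with
#' the exclusion root defaulting to the integer part of the phecode. Useful
#' for simulation studies with many null phecodes.
#'
#' @param phecode_ids Character vector of phecodes.
#' @param category Disease-category label(s), recycled.
#' @return A phecode-map tibble (see [read_phecode_map()]).
#' @export
#' @examples
#' synthetic_phecode_map(c("280.1", "401.1"))
synthetic_phecode_map <- function(phecode_ids, category = "Synthetic") {
  phecode_ids <- as.character(phecode_ids)
  tibble::tibble(
    icd_version = rep(10L, length(phecode_ids)),
    icd_code = paste0("SYN", gsub("\\.", "X", phecode_ids)),
    phecode = phecode_ids,
    exclusion_root = sub("\\..*$", "", phecode_ids),
    description = paste("Synthetic phenotype", phecode_ids),
    category = rep_len(category, length(phecode_ids)),
    sex = "both"
  )
}

#' Write a synthetic cohort to tab-delimited files
#'
#' Writes `genotypes.tsv`, `covariates.tsv`, `biomarkers.tsv`,
#' `icd_events.tsv`, `kinship.tsv`, `phecode_map.tsv`, and the scenario as
#' `scenario.yaml` into `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("genotypes", "covariates", "biomarkers", "icd_events",
               "kinship", "phecode_map")) {
    readr::write_tsv(cohort[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  write_scenario_config(cohort$config, file.path(dir, "scenario.yaml"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the tab-delimited cohort tables.
#' @return A `synthetic_cohort` object.
#' @export
read_cohort <- function(dir) {
  rd <- function(nm) readr::read_tsv(file.path(dir, paste0(nm, ".tsv")),
                                     show_col_types = FALSE, progress = FALSE)
  config <- read_scenario_config(file.path(dir, "scenario.yaml"))
  structure(
    list(genotypes = rd("genotypes"), covariates = rd("covariates"),
         biomarkers = rd("biomarkers"), icd_events = rd("icd_events"),
         kinship = rd("kinship"), phecode_map = rd("phecode_map"),
         config = config),
    class = "synthetic_cohort"
  )
}

#' Write a scenario configuration as YAML
#' @param config A [scenario_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  x <- unclass(config)
  x$snps <- as.list(as.data.frame(config$snps))
  sc <- config$phecode_scenarios
  x$phecode_scenarios <- purrr::pmap(sc, function(phecode_id,
                                                  baseline_prevalence,
                                                  causal_log_or_per_sd_iron,
                                                  direct_snp_log_ors,
                                                  sex_ratio) {
    list(phecode_id = phecode_id, baseline_prevalence = baseline_prevalence,
         causal_log_or_per_sd_iron = causal_log_or_per_sd_iron,
         direct_snp_log_ors = as.list(direct_snp_log_ors),
         sex_ratio = sex_ratio)
  })
  yaml::write_yaml(x, path, precision = 12)
  invisible(path)
}

#' Read a scenario configuration from YAML
#' @param path Path to a file written by [write_scenario_config()].
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  x <- yaml::read_yaml(path)
  scenarios <- if (length(x$phecode_scenarios)) {
    dplyr::bind_rows(lapply(x$phecode_scenarios, function(s) {
      phecode_scenario(
        s$phecode_id, s$baseline_prevalence, s$causal_log_or_per_sd_iron,
        direct_snp_log_ors = if (length(s$direct_snp_log_ors)) {
          list(unlist(s$direct_snp_log_ors))
        } else NULL,
        sex_ratio = if (is.null(s$sex_ratio)) NA_real_ else s$sex_ratio
      )
    }))
  } else {
    NULL
  }
  scenario_config(
    n_individuals = x$n_individuals,
    snps = tibble::as_tibble(x$snps),
    biomarker_noise_sd = x$biomarker_noise_sd,
    phecode_scenarios = scenarios,
    n_related_pairs = x$n_related_pairs,
    kinship_range = unlist(x$kinship_range),
    female_fraction = x$female_fraction,
    age_log_or_per_decade = x$age_log_or_per_decade,
    sex_log_or = x$sex_log_or,
    seed = x$seed
  )
}
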