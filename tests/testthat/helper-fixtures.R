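# Shared fixtures built in code: small scenario configs and toy tables.

one_snp_config <- function(eaf, beta = 0, n = 1e5, seed = 1,
                           noise_sd = NULL) {
  scenario_config(
    n_individuals = n,
    snps = tibble::tibble(rsid = "rsX", effect_allele = "A",
                          other_allele = "G", eaf = eaf,
                          beta_iron_sd_units = beta),
    biomarker_noise_sd = noise_sd,
    seed = seed
  )
}

toy_phecode_map <- function() {
  tibble::tibble(
    icd_version = c(10L, 10L, 10L),
    icd_code = c("D509", "D510", "I10"),
    phecode = c("280.1", "280.2", "401.1"),
    exclusion_root = c("280", "280", "401"),
    description = c("Iron deficiency anemia", "Other anemia",
                    "Hypertension"),
    category = c("Hematopoietic", "Hematopoietic", "Circulatory system"),
    sex = "both"
  )
}

# Directly simulate a case/control set plus covariates/dosages for
# regression tests, without the ICD machinery.
simulate_cc_data <- function(n = 5000, eaf = 0.3, beta_g = 0,
                             prevalence = 0.1, beta_age = 0, seed = 1) {
  withr::with_seed(seed, {
    g <- rbinom(n, 2, eaf)
    covariates <- tibble::tibble(
      person_id = seq_len(n),
      age = pmin(pmax(rnorm(n, 56.8, 8), 40), 69),
      sex = rbinom(n, 1, 0.54),
      array = rbinom(n, 1, 0.11),
      pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n), pc4 = rnorm(n)
    )
    eta <- qlogis(prevalence) + beta_g * (g - 2 * eaf) +
      beta_age * (covariates$age - mean(covariates$age))
    y <- rbinom(n, 1, plogis(eta))
  })
  cc <- structure(
    list(phecode_id = "test", case_ids = which(y == 1L),
         control_ids = which(y == 0L), excluded_ids = integer(0)),
    class = "case_control_set"
  )
  list(dosage = stats::setNames(g, seq_len(n)), case_control = cc,
       covariates = covariates, y = y)
}

# Instruments with exact ratio structure for rescaling algebra tests.
algebra_instruments <- function() {
  tibble::tibble(
    rsid = c("s1", "s2", "s3"),
    effect_allele = c("A", "A", "A"),
    other_allele = c("C", "C", "C"),
    eaf = c(0.3, 0.4, 0.5),
    beta_serum_iron = c(0.3, 0.25, 0.2),
    se_serum_iron = c(0.02, 0.02, 0.02),
    beta_log10_ferritin = c(0.15, 0.125, 0.1),   # half the iron betas
    se_log10_ferritin = c(0.01, 0.01, 0.01),     # half the iron SEs
    beta_transferrin = c(-0.3, -0.25, -0.2),     # sign-flipped iron betas
    se_transferrin = c(0.02, 0.02, 0.02),
    beta_transferrin_saturation = c(0.3, 0.25, 0.2),
    se_transferrin_saturation = c(0.02, 0.02, 0.02)
  )
}
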