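test_that("absolute effects rescale to SD units by division", {
  expect_equal(scale_to_sd(6.1), 1.0)
  expect_equal(scale_to_sd(0), 0)
  expect_equal(scale_to_sd(3.05), 0.5)
  out <- scale_to_sd(c(6.1, 3.05), se = c(0.61, 0.61))
  expect_equal(out$beta, c(1, 0.5))
  expect_equal(out$se, c(0.1, 0.1))
  expect_error(scale_to_sd(1, sd_serum_iron = 0), "positive")
  expect_error(scale_to_sd(1, sd_serum_iron = -6.1), "positive")
})

test_that("harmonization aligns outcome effects to the instrument effect allele", {
  ins <- algebra_instruments()
  aligned <- tibble::tibble(rsid = "s1", effect_allele = "A",
                            other_allele = "C", beta = 0.10, se = 0.05)
  h <- harmonize(ins, aligned)
  expect_equal(h$beta, 0.10)
  expect_equal(h$gamma, 0.3)

  flipped <- tibble::tibble(rsid = "s1", effect_allele = "C",
                            other_allele = "A", beta = 0.10, se = 0.05)
  hf <- harmonize(ins, flipped)
  expect_equal(hf$beta, -0.10)
  expect_equal(hf$effect_allele, "A")
  expect_equal(hf$other_allele, "C")

  expect_error(
    harmonize(ins, tibble::tibble(rsid = "rs000", effect_allele = "A",
                                  beta = 0.1, se = 0.05)),
    "No instrument entry")
  expect_error(
    harmonize(ins, tibble::tibble(rsid = "s1", effect_allele = "T",
                                  other_allele = "G", beta = 0.1, se = 0.05)),
    "Incompatible allele")
})

test_that("ratio estimates use second-order delta-method standard errors", {
  # null numerator: se reduces to se_Gamma / |gamma|
  r0 <- ratio_estimate(0.5, 0.05, 0, 0.05)
  expect_equal(r0$beta_mr, 0)
  expect_equal(r0$se_mr, 0.1)
  # worked example
  r <- ratio_estimate(0.5, 0.05, 0.1, 0.05)
  expect_equal(r$beta_mr, 0.2)
  expect_equal(r$se_mr, sqrt(0.01 + 0.0004), tolerance = 1e-12)
  expect_equal(r$se_mr, 0.10198, tolerance = 1e-4)
  # zero exposure uncertainty: first-order limit
  r1 <- ratio_estimate(0.5, 0, 0.1, 0.05)
  expect_equal(r1$se_mr, 0.1)
  expect_error(ratio_estimate(0, 0.05, 0.1, 0.05), "zero")
})

test_that("second-order SE matches a Monte-Carlo ratio-distribution oracle", {
  withr::with_seed(421, {
    gamma <- 0.5; se_g <- 0.04; Gam <- 0.15; se_G <- 0.06
    G <- rnorm(1e6, Gam, se_G)
    g <- rnorm(1e6, gamma, se_g)
    mc_sd <- sd(G / g)
  })
  r <- ratio_estimate(gamma, se_g, Gam, se_G)
  expect_lt(abs(r$se_mr - mc_sd) / mc_sd, 0.02)
})

test_that("IVW pooling matches closed forms and never loses precision", {
  r_eq <- ratio_estimate(rep(1, 3), 0, rep(0.2, 3), rep(0.1, 3))
  ivw_eq <- ivw_meta(r_eq)
  expect_equal(ivw_eq$beta, 0.2)
  expect_equal(ivw_eq$se, 0.1 / sqrt(3), tolerance = 1e-12)

  r <- ratio_estimate(rep(1, 3), 0, c(0.1, 0.2, 0.3), rep(0.1, 3))
  ivw <- ivw_meta(r)
  expect_equal(ivw$beta, 0.2, tolerance = 1e-12)
  expect_equal(ivw$se, 0.0577350269, tolerance = 1e-9)
  expect_lt(ivw$ci_low, ivw$beta)
  expect_gt(ivw$ci_high, ivw$beta)
  expect_equal(ivw$q_df, 2L)

  expect_error(ivw_meta(ratio_estimate(1, 0, 0.1, 0.1)), "at least 2")

  # pooled SE is never larger than the most precise instrument
  withr::with_seed(11, {
    for (i in 1:25) {
      rr <- ratio_estimate(runif(3, 0.2, 0.6), runif(3, 0, 0.05),
                           rnorm(3, 0, 0.3), runif(3, 0.02, 0.2))
      expect_lte(ivw_meta(rr)$se, min(rr$se_mr) + 1e-12)
    }
  })
})

test_that("Cochran Q matches its chi-square closed form", {
  q0 <- cochran_q(rep(0.2, 3), rep(0.1, 3))
  expect_equal(q0$q_stat, 0)
  expect_equal(q0$q_p, 1)

  q <- cochran_q(c(0.1, 0.2, 0.3), rep(0.1, 3))
  expect_equal(q$q_stat, 2.0, tolerance = 1e-12)
  expect_equal(q$q_df, 2L)
  expect_equal(q$q_p, exp(-1), tolerance = 1e-9)
})

test_that("Cochran Q has nominal type-I error under instrument homogeneity", {
  n_rep <- 1000
  withr::with_seed(99, {
    rejections <- vapply(seq_len(n_rep), function(i) {
      true_b <- 0.1
      se <- runif(3, 0.05, 0.15)
      b <- rnorm(3, true_b, se)
      cochran_q(b, se)$q_p < 0.05
    }, logical(1))
  })
  half <- 1.96 * sqrt(0.05 * 0.95 / n_rep)
  expect_gt(mean(rejections), 0.05 - half)
  expect_lt(mean(rejections), 0.05 + half)
})

test_that("weighted median interpolation matches hand arithmetic", {
  # symmetric equal weights: breakpoints (1/6, 1/2, 5/6) hit 0.5 exactly
  r_eq <- tibble::tibble(beta_mr = c(0.1, 0.2, 0.4), se_mr = rep(1, 3))
  wm <- weighted_median(r_eq, n_boot = 100, seed = 1)
  expect_equal(wm$beta, 0.2, tolerance = 1e-12)

  # normalized weights (0.5, 0.25, 0.25): interpolate in the first gap
  r_w <- tibble::tibble(beta_mr = c(0.1, 0.2, 0.4),
                        se_mr = c(1, sqrt(2), sqrt(2)))
  wm_w <- weighted_median(r_w, n_boot = 100, seed = 1)
  expect_equal(wm_w$beta, 0.1 + 0.1 * (0.25 / 0.375), tolerance = 1e-12)
  expect_equal(wm_w$beta, 0.16667, tolerance = 1e-4)

  # degenerate limit: nearly all weight on one instrument
  r_dom <- tibble::tibble(beta_mr = c(0.1, 0.2, 0.4),
                          se_mr = c(1e-4, 10, 10))
  expect_equal(weighted_median(r_dom, n_boot = 100, seed = 1)$beta, 0.1,
               tolerance = 1e-3)

  expect_error(
    weighted_median(tibble::tibble(beta_mr = c(0.1, 0.2),
                                   se_mr = c(1, 1))),
    "at least 3")
  expect_error(weighted_median(r_eq, n_boot = 50), "at least 100")
})

test_that("weighted median bootstrap is seeded and reproducible", {
  r <- ratio_estimate(c(0.3, 0.25, 0.2), 0.02, c(0.05, 0.04, 0.03), 0.02)
  a <- weighted_median(r, n_boot = 300, seed = 42)
  b <- weighted_median(r, n_boot = 300, seed = 42)
  expect_identical(a$beta, b$beta)
  expect_identical(a$se_boot, b$se_boot)
  expect_gt(a$se_boot, 0)
  c2 <- weighted_median(r, n_boot = 300, seed = 43)
  expect_false(identical(a$se_boot, c2$se_boot))
})

test_that("weighted median resists a minority pleiotropic instrument", {
  true_beta <- -0.3
  withr::with_seed(7, {
    hits <- vapply(1:30, function(i) {
      gamma <- c(0.3, 0.25, 0.2)
      se_g <- rep(0.01, 3)
      se_G <- c(0.03, 0.03, 0.12)  # pleiotropic SNP is least precise
      Gam <- rnorm(3, gamma * true_beta + c(0, 0, 0.4), se_G)
      r <- ratio_estimate(gamma, se_g, Gam, se_G)
      wm <- weighted_median(r, n_boot = 200, seed = i)
      abs(wm$beta - true_beta) < 3 * wm$se_boot
    }, logical(1))
  })
  expect_gte(mean(hits), 0.8)
})

test_that("rescaling to other biomarkers follows ratio algebra", {
  ins <- algebra_instruments()
  assoc <- tibble::tibble(
    rsid = ins$rsid, effect_allele = ins$effect_allele,
    other_allele = ins$other_allele,
    beta = c(-0.09, -0.075, -0.06),  # exactly -0.3 * gamma
    se = c(0.02, 0.02, 0.02))
  primary <- ivw_meta(with(harmonize(ins, assoc, "serum_iron"),
                           ratio_estimate(gamma, se_gamma, beta, se)))
  # serum iron: identity with the primary analysis
  serum <- rescale_to_biomarker(ins, assoc, "serum_iron")
  expect_equal(serum$beta, primary$beta)
  expect_equal(primary$beta, -0.3, tolerance = 1e-12)

  # ferritin betas (and SEs) are half the iron ones: log-OR doubles
  ferr <- rescale_to_biomarker(ins, assoc, "log10_ferritin")
  expect_equal(ferr$beta, 2 * primary$beta, tolerance = 1e-12)

  # transferrin effects have the opposite sign: protective becomes harmful
  trans <- rescale_to_biomarker(ins, assoc, "transferrin")
  expect_equal(trans$beta, -primary$beta, tolerance = 1e-12)
  expect_gt(trans$beta, 0)

  expect_error(rescale_to_biomarker(ins, assoc, "hepcidin"),
               "Unknown biomarker")
})

test_that("allele-flip invariance holds through the ratio-IVW chain", {
  gamma <- c(0.3, 0.25, 0.2); se_g <- rep(0.02, 3)
  Gam <- c(-0.1, -0.07, -0.05); se_G <- rep(0.03, 3)
  base <- ivw_meta(ratio_estimate(gamma, se_g, Gam, se_G))
  # jointly negating exposure and outcome effects changes nothing
  joint <- ivw_meta(ratio_estimate(-gamma, se_g, -Gam, se_G))
  expect_equal(joint$beta, base$beta, tolerance = 1e-12)
  expect_equal(joint$se, base$se, tolerance = 1e-12)
  # negating only the outcome flips the causal direction
  flip <- ivw_meta(ratio_estimate(gamma, se_g, -Gam, se_G))
  expect_equal(flip$beta, -base$beta, tolerance = 1e-12)
})

test_that("the packaged instrument file matches the in-code defaults", {
  ins_file <- read_instruments(system.file(
    "extdata", "instruments_synthetic.tsv", package = "ironmr"))
  ins_code <- default_instruments()
  expect_equal(as.data.frame(ins_file), as.data.frame(ins_code),
               tolerance = 1e-9)
  # calibrated to ~3.8% of serum-iron variance under HWE
  expect_equal(instrument_r2(ins_code), 0.038, tolerance = 0.02)
})

test_that("tidy and glance methods expose MR fits as tibbles", {
  r <- ratio_estimate(c(0.3, 0.25, 0.2), 0.02, c(-0.1, -0.08, -0.07), 0.03)
  ivw <- ivw_meta(r)
  td <- tidy(ivw, exponentiate = TRUE)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$estimate, exp(ivw$beta))
  expect_equal(glance(ivw)$q_df, 2L)
  wm <- weighted_median(r, n_boot = 100, seed = 1)
  expect_equal(tidy(wm)$estimate, wm$beta)
})
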