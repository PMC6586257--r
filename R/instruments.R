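#' Synthetic genetic instruments for systemic iron status
#'
#' Returns the per-SNP summary associations used as the default exposure side
#' of the two-sample MR analysis: three variants (rs1800562 and rs1799945 in
#' *HFE*, rs855791 in *TMPRSS6*) with effects on serum iron, log10 ferritin,
#' transferrin, and transferrin saturation, all in SD units per effect allele.
#'
#' The numbers are **synthetic**: they reproduce the structure real iron
#' instruments have — the concordant sign pattern (positive on serum iron,
#' ferritin, and transferrin saturation; negative on transferrin) and a joint
#' serum-iron variance explained of about 3.8% — without copying any
#' published table. Substitute real consortium estimates via
#' [read_instruments()] for analyses of real data.
#'
#' @return A tibble with one row per SNP and columns `rsid`, `effect_allele`,
#'   `other_allele`, `eaf`, and `beta_*`/`se_*` pairs for each of the four
#'   biomarkers (`serum_iron`, `log10_ferritin`, `transferrin`,
#'   `transferrin_saturation`).
#' @export
#' @examples
#' default_instruments()
default_instruments <- function() {
  ins <- tibble::tibble(
    rsid = c("rs1800562", "rs1799945", "rs855791"),
    effect_allele = c("A", "G", "G"),
    other_allele = c("G", "C", "A"),
    eaf = c(0.07, 0.15, 0.45),
    beta_serum_iron = c(0.32, 0.19, 0.18),
    se_serum_iron = c(0.016, 0.011, 0.008)
  )
  # The three secondary biomarkers scale off the serum-iron effect with the
  # loadings used by the cohort simulator (transferrin negative).
  for (bm in names(BIOMARKER_LOADINGS)) {
    ins[[paste0("beta_", bm)]] <- round(ins$beta_serum_iron *
                                          BIOMARKER_LOADINGS[[bm]], 4)
    ins[[paste0("se_", bm)]] <- ins$se_serum_iron
  }
  validate_instruments(ins)
}

# Fixed loadings of the secondary biomarkers on serum iron (SD units).
BIOMARKER_LOADINGS <- c(
  log10_ferritin = 0.55,
  transferrin = -0.65,
  transferrin_saturation = 0.85
)

BIOMARKERS <- c("serum_iron", names(BIOMARKER_LOADINGS))

#' Read an instrument summary-statistics table
#'
#' Loads a tab-delimited instrument file with one row per SNP and columns
#' `rsid`, `effect_allele`, `other_allele`, `eaf`, then `beta_<biomarker>` and
#' `se_<biomarker>` for each of `serum_iron`, `log10_ferritin`, `transferrin`,
#' and `transferrin_saturation`, and validates the iron-status sign pattern.
#'
#' @param path Path to the tab-delimited file.
#' @return A validated tibble of instruments.
#' @seealso [default_instruments()] for the packaged synthetic table.
#' @export
read_instruments <- function(path) {
  ins <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_instruments(ins)
}

#' Validate an instrument table
#'
#' Checks the columns, allele codes, frequencies, standard errors, and the
#' concordant iron-status sign pattern: within every SNP the serum iron,
#' ferritin, and transferrin saturation effects must share one sign and the
#' transferrin effect must have the opposite sign.
#'
#' @param instruments A tibble as described in [read_instruments()].
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_instruments <- function(instruments) {
  need <- c("rsid", "effect_allele", "other_allele", "eaf",
            paste0("beta_", BIOMARKERS), paste0("se_", BIOMARKERS))
  missing <- setdiff(need, names(instruments))
  if (length(missing)) {
    abort(paste0("Instrument table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  check_prob(instruments$eaf, "eaf")
  ses <- as.matrix(instruments[paste0("se_", BIOMARKERS)])
  if (any(!is.finite(ses)) || any(ses <= 0)) {
    abort("All instrument standard errors must be finite and positive.")
  }
  concordant <- sign(instruments$beta_serum_iron)
  ok <- sign(instruments$beta_log10_ferritin) == concordant &
    sign(instruments$beta_transferrin_saturation) == concordant &
    sign(instruments$beta_transferrin) == -concordant
  if (any(!ok)) {
    abort(paste0("Instrument(s) violate the iron-status sign pattern ",
                 "(iron/ferritin/saturation concordant, transferrin ",
                 "opposite): ", paste(instruments$rsid[!ok], collapse = ", ")))
  }
  tibble::as_tibble(instruments)
}

#' Proportion of exposure variance explained by the instruments
#'
#' Under Hardy-Weinberg equilibrium each SNP contributes
#' `2 p (1 - p) beta^2` to the variance of a biomarker measured in SD units.
#'
#' @param instruments An instrument tibble.
#' @param biomarker Which biomarker's effects to use.
#' @return A single numeric proportion.
#' @export
#' @examples
#' instrument_r2(default_instruments()) # about 0.038
instrument_r2 <- function(instruments, biomarker = "serum_iron") {
  beta <- instruments[[paste0("beta_", biomarker)]]
  sum(2 * instruments$eaf * (1 - instruments$eaf) * beta^2)
}
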