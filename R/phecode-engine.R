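#' Read a phecode map
#'
#' The map dialect is a tab-delimited table with columns `icd_version`
#' (9 or 10), `icd_code`, `phecode` (dotted decimal string), `exclusion_root`
#' (phecode prefix whose carriers are removed from the control pool),
#' `description`, `category`, and an optional `sex` column
#' (`both`/`male`/`female`). The packaged example map
#' (`system.file("extdata", "phecode_map_synthetic.tsv", package = "ironmr")`)
#' is a small synthetic stand-in; supply a full published phecode map in the
#' same shape for real analyses.
#'
#' @param path Path to a tab-delimited map file.
#' @return A validated tibble.
#' @export
read_phecode_map <- function(path) {
  map <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           icd_version = readr::col_integer(),
                           icd_code = readr::col_character(),
                           phecode = readr::col_character(),
                           .default = readr::col_character()
                         ))
  validate_phecode_map(map)
}

validate_phecode_map <- function(map) {
  need <- c("icd_version", "icd_code", "phecode", "exclusion_root",
            "description", "category")
  missing <- setdiff(need, names(map))
  if (length(missing)) {
    abort(paste0("Phecode map is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (!all(map$icd_version %in% c(9L, 10L))) {
    abort("`icd_version` must be 9 or 10 for every map row.")
  }
  if (any(is.na(suppressWarnings(as.numeric(map$phecode))))) {
    abort("Every `phecode` must parse as a decimal number.")
  }
  if (!"sex" %in% names(map)) map$sex <- "both"
  tibble::as_tibble(map)
}

# Normalize an ICD code: uppercase, dots and spaces stripped.
normalize_icd <- function(code) {
  toupper(gsub("[. ]", "", as.character(code)))
}

#' Prune one member of each related pair
#'
#' For every pair of participants with kinship coefficient above the
#' threshold (default 0.0884, approximately second-degree relatives), one
#' member is excluded at random. Pairs are resolved greedily in input order:
#' if both members are still retained when a pair is visited, one is dropped
#' by a seeded coin flip, so chains such as A-B, B-C leave no retained pair
#' above the threshold.
#'
#' @param individual_ids Vector of cohort ids.
#' @param kinship Tibble `id_a`, `id_b`, `coefficient`.
#' @param threshold Kinship coefficient above which a pair is pruned.
#' @param seed Seed for the member choice.
#' @return The retained ids (same type and order as `individual_ids`).
#' @export
#' @examples
#' prune_related(1:4, tibble::tibble(id_a = 1, id_b = 2, coefficient = 0.25))
prune_related <- function(individual_ids, kinship, threshold = 0.0884,
                          seed = 1) {
  if (!nrow(kinship)) return(individual_ids)
  if (any(!is.finite(kinship$coefficient)) || any(kinship$coefficient < 0)) {
    abort("Kinship coefficients must be finite and nonnegative.")
  }
  unknown <- setdiff(c(kinship$id_a, kinship$id_b), individual_ids)
  if (length(unknown)) {
    abort(paste0("Kinship pair references unknown id(s): ",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  }
  close_pairs <- kinship[kinship$coefficient > threshold, , drop = FALSE]
  dropped <- new.env(parent = emptyenv())
  with_stage_seed(seed, "prune-related", {
    for (i in seq_len(nrow(close_pairs))) {
      a <- as.character(close_pairs$id_a[i])
      b <- as.character(close_pairs$id_b[i])
      if (is.null(dropped[[a]]) && is.null(dropped[[b]])) {
        victim <- if (runif(1) < 0.5) a else b
        dropped[[victim]] <- TRUE
      }
    }
  })
  individual_ids[!(as.character(individual_ids) %in% ls(dropped))]
}

#' Map ICD events to a person-by-phecode incidence table
#'
#' A person is flagged for a phecode if they have at least one hospital event
#' whose (version, normalized code) appears in the map for that phecode.
#' Repeat events flag once. Events whose code does not normalize to a plain
#' alphanumeric string are skipped with a warning; events with well-formed
#' but unmapped codes are counted in the `unmapped` attribute and a message,
#' never silently dropped.
#'
#' @param icd_events Tibble `person_id`, `icd_version`, `code`.
#' @param phecode_map A map tibble (see [read_phecode_map()]).
#' @return Distinct tibble `person_id`, `phecode`, with attribute `unmapped`
#'   (a count tibble of unmapped codes).
#' @export
map_icd_to_phecodes <- function(icd_events, phecode_map) {
  phecode_map <- validate_phecode_map(phecode_map)
  ev <- tibble::as_tibble(icd_events)
  ev$code_norm <- normalize_icd(ev$code)
  malformed <- is.na(ev$code_norm) | ev$code_norm == "" |
    grepl("[^A-Z0-9]", ev$code_norm)
  if (any(malformed)) {
    warn(sprintf("Skipping %d event(s) with malformed ICD codes.",
                 sum(malformed)))
    ev <- ev[!malformed, , drop = FALSE]
  }
  map <- phecode_map
  map$code_norm <- normalize_icd(map$icd_code)
  hits <- dplyr::inner_join(
    ev, dplyr::distinct(map[c("icd_version", "code_norm", "phecode")]),
    by = c("icd_version", "code_norm")
  )
  unmapped <- dplyr::count(
    dplyr::anti_join(ev, map, by = c("icd_version", "code_norm")),
    .data$icd_version, .data$code_norm, name = "n_events"
  )
  if (nrow(unmapped)) {
    rlang::inform(sprintf(
      "%d distinct ICD code(s) (%d events) had no phecode mapping.",
      nrow(unmapped), sum(unmapped$n_events)))
  }
  out <- dplyr::distinct(hits[c("person_id", "phecode")])
  attr(out, "unmapped") <- unmapped
  out
}

#' Build a case/control set for one phecode
#'
#' Cases are individuals flagged for the phecode. Individuals not flagged
#' for it but flagged for any *related* phecode — one sharing the target's
#' exclusion root — are removed from the control pool; everyone else in the
#' retained cohort is a control. The three sets partition the cohort.
#'
#' @param phecode_id Target phecode.
#' @param incidence Output of [map_icd_to_phecodes()].
#' @param phecode_map Map tibble supplying the exclusion roots.
#' @param cohort_ids Ids of the retained cohort (after relatedness pruning).
#' @return A `case_control_set`: list with `phecode_id`, `case_ids`,
#'   `control_ids`, `excluded_ids`.
#' @export
build_case_control <- function(phecode_id, incidence, phecode_map,
                               cohort_ids) {
  if (!length(cohort_ids)) abort("Empty cohort: no retained individuals.")
  phecode_map <- validate_phecode_map(phecode_map)
  rows <- phecode_map[phecode_map$phecode == phecode_id, , drop = FALSE]
  if (!nrow(rows)) {
    abort(paste0("Phecode ", phecode_id, " is not present in the map."))
  }
  root <- rows$exclusion_root[1]
  related <- unique(phecode_map$phecode[phecode_map$exclusion_root == root])
  inc <- incidence[incidence$person_id %in% cohort_ids, , drop = FALSE]
  cases <- unique(inc$person_id[inc$phecode == phecode_id])
  rel_flagged <- unique(inc$person_id[inc$phecode %in% setdiff(related,
                                                               phecode_id)])
  excluded <- setdiff(rel_flagged, cases)
  controls <- setdiff(cohort_ids, c(cases, excluded))
  structure(
    list(phecode_id = phecode_id, case_ids = cases, control_ids = controls,
         excluded_ids = excluded),
    class = "case_control_set"
  )
}

#' @export
print.case_control_set <- function(x, ...) {
  cat(sprintf("<case_control_set %s> cases: %d, controls: %d, excluded: %d\n",
              x$phecode_id, length(x$case_ids), length(x$control_ids),
              length(x$excluded_ids)))
  invisible(x)
}

#' Build case/control sets for every mapped phecode
#'
#' @inheritParams build_case_control
#' @param phecodes Which phecodes to build; defaults to all in the map.
#' @return Named list of `case_control_set` objects.
#' @export
build_case_control_sets <- function(incidence, phecode_map, cohort_ids,
                                    phecodes = NULL) {
  phecode_map <- validate_phecode_map(phecode_map)
  if (is.null(phecodes)) phecodes <- unique(phecode_map$phecode)
  sets <- lapply(phecodes, build_case_control, incidence = incidence,
                 phecode_map = phecode_map, cohort_ids = cohort_ids)
  stats::setNames(sets, phecodes)
}

#' Keep only phecodes with enough cases
#'
#' Phenome scans restrict analysis to outcomes with at least `minimum` cases
#' (default 200) so the downstream MR estimates have usable precision.
#'
#' @param sets Named list of `case_control_set` objects.
#' @param minimum Minimum case count to retain a phecode.
#' @return The retained subset of `sets`.
#' @export
filter_min_cases <- function(sets, minimum = 200) {
  Filter(function(s) length(s$case_ids) >= minimum, sets)
}

#' Tabulate case/control counts per phecode
#'
#' @param sets Named list of `case_control_set` objects.
#' @param phecode_map Optional map to join descriptions and categories.
#' @return Tibble `phecode_id`, `n_cases`, `n_controls`, `n_excluded`
#'   (plus `description`, `category` when a map is given).
#' @export
case_control_counts <- function(sets, phecode_map = NULL) {
  out <- dplyr::bind_rows(lapply(sets, function(s) {
    tibble::tibble(phecode_id = s$phecode_id,
                   n_cases = length(s$case_ids),
                   n_controls = length(s$control_ids),
                   n_excluded = length(s$excluded_ids))
  }))
  if (!is.null(phecode_map) && nrow(out)) {
    info <- dplyr::distinct(
      validate_phecode_map(phecode_map)[c("phecode", "description",
                                          "category")])
    info <- info[!duplicated(info$phecode), ]
    out <- dplyr::left_join(out, info,
                            by = c(phecode_id = "phecode"))
  }
  out
}
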