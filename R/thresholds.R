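#' Filtering thresholds for the recurrence screen
#'
#' @param min_case_occurrences minimum number of case carriers for a variant
#'   to count as recurrent ("occurred more than once" in cases). Default 2.
#' @param max_control_frequency carrier-frequency ceiling in controls
#'   (strict `<`). Default 0.01.
#' @param max_population_maf allele-frequency ceiling in each reference
#'   population database (esp6500, 1000 Genomes, gnomAD; strict `<`; absent
#'   values pass). Default 0.01.
#' @param alpha_meta significance level for the cross-stratum meta screen.
#'   Default 0.05.
#' @return A list of class `"filter_thresholds"`.
#' @export
filter_thresholds <- function(min_case_occurrences = 2L,
                              max_control_frequency = 0.01,
                              max_population_maf = 0.01,
                              alpha_meta = 0.05) {
  min_case_occurrences <- as.integer(min_case_occurrences)
  stopifnot(min_case_occurrences >= 1L,
            max_control_frequency > 0, max_control_frequency <= 1,
            max_population_maf > 0, max_population_maf <= 1,
            alpha_meta > 0, alpha_meta <= 1)
  structure(list(min_case_occurrences = min_case_occurrences,
                 max_control_frequency = max_control_frequency,
                 max_population_maf = max_population_maf,
                 alpha_meta = alpha_meta),
            class = "filter_thresholds")
}

#' Cohort definition: ancestry strata and their case/control sizes
#'
#' @param labels character vector of stratum labels (unique).
#' @param n_cases,n_controls integer vectors of per-stratum case and control
#'   counts (each >= 1).
#' @return A data.frame of class `"cohort_spec"` with columns `label`,
#'   `n_cases`, `n_controls`.
#' @examples
#' cohort_spec(c("AA", "EA"), c(116, 89), c(408, 262))
#' @export
cohort_spec <- function(labels, n_cases, n_controls) {
  labels <- as.character(labels)
  n_cases <- as.integer(n_cases)
  n_controls <- as.integer(n_controls)
  if (anyDuplicated(labels)) stop("stratum labels must be unique", call. = FALSE)
  if (length(n_cases) != length(labels) || length(n_controls) != length(labels))
    stop("labels, n_cases and n_controls must have equal length", call. = FALSE)
  if (any(n_cases < 1L) || any(n_controls < 1L))
    stop("each stratum needs at least one case and one control", call. = FALSE)
  structure(data.frame(label = labels, n_cases = n_cases,
                       n_controls = n_controls, stringsAsFactors = FALSE),
            class = c("cohort_spec", "data.frame"))
}

#' The default study cohort: two ancestry strata
#'
#' African American stratum of 116 cases / 408 controls and European American
#' stratum of 89 cases / 262 controls.
#' @return a [cohort_spec()].
#' @export
default_cohort <- function() {
  cohort_spec(c("AA", "EA"), c(116L, 89L), c(408L, 262L))
}

#' Read screen configuration from a YAML file
#'
#' Recognized top-level keys: `thresholds` (any of the [filter_thresholds()]
#' arguments) and `cohort` (a map of stratum label to `{cases, controls}`).
#' Missing keys fall back to package defaults.
#'
#' @param path YAML file.
#' @return list with elements `thresholds` and `cohort`.
#' @export
read_screen_config <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("cannot parse config file '", path, "': ", conditionMessage(e),
         call. = FALSE))
  th <- do.call(filter_thresholds, as.list(cfg$thresholds %||% list()))
  co <- if (is.null(cfg$cohort)) default_cohort() else
    cohort_spec(names(cfg$cohort),
                vapply(cfg$cohort, function(s) s$cases, numeric(1)),
                vapply(cfg$cohort, function(s) s$controls, numeric(1)))
  list(thresholds = th, cohort = co)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
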