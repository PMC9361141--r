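#' Packaged demonstration fixtures
#'
#' Small named datasets used in examples, tests, and the command line:
#' the seed prompt catalog, a six-participant demo cohort, and the
#' published baseline contingency tables of the trial the package models
#' (counts as printed; the `table1-*` names cover alcohol use, smoking,
#' and alcohol-as-sleep-aid in the ISI-8 insomniac subgroup, plus the
#' total-population alcohol-as-sleep-aid table).
#'
#' @param name Fixture name; call `fixture_names()` for the registry.
#' @return The fixture object (a catalog tibble, roster tibble, or counts
#'   matrix).
#' @examples
#' pearson_chi_square(trial_fixture("table1-isi8-alcohol"))$statistic
#' @export
trial_fixture <- function(name) {
  registry <- list(
    "seed-catalog" = default_catalog,
    "demo-cohort" = function() {
      generate_cohort(cohort_config(n_per_arm = 3L), seed = 20210104L)
    },
    "table1-isi8-alcohol" = function() {
      matrix(c(6, 23, 8, 15, 13, 6), nrow = 2, byrow = TRUE,
             dimnames = list(c("SPA", "control"),
                             c("never", "sometimes", "everyday")))
    },
    "table1-isi8-smoking" = function() {
      matrix(c(4, 33, 0, 34), nrow = 2, byrow = TRUE,
             dimnames = list(c("SPA", "control"),
                             c("smoker", "non_smoker")))
    },
    "table1-isi8-sleep-aid" = function() {
      matrix(c(0, 37, 5, 29), nrow = 2, byrow = TRUE,
             dimnames = list(c("SPA", "control"),
                             c("uses_alcohol_aid", "does_not")))
    },
    "table1-total-sleep-aid" = function() {
      matrix(c(1, 59, 6, 50), nrow = 2, byrow = TRUE,
             dimnames = list(c("SPA", "control"),
                             c("uses_alcohol_aid", "does_not")))
    }
  )
  if (!name %in% names(registry)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(registry), collapse = ", "), call. = FALSE)
  }
  registry[[name]]()
}

#' @rdname trial_fixture
#' @export
fixture_names <- function() {
  c("seed-catalog", "demo-cohort", "table1-isi8-alcohol",
    "table1-isi8-smoking", "table1-isi8-sleep-aid",
    "table1-total-sleep-aid")
}
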