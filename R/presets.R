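#' The nine standard signature tests
#'
#' Named configurations of the discriminant analyses run on a vampire-bat
#' contact-call dataset: species assignment controlling for individual
#' (test 1) or colony (test 2); sex assignment in captive *Diaemus*
#' controlling for individual (test 3); population assignment (captive
#' vs wild) in female *Desmodus* controlling for individual (test 4);
#' conventional individual assignment within captive *Desmodus* (test 5),
#' wild *Desmodus* (test 6), and captive *Diaemus* using single first
#' notes (test 8) or double-note rows (test 9); and individual assignment
#' controlling for recording session in *Desmodus* (test 7). Permuted
#' DFAs are used wherever a nested control factor must be held together;
#' tests 5, 6, 8 and 9 are conventional leave-one-out DFAs.
#'
#' @return data.frame with one row per test: `test`, `label`, `method`
#'   (`"pdfa"` or `"dfa"`), `test_factor`, `control_factor`, `species`
#'   (comma-separated subset or `"all"`), `population` subset, and
#'   `notes` (`"first"` or `"double"`).
#' @export
paper_presets <- function() {
  data.frame(
    test = 1:9,
    label = c("species controlling individual",
              "species controlling colony",
              "sex controlling individual (Diaemus)",
              "population controlling individual (Desmodus)",
              "individual, captive Desmodus",
              "individual, wild Desmodus",
              "individual controlling session (Desmodus)",
              "individual, captive Diaemus, single notes",
              "individual, captive Diaemus, double notes"),
    method = c("pdfa", "pdfa", "pdfa", "pdfa",
               "dfa", "dfa", "pdfa", "dfa", "dfa"),
    test_factor = c("species", "species", "sex", "population",
                    "individual", "individual", "individual",
                    "individual", "individual"),
    control_factor = c("individual", "colony", "individual", "individual",
                       NA, NA, "session", NA, NA),
    species = c("all", "all", "Diaemus", "Desmodus", "Desmodus",
                "Desmodus", "Desmodus", "Diaemus", "Diaemus"),
    population = c("all", "all", "captive", "all", "captive", "wild",
                   "all", "captive", "captive"),
    notes = c("first", "first", "first", "first", "first", "first",
              "first", "first", "double"),
    row.names = NULL)
}

# subset a feature table according to a preset row
apply_preset_subset <- function(features, preset) {
  keep <- rep(TRUE, nrow(features))
  if (preset$species != "all")
    keep <- keep & features$species %in% strsplit(preset$species, ",")[[1]]
  if (preset$population != "all")
    keep <- keep & features$population %in%
      strsplit(preset$population, ",")[[1]]
  features[keep, , drop = FALSE]
}

#' Run one preset signature test
#'
#' Applies the preset's subset, picks the measurement columns, and runs
#' either a conventional leave-one-out DFA on the test factor or a
#' permuted DFA with the preset's control factor. For test 7 (session
#' control) the pDFA tests individual assignment while holding each
#' individual-session block together.
#'
#' @param preset one row of [paper_presets()].
#' @param features first-note feature table (with label columns).
#' @param double_features paired double-note table (needed for
#'   double-note presets), as from [select_double_notes()].
#' @param variables measurement columns to use; default all complete
#'   numeric measurements.
#' @param n_dfa_reps,n_permutations,seed pDFA settings.
#' @return a `dfa_result` or `pdfa_result`, with the preset attached as
#'   attribute `preset`.
#' @export
run_preset_test <- function(preset, features, double_features = NULL,
                            variables = NULL, n_dfa_reps = 10,
                            n_permutations = 100, seed = 1L) {
  dat <- if (preset$notes == "double") {
    if (is.null(double_features)) stop("preset needs double-note rows")
    apply_preset_subset(double_features, preset)
  } else apply_preset_subset(features, preset)
  if (nrow(dat) == 0) stop("preset subset is empty: ", preset$label)
  if (is.null(variables)) {
    fn <- if (preset$notes == "double")
      c(paste0(feature_names(), "_n1"), paste0(feature_names(), "_n2"),
        "inter_note_interval_ms")
    else feature_names()
    variables <- fn[vapply(fn, function(v)
      v %in% names(dat) && !anyNA(dat[[v]]), logical(1))]
  }
  x <- as.matrix(dat[, variables, drop = FALSE])
  res <- if (preset$method == "dfa") {
    lda_fit(x, dat[[preset$test_factor]])
  } else {
    ctrl <- if (preset$test_factor == "individual" &&
                preset$control_factor == "session")
      interaction(dat$individual, dat$session, drop = TRUE)
    else dat[[preset$control_factor]]
    pdfa(x, dat[[preset$test_factor]], ctrl,
         n_dfa_reps = n_dfa_reps, n_permutations = n_permutations,
         seed = seed)
  }
  attr(res, "preset") <- preset
  res
}
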