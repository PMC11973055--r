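#' Run the full analysis pipeline on a cohort
#'
#' Convenience composition of all stages: preprocess every recording to the
#' common rate, compute the 43-metric feature cube on 1-s windows, compress
#' it to one flat vector per subject, assemble min-max normalized pairwise
#' matrices for the requested group contrasts, and (optionally) run the
#' classifier roster under stratified cross-validation.
#'
#' @param recordings List of [eeg_recording()]s (e.g. [generate_cohort()]
#'   output or recordings read from CSV).
#' @param pairs List of `c(group_a, group_b)` contrasts; by default all
#'   ordered pairs of observed groups in first-appearance order, more
#'   affected group second (e.g. control vs mci, control vs ad, mci vs ad
#'   for the canonical three-group cohort).
#' @param preprocess A [preprocess_config()].
#' @param windowing A [windowing_config()].
#' @param params A [feature_params()].
#' @param cv A [cv_config()], or `NULL` to skip classification.
#' @param roster Classifier names (default the full [classifier_roster()]).
#' @param classify Run the classification stage (default `TRUE`).
#' @param verbose Log stage shapes to the console.
#' @return List with `vectors` (per-subject compressed vectors), `datasets`
#'   (normalized pairwise datasets) and `report` (a [run_all()] result, or
#'   `NULL` if classification was skipped).
#' @export
run_pipeline <- function(recordings, pairs = NULL,
                         preprocess = preprocess_config(),
                         windowing = windowing_config(),
                         params = feature_params(),
                         cv = cv_config(), roster = classifier_roster(),
                         classify = TRUE, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  vectors <- lapply(recordings, function(rec) {
    pp <- preprocess_recording(rec, preprocess)
    cube <- compute_feature_cube(pp, windowing, params)
    v <- compress_cube(cube)
    say("subject %s: %d ch x %d win -> vector of %d", rec$subject_id,
        dim(cube$values)[1], dim(cube$values)[2], length(v$values))
    v
  })
  groups <- unique(vapply(vectors, `[[`, "", "group"))
  if (is.null(pairs)) {
    pairs <- list()
    if (length(groups) >= 2) {
      cmb <- utils::combn(groups, 2, simplify = FALSE)
      pairs <- cmb
    }
  }
  datasets <- lapply(pairs, function(p) {
    ds <- minmax_normalize(build_pairwise(vectors, p[1], p[2]))
    say("pair %s vs %s: %d x %d", p[1], p[2], nrow(ds$X), ncol(ds$X))
    ds
  })
  report <- NULL
  if (classify && length(datasets)) {
    report <- run_all(datasets, roster = roster, cfg = cv)
  }
  list(vectors = vectors, datasets = datasets, report = report)
}
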