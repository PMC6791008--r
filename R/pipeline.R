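#' Run the full marker pipeline on a (simulated or real) study
#'
#' Executes every analysis stage end to end: qPCR quantification of T/S and
#' TREC/KREC per subject, spectratype classification and perturbation scoring
#' against the healthy-control reference, and the group-level statistics
#' (Kruskal-Wallis + Dunn for the four markers, category-proportion test,
#' correlations with CD4 in the perinatal group).
#'
#' @param cohort Metadata data frame (as written by [simulate_study()]).
#' @param peaks Peak table: named list per sample (from [parse_peak_table()])
#'   or a raw peak data frame.
#' @param plate_telomere,plate_excision qPCR plate data frames.
#' @param config A [cohort_config()] supplying blood normalization factors
#'   (defaults used for real plates when absent).
#' @param ref_group,n_ref,ref_seed Reference-repertoire settings.
#' @param alpha Significance level for the statistical layer.
#' @return List with `markers` (per-subject data frame: T/S, TREC, KREC,
#'   global perturbation, n over-perturbed), `repertoire` (full
#'   [analyze_repertoire()] output), `comparisons` (named list of
#'   `group_comparison` objects), `category_test`, `correlations`.
#' @export
run_study_pipeline <- function(cohort, peaks, plate_telomere, plate_excision,
                               config = cohort_config(), ref_group = "HC",
                               n_ref = 12, ref_seed = 1, alpha = 0.05) {
  if (is.data.frame(peaks)) peaks <- split(peaks, peaks$sample_id)
  groups <- stats::setNames(cohort$group, cohort$subject_id)

  ts <- vapply(cohort$subject_id, function(sid) {
    compute_ts_ratio(plate_telomere, sid)$ts_ratio
  }, numeric(1))
  exc <- lapply(cohort$subject_id, function(sid) {
    quantify_excision_circles(plate_excision, sid,
                              cells_per_ml = config$cells_per_ml,
                              cells_per_reaction = config$cells_per_reaction)
  })
  trec <- vapply(exc, function(e) e$trec_copies_per_ml, numeric(1))
  krec <- vapply(exc, function(e) e$krec_copies_per_ml, numeric(1))

  rep_res <- analyze_repertoire(peaks, groups, ref_group = ref_group,
                                n_ref = n_ref, seed = ref_seed)
  pert <- stats::setNames(rep_res$per_subject$global_perturbation,
                          rep_res$per_subject$sample_id)
  nover <- stats::setNames(rep_res$per_subject$n_overperturbed,
                           rep_res$per_subject$sample_id)

  markers <- data.frame(
    subject_id = cohort$subject_id,
    group = cohort$group,
    ts_ratio = unname(ts),
    trec_copies_per_ml = unname(trec),
    krec_copies_per_ml = unname(krec),
    global_perturbation = unname(pert[cohort$subject_id]),
    n_overperturbed = unname(nover[cohort$subject_id]),
    stringsAsFactors = FALSE
  )

  comparisons <- lapply(
    stats::setNames(c("trec_copies_per_ml", "krec_copies_per_ml", "ts_ratio",
                      "global_perturbation"),
                    c("trec", "krec", "ts", "perturbation")),
    function(v) compare_groups(markers[[v]], markers$group, alpha = alpha,
                               variable = v))
  category_test <- category_proportion_test(rep_res$classes, groups,
                                            alpha = alpha)

  ph <- merge(markers, cohort[, c("subject_id", "cd4_abs", "cd4_cd8_ratio")],
              by = "subject_id")
  ph <- ph[ph$group == "pHIVy", ]
  correlations <- NULL
  if (nrow(ph) >= 3) {
    correlations <- rbind(
      cbind(pair = "trec~cd4_abs",
            correlate(ph$trec_copies_per_ml, ph$cd4_abs)),
      cbind(pair = "ts~cd4_abs", correlate(ph$ts_ratio, ph$cd4_abs)),
      cbind(pair = "perturbation~cd4_cd8_ratio",
            correlate(ph$global_perturbation, ph$cd4_cd8_ratio))
    )
    rownames(correlations) <- NULL
  }

  list(markers = markers, repertoire = rep_res, comparisons = comparisons,
       category_test = category_test, correlations = correlations)
}

#' Simulate one study and test the qualitative marker pattern
#'
#' Generates a default-configuration cohort under the given seed, runs the
#' full pipeline and reports whether the study's qualitative result is
#' reproduced: TREC and KREC group comparisons non-significant, telomere T/S
#' and global repertoire perturbation significant.
#'
#' @param seed Master seed for the simulated study.
#' @param config Optional [cohort_config()] override (its seed is replaced).
#' @param alpha Significance level.
#' @return List with `p` (named p-values), `pattern_ok` (logical).
#' @export
simulate_and_check_pattern <- function(seed, config = NULL, alpha = 0.05) {
  if (is.null(config)) config <- cohort_config(seed = seed)
  else config$seed <- as.integer(seed)
  cohort <- generate_cohort(config)
  peaks <- generate_peak_table(cohort, config)
  plate_tel <- generate_qpcr_plate(cohort$truth$clinical, "telomere", config,
                                   seed = subject_seed(config$seed, 0L, 0L, 2L))
  plate_exc <- generate_qpcr_plate(cohort$truth$clinical, "excision", config,
                                   seed = subject_seed(config$seed, 0L, 0L, 3L))
  res <- run_study_pipeline(cohort$subjects, peaks, plate_tel, plate_exc,
                            config = config, alpha = alpha)
  p <- vapply(res$comparisons, function(cmp) cmp$kw_p, numeric(1))
  pattern_ok <- p[["trec"]] > alpha && p[["krec"]] > alpha &&
    p[["ts"]] <= alpha && p[["perturbation"]] <= alpha
  list(p = p, pattern_ok = pattern_ok, result = res)
}
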