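#' Derive composite sub-scores from raw test results
#'
#' Adds (or recomputes) the battery's derived scores at both timepoints:
#'
#' * `stroop_interference`: Stroop card 3 time minus the mean of cards
#'   1 and 2;
#' * `mct_slope`: Memory Comparison Test 4-letter trial time minus the
#'   1-letter trial time;
#' * `wlg_total`: total correct responses over the three Word List
#'   Generation trials (animals, professions, letter M);
#' * `spart_direct`: mean of the three SPART direct-recall trials;
#' * `srt_average`: mean of the four SRT sub-scores (informational; the
#'   memory domain uses the four SRT sub-scores individually).
#'
#' A derived score is `NA` whenever any constituent trial is missing --
#' missingness propagates, it is never treated as zero.
#'
#' @param cohort A [CognitiveCohort-class].
#' @return The cohort with derived rows appended (replaced if present).
#' @export
#' @examples
#' cfg <- cohortConfig(n_controls = 25, n_patients = 0, seed = 3)
#' hc <- deriveComposites(generateControls(cfg))
#' rawScores(hc)["stroop_interference", 1:3]
deriveComposites <- function(cohort) {
  stopifnot(is(cohort, "CognitiveCohort"))
  registry <- subscoreRegistry()
  t1 <- derive_matrix(rawScores(cohort, 1))
  t2 <- derive_matrix(rawScores(cohort, 2))
  CognitiveCohort(t1, t2, subjectInfo(cohort), registry = registry)
}

# composite definitions on a sub-score x subject matrix
derive_matrix <- function(m) {
  get_row <- function(name) {
    if (name %in% rownames(m)) m[name, ] else rep(NA_real_, ncol(m))
  }
  strict_mean <- function(rows) {
    vals <- do.call(rbind, lapply(rows, get_row))
    out <- colMeans(vals)          # NA if any constituent NA
    out
  }
  derived <- rbind(
    stroop_interference = get_row("stroop_card3") -
      (get_row("stroop_card1") + get_row("stroop_card2")) / 2,
    mct_slope = get_row("mct_4letter") - get_row("mct_1letter"),
    wlg_total = get_row("wlg_animals") + get_row("wlg_professions") +
      get_row("wlg_m"),
    spart_direct = strict_mean(c("spart_t1", "spart_t2", "spart_t3")),
    srt_average = strict_mean(c("srt_lts", "srt_ltr", "srt_cltr",
                                "srt_delayed"))
  )
  colnames(derived) <- colnames(m)
  keep <- setdiff(rownames(m), rownames(derived))
  rbind(m[keep, , drop = FALSE], derived)
}
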