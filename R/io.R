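#' Read a cohort from CSV files
#'
#' The interchange contract is long-format scores plus per-subject
#' covariates:
#'
#' * `scores`: columns `subject_id`, `timepoint` (1 or 2), `subscore`
#'   (registry name), `value`;
#' * `subjects`: one row per subject with `subject_id`, `age`, `sex`,
#'   `education` and optionally `edss`, `disease_duration`, `ms_type`,
#'   `group_truth`, `followup`, the [MRI_MEASURES] columns (alternatively
#'   supplied in a separate `mri` CSV keyed by `subject_id`).
#'
#' Row-level validation problems (unknown sub-score names, duplicate
#' subject-timepoint-sub-score rows, out-of-range education or EDSS,
#' non-finite values) are collected and reported together.
#'
#' @param scores,subjects,mri File paths (`mri` optional).
#' @param registry Sub-score registry.
#' @return A [CognitiveCohort-class].
#' @export
readCohort <- function(scores, subjects, mri = NULL,
                       registry = subscoreRegistry()) {
  sc <- read.csv(scores, stringsAsFactors = FALSE)
  su <- read.csv(subjects, stringsAsFactors = FALSE)
  problems <- character()
  need <- setdiff(c("subject_id", "timepoint", "subscore", "value"),
                  names(sc))
  if (length(need)) {
    stop("scores CSV lacks column(s): ", paste(need, collapse = ", "))
  }
  need <- setdiff(c("subject_id", "age", "sex", "education"), names(su))
  if (length(need)) {
    stop("subjects CSV lacks column(s): ", paste(need, collapse = ", "))
  }
  unknown <- setdiff(unique(sc$subscore), registry$subscore)
  if (length(unknown)) {
    problems <- c(problems, paste0(
      "unknown sub-score name(s): ", paste(unknown, collapse = ", "),
      " (registry: ", paste(registry$subscore, collapse = ", "), ")"))
  }
  if (!all(sc$timepoint %in% c(1, 2))) {
    problems <- c(problems, "timepoint must be 1 or 2")
  }
  key <- paste(sc$subject_id, sc$timepoint, sc$subscore)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    problems <- c(problems, paste0("duplicated score row(s): ",
                                   paste(head(dup, 5), collapse = "; ")))
  }
  if (any(!is.finite(sc$value) & !is.na(sc$value))) {
    problems <- c(problems, "non-finite score values present")
  }
  bad_edu <- !is.na(su$education) & !(su$education %in% 1:7)
  if (any(bad_edu)) {
    problems <- c(problems, paste0(
      "education outside the 1-7 scale for subject(s): ",
      paste(su$subject_id[bad_edu], collapse = ", ")))
  }
  if ("edss" %in% names(su)) {
    e <- su$edss
    bad <- !is.na(e) & (e < 0 | e > 10 | abs(e * 2 - round(e * 2)) > 1e-8)
    if (any(bad)) {
      problems <- c(problems, paste0(
        "EDSS outside 0-10 (0.5 steps) for subject(s): ",
        paste(su$subject_id[bad], collapse = ", ")))
    }
  }
  orphan <- setdiff(unique(sc$subject_id), su$subject_id)
  if (length(orphan)) {
    problems <- c(problems, paste0("scores for unlisted subject(s): ",
                                   paste(orphan, collapse = ", ")))
  }
  if (!is.null(mri)) {
    mr <- read.csv(mri, stringsAsFactors = FALSE)
    if (!"subject_id" %in% names(mr)) {
      problems <- c(problems, "mri CSV lacks subject_id")
    } else {
      su <- merge(su, mr, by = "subject_id", all.x = TRUE, sort = FALSE)
    }
  }
  if (length(problems)) {
    stop("cohort validation failed:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  ids <- su$subject_id
  subs <- unique(sc$subscore)
  mk <- function(tp) {
    m <- matrix(NA_real_, length(subs), length(ids),
                dimnames = list(subs, ids))
    rows <- sc[sc$timepoint == tp, ]
    m[cbind(match(rows$subscore, subs), match(rows$subject_id, ids))] <-
      rows$value
    m
  }
  CognitiveCohort(mk(1), mk(2), su, registry = registry)
}

#' Write a cohort to CSV files
#'
#' Inverse of [readCohort()]: writes `scores.csv` (long format, one row
#' per subject-timepoint-sub-score, missing values omitted) and
#' `subjects.csv` into `dir`.
#'
#' @param cohort A [CognitiveCohort-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- function(tp) {
    m <- rawScores(cohort, tp)
    df <- data.frame(subject_id = rep(colnames(m), each = nrow(m)),
                     timepoint = tp,
                     subscore = rep(rownames(m), times = ncol(m)),
                     value = as.vector(m), stringsAsFactors = FALSE)
    df[!is.na(df$value), ]
  }
  scores_path <- file.path(dir, "scores.csv")
  subjects_path <- file.path(dir, "subjects.csv")
  write.csv(rbind(long(1), long(2)), scores_path, row.names = FALSE)
  write.csv(subjectInfo(cohort), subjects_path, row.names = FALSE)
  invisible(list(scores = scores_path, subjects = subjects_path))
}
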