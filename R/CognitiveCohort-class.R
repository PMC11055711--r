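#' MRI summary measures consumed by the pipeline
#'
#' Per-subject scalar MRI measures: normalized cortical grey-matter volume
#' (L), normalized white-matter volume (L), white-matter lesion volume
#' (natural-log mL), normalized thalamus and hippocampus volumes (mL),
#' cortical-lesion count and whole-skeleton fractional anisotropy.  Image
#' acquisition and processing are out of scope; these enter as precomputed
#' scalars.
#'
#' @export
MRI_MEASURES <- c("cortical_gmv", "wm_volume", "lesion_volume",
                  "thalamus_volume", "hippocampus_volume",
                  "cortical_lesion_count", "fa")

#' CognitiveCohort: raw neuropsychological scores plus clinical covariates
#'
#' An S4 container extending
#' [SummarizedExperiment::SummarizedExperiment]: rows are battery
#' sub-scores (described by the sub-score registry in `rowData`), columns
#' are subjects, and the two assays `"t1"` and `"t2"` hold raw scores at
#' baseline and follow-up (`NA` throughout `"t2"` for subjects lost to
#' follow-up).  `colData` carries demographics (age, sex, education on the
#' 1--7 scale, EDSS, disease type and duration), the per-subject MRI
#' scalars, the generating group label for synthetic cohorts and a
#' `followup` flag.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @aliases CognitiveCohort-class
#' @export
setClass("CognitiveCohort", contains = "SummarizedExperiment")

.validCognitiveCohort <- function(object) {
  msgs <- character()
  if (!all(c("t1", "t2") %in% names(assays(object)))) {
    msgs <- c(msgs, "assays must contain 't1' and 't2'")
  }
  cd <- colData(object)
  needed <- c("subject_id", "age", "sex", "education", "followup")
  miss <- setdiff(needed, names(cd))
  if (length(miss)) {
    msgs <- c(msgs, paste0("colData lacks column(s): ",
                           paste(miss, collapse = ", ")))
  } else {
    if (anyDuplicated(cd$subject_id)) {
      msgs <- c(msgs, "duplicated subject_id")
    }
    bad_sex <- !(cd$sex %in% c("male", "female") | is.na(cd$sex))
    if (any(bad_sex)) msgs <- c(msgs, "sex must be 'male' or 'female'")
    edu <- cd$education
    bad_edu <- !is.na(edu) & !(edu %in% 1:7)
    if (any(bad_edu)) {
      msgs <- c(msgs, "education must be on the 1-7 scale")
    }
    if ("edss" %in% names(cd)) {
      e <- cd$edss
      bad <- !is.na(e) & (e < 0 | e > 10 | abs(e * 2 - round(e * 2)) > 1e-8)
      if (any(bad)) msgs <- c(msgs, "edss must lie in 0-10 in 0.5 steps")
    }
    if ("ms_type" %in% names(cd)) {
      bad <- !(cd$ms_type %in% c("RR", "SP", "PP", "none") | is.na(cd$ms_type))
      if (any(bad)) msgs <- c(msgs, "ms_type must be RR/SP/PP/none")
    }
  }
  rd <- rowData(object)
  if (!all(c("direction", "constituent") %in% names(rd))) {
    msgs <- c(msgs, "rowData must carry the sub-score registry")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("CognitiveCohort", .validCognitiveCohort)

#' Construct a CognitiveCohort
#'
#' @param t1 Numeric matrix of raw scores, sub-scores in rows, subjects in
#'   columns.  Row names must appear in the registry; column names are
#'   subject ids.
#' @param t2 Matching follow-up matrix, or `NULL` when no subject has
#'   follow-up data (an all-`NA` matrix is then used).
#' @param subjects `data.frame` with one row per subject: `subject_id`,
#'   `age`, `sex` (`"male"`/`"female"`), `education` (1--7) and optionally
#'   `edss`, `disease_duration`, `ms_type`, `group_truth` and the
#'   [MRI_MEASURES] columns.
#' @param registry Sub-score registry, see [subscoreRegistry()].
#' @return A [CognitiveCohort-class] object.
#' @export
#' @examples
#' cfg <- cohortConfig(n_controls = 30, n_patients = 0, seed = 1)
#' hc <- generateControls(cfg)
#' hc
CognitiveCohort <- function(t1, t2 = NULL, subjects, registry = subscoreRegistry()) {
  t1 <- as.matrix(t1)
  if (is.null(rownames(t1))) stop("t1 must have sub-score row names")
  unknown <- setdiff(rownames(t1), registry$subscore)
  if (length(unknown)) {
    stop("unknown sub-score name(s): ", paste(unknown, collapse = ", "),
         "; registry knows: ", paste(registry$subscore, collapse = ", "))
  }
  if (is.null(t2)) {
    t2 <- t1
    t2[] <- NA_real_
  }
  t2 <- as.matrix(t2)
  if (!identical(dim(t1), dim(t2))) stop("t1 and t2 must have equal dims")
  t2 <- t2[rownames(t1), , drop = FALSE]
  subjects <- as.data.frame(subjects)
  if (!"subject_id" %in% names(subjects)) stop("subjects needs subject_id")
  if (is.null(colnames(t1))) colnames(t1) <- subjects$subject_id
  ord <- match(colnames(t1), subjects$subject_id)
  if (anyNA(ord)) stop("score columns and subject rows do not match")
  subjects <- subjects[ord, , drop = FALSE]
  if (!"followup" %in% names(subjects)) {
    subjects$followup <- colSums(!is.na(t2)) > 0
  }
  colnames(t2) <- colnames(t1)
  rd <- registry[rownames(t1), , drop = FALSE]
  se <- SummarizedExperiment(
    assays = list(t1 = t1, t2 = t2),
    rowData = DataFrame(rd),
    colData = DataFrame(subjects, row.names = subjects$subject_id)
  )
  new("CognitiveCohort", se)
}

#' @describeIn CognitiveCohort-class raw-score matrix at one timepoint.
#' @param x A `CognitiveCohort`.
#' @param timepoint 1 (baseline) or 2 (follow-up).
#' @export
rawScores <- function(x, timepoint = 1) {
  stopifnot(is(x, "CognitiveCohort"), timepoint %in% c(1, 2))
  assay(x, if (timepoint == 1) "t1" else "t2")
}

#' @describeIn CognitiveCohort-class subject-level covariates as a
#'   `data.frame`.
#' @export
subjectInfo <- function(x) {
  stopifnot(is(x, "CognitiveCohort"))
  as.data.frame(colData(x))
}

#' @describeIn CognitiveCohort-class subjects-by-measures matrix of MRI
#'   scalars (columns restricted to those present).
#' @export
mriMeasures <- function(x) {
  cd <- subjectInfo(x)
  have <- intersect(MRI_MEASURES, names(cd))
  as.matrix(cd[, have, drop = FALSE])
}

#' @describeIn CognitiveCohort-class logical: which subjects have
#'   follow-up scores.
#' @export
hasFollowup <- function(x) {
  stats::setNames(subjectInfo(x)$followup, colnames(x))
}

setMethod("show", "CognitiveCohort", function(object) {
  cd <- subjectInfo(object)
  cat("CognitiveCohort with", ncol(object), "subjects and",
      nrow(object), "sub-scores\n")
  if ("ms_type" %in% names(cd)) {
    n_ms <- sum(cd$ms_type != "none", na.rm = TRUE)
    cat("  patients:", n_ms, " controls:", ncol(object) - n_ms, "\n")
  }
  cat("  follow-up available:", sum(cd$followup), "subjects\n")
  cat("  derived composites present:",
      any(!rowData(object)$input), "\n")
})
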