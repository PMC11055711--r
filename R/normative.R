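#' NormativeModelSet: regression-based norms fitted on healthy controls
#'
#' One ordinary-least-squares model per battery sub-score, regressing the
#' raw score on age (years), sex (male = 1, female = 0) and education
#' (numeric 1--7).  The residual standard deviation (denominator n - 4)
#' scales the demographically corrected Z-score; the orientation of each
#' sub-score is fixed a priori by the registry, never by the data.
#'
#' @slot models Named list, one per sub-score, each with elements
#'   `coefficients` (intercept, age, sex_male, education), `residual_sd`,
#'   `direction` and `n_fit`.
#' @slot timepoint Which control timepoint the norms were fitted on.
#' @aliases NormativeModelSet-class
#' @export
setClass("NormativeModelSet",
         representation(models = "list", timepoint = "integer"))

setValidity("NormativeModelSet", function(object) {
  msgs <- character()
  for (s in names(object@models)) {
    m <- object@models[[s]]
    if (!all(c("coefficients", "residual_sd", "direction", "n_fit") %in%
             names(m))) {
      msgs <- c(msgs, paste0("model '", s, "' incomplete"))
      next
    }
    if (!is.finite(m$residual_sd) || m$residual_sd <= 0) {
      msgs <- c(msgs, paste0("model '", s, "' has non-positive residual SD"))
    }
    if (m$n_fit < 20) {
      msgs <- c(msgs, paste0("model '", s, "' fitted on fewer than 20 controls"))
    }
    if (!m$direction %in% c("higher", "lower")) {
      msgs <- c(msgs, paste0("model '", s, "' has invalid direction"))
    }
  }
  if (!object@timepoint %in% c(1L, 2L)) msgs <- c(msgs, "timepoint must be 1 or 2")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "NormativeModelSet", function(object) {
  cat("NormativeModelSet:", length(object@models),
      "sub-score norms (timepoint", object@timepoint, ")\n")
  n <- vapply(object@models, function(m) m$n_fit, numeric(1))
  cat("  fitted on", max(n), "controls\n")
  cat("  sub-scores:", paste(head(names(object@models), 6), collapse = ", "),
      if (length(object@models) > 6) "..." else "", "\n")
})

#' @describeIn NormativeModelSet-class extract one sub-score's model.
#' @param norms A `NormativeModelSet`.
#' @param subscore Sub-score name.
#' @export
normModel <- function(norms, subscore) {
  m <- norms@models[[subscore]]
  if (is.null(m)) stop("no normative model for sub-score '", subscore, "'")
  m
}

#' @describeIn NormativeModelSet-class names of covered sub-scores.
#' @export
normedSubscores <- function(norms) names(norms@models)

# predicted raw score at given demographics
norm_predict <- function(model, covars) {
  b <- model$coefficients
  b[["(Intercept)"]] + b[["age"]] * covars$age +
    b[["sex_male"]] * covars$sex_male + b[["education"]] * covars$education
}

#' Fit regression-based normative models on healthy controls
#'
#' For every domain-constituent sub-score present in the cohort, fits
#' `raw ~ age + sex + education` by OLS on controls with complete
#' demographics at the requested timepoint.  Timepoint-2 norms capture
#' practice and are intended for the reliable-change stage only;
#' cross-sectional classification at follow-up reuses timepoint-1 norms.
#'
#' @param controls A [CognitiveCohort-class] of healthy controls with
#'   composites derived (see [deriveComposites()]).
#' @param timepoint 1 or 2.
#' @param subscores Which sub-scores to fit; defaults to all registry
#'   constituents present in the cohort.
#' @return A [NormativeModelSet-class].
#' @export
#' @examples
#' hc <- deriveComposites(generateControls(cohortConfig(n_controls = 40,
#'                                                      seed = 2)))
#' fitNorms(hc, timepoint = 1)
fitNorms <- function(controls, timepoint = 1, subscores = NULL) {
  stopifnot(is(controls, "CognitiveCohort"))
  registry <- subscoreRegistry()
  scores <- rawScores(controls, timepoint)
  if (is.null(subscores)) {
    subscores <- intersect(registry$subscore[registry$constituent],
                           rownames(scores))
    if (!length(subscores)) {
      stop("no constituent sub-scores present; run deriveComposites() first")
    }
  }
  cd <- subjectInfo(controls)
  covars <- data.frame(age = cd$age,
                       sex_male = as.numeric(cd$sex == "male"),
                       education = as.numeric(cd$education))
  models <- list()
  for (s in subscores) {
    if (!s %in% rownames(scores)) {
      stop("cannot fit norms: sub-score '", s, "' absent from controls")
    }
    y <- scores[s, ]
    usable <- is.finite(y) & complete.cases(covars)
    if (sum(usable) < 20) {
      stop("cannot fit norms for sub-score '", s, "': only ", sum(usable),
           " usable controls (need >= 20)")
    }
    dat <- cbind(y = y[usable], covars[usable, , drop = FALSE])
    if (sd(dat$y) < 1e-12) {
      stop("cannot fit norms for sub-score '", s,
           "': raw scores are constant (zero residual variance)")
    }
    fit <- lm(y ~ age + sex_male + education, data = dat)
    rsd <- summary(fit)$sigma                 # denominator n - 4
    if (!is.finite(rsd) || rsd <= 0) {
      stop("cannot fit norms for sub-score '", s, "': zero residual variance")
    }
    models[[s]] <- list(coefficients = coef(fit), residual_sd = rsd,
                        direction = registry[s, "direction"],
                        n_fit = sum(usable),
                        se = summary(fit)$coefficients[, "Std. Error"])
  }
  new("NormativeModelSet", models = models, timepoint = as.integer(timepoint))
}

#' Demographically corrected Z-scores
#'
#' Converts raw sub-scores to Z: `z_raw = (observed - predicted) /
#' residual_sd`, sign-flipped for lower-is-better (timed) scores so that
#' the returned Z is always oriented higher = better and Z < -1.5
#' uniformly means impairment.  Subjects with missing demographics are
#' excluded (all-`NA` column) with a warning; missing raw scores
#' propagate as `NA`.
#'
#' @param cohort A [CognitiveCohort-class] with composites derived.
#' @param norms A [NormativeModelSet-class] covering every constituent
#'   present.
#' @param timepoint Which assay to score (1 or 2).
#' @return Numeric matrix, sub-scores x subjects, oriented higher = better.
#' @export
#' @examples
#' sim <- simulateCohort(cohortConfig(n_controls = 40, n_patients = 20,
#'                                    seed = 5))
#' z <- scoreZ(sim$patients, sim$norms)
#' z["sdmt", 1:3]
scoreZ <- function(cohort, norms, timepoint = 1) {
  stopifnot(is(cohort, "CognitiveCohort"), is(norms, "NormativeModelSet"))
  scores <- rawScores(cohort, timepoint)
  subscores <- intersect(rownames(scores), normedSubscores(norms))
  present_cons <- intersect(rownames(scores),
                            subscoreRegistry()$subscore[subscoreRegistry()$constituent])
  uncovered <- setdiff(present_cons, subscores)
  if (length(uncovered)) {
    stop("norms do not cover sub-score(s): ",
         paste(uncovered, collapse = ", "))
  }
  cd <- subjectInfo(cohort)
  covars <- data.frame(age = cd$age,
                       sex_male = as.numeric(cd$sex == "male"),
                       education = as.numeric(cd$education))
  bad_demo <- !complete.cases(covars)
  if (any(bad_demo)) {
    warning(sum(bad_demo), " subject(s) with missing demographics excluded ",
            "from scoring: ", paste(cd$subject_id[bad_demo], collapse = ", "))
  }
  z <- matrix(NA_real_, length(subscores), ncol(scores),
              dimnames = list(subscores, colnames(scores)))
  for (s in subscores) {
    mod <- normModel(norms, s)
    pred <- norm_predict(mod, covars)
    zr <- (scores[s, ] - pred) / mod$residual_sd
    z[s, ] <- if (mod$direction == "higher") zr else -zr
  }
  z[, bad_demo] <- NA_real_
  z
}

#' Serialize / read normative models as JSON
#'
#' @param norms A [NormativeModelSet-class].
#' @param path Output (input) JSON file.
#' @return `readNorms` returns a [NormativeModelSet-class];
#'   `writeNorms` returns `path` invisibly.
#' @export
writeNorms <- function(norms, path) {
  payload <- list(timepoint = norms@timepoint,
                  models = lapply(norms@models, function(m) {
                    list(coefficients = as.list(m$coefficients),
                         residual_sd = m$residual_sd,
                         direction = m$direction, n_fit = m$n_fit)
                  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeNorms
#' @export
readNorms <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(payload$models, function(m) {
    list(coefficients = unlist(m$coefficients), residual_sd = m$residual_sd,
         direction = m$direction, n_fit = m$n_fit)
  })
  new("NormativeModelSet", models = models,
      timepoint = as.integer(payload$timepoint))
}
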