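#' Cognitive domains recognised by the pipeline
#'
#' The four a-priori domains: information processing speed (`ips`), verbal
#' and visuospatial memory (`memory`), executive functioning / working
#' memory (`efwm`) and attention (`attention`).
#'
#' @export
COGNITIVE_DOMAINS <- c("ips", "memory", "efwm", "attention")

#' Phenotype categories
#'
#' Six-level phenotype labelling used by the transition cross-tabulation:
#' the four isolated phenotypes, multi-domain impairment and cognitively
#' preserved.
#'
#' @export
PHENOTYPE_CATEGORIES <- c("isolated_ips", "isolated_memory", "isolated_efwm",
                          "isolated_attention", "multidomain", "preserved")

#' Load the neuropsychological sub-score registry
#'
#' The registry is a versioned plain-text table shipped with the package
#' (`inst/extdata/subscore_registry.csv`).  It defines, for every sub-score
#' of the extended BRB-N battery:
#'
#' * `input`: whether the score is a raw test result (as administered) or a
#'   derived composite (Stroop interference, MCT slope, WLG total, SPART
#'   direct-recall average, SRT average) computed by [deriveComposites()];
#' * `constituent` / `domain`: whether the score enters one of the four
#'   cognitive domains, and which;
#' * `direction`: `"higher"` when larger raw scores mean better performance
#'   (counts of correct responses) and `"lower"` for timed scores, fixed a
#'   priori so that Z < -1.5 uniformly means impairment;
#' * `efwm_facet`: the executive facet (inhibition, flexibility, fluency,
#'   working memory) a sub-score informs, used for sub-profiling;
#' * generator truth model (`ref_mean`, `age_slope`, `sex_slope`,
#'   `edu_slope`, `sd`, `trial_sd`, `practice`, `retest_r`): the linear
#'   demographic model, trial scatter, timepoint-1 to 2 practice effect and
#'   test-retest correlation used by the synthetic-cohort generator.
#'   Reference demographics are age 46, 40% male, education level 5.5.
#'
#' @param path Optional path to an alternative registry CSV with the same
#'   columns; defaults to the packaged registry.
#' @return A `data.frame`, one row per sub-score.
#' @export
#' @examples
#' reg <- subscoreRegistry()
#' table(reg$domain[reg$constituent])
subscoreRegistry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "subscore_registry.csv",
                        package = "cogpheno", mustWork = TRUE)
  }
  reg <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("subscore", "input", "constituent", "domain", "direction",
                "efwm_facet", "ref_mean", "age_slope", "sex_slope",
                "edu_slope", "sd", "trial_sd", "practice", "retest_r")
  missing <- setdiff(required, names(reg))
  if (length(missing)) {
    stop("registry is missing columns: ", paste(missing, collapse = ", "))
  }
  reg$input <- as.logical(reg$input)
  reg$constituent <- as.logical(reg$constituent)
  reg$domain[!nzchar(trimws(ifelse(is.na(reg$domain), "", reg$domain)))] <- NA
  reg$efwm_facet[!nzchar(trimws(ifelse(is.na(reg$efwm_facet), "",
                                       reg$efwm_facet)))] <- NA
  if (anyDuplicated(reg$subscore)) {
    stop("registry contains duplicated sub-score names")
  }
  bad <- reg$constituent & !(reg$domain %in% COGNITIVE_DOMAINS)
  if (any(bad)) {
    stop("constituent sub-scores with unknown domain: ",
         paste(reg$subscore[bad], collapse = ", "))
  }
  if (!all(reg$direction %in% c("higher", "lower"))) {
    stop("direction must be 'higher' or 'lower'")
  }
  rownames(reg) <- reg$subscore
  reg
}

#' Constituent sub-scores of a domain
#'
#' @param domain One of [COGNITIVE_DOMAINS].
#' @param registry A registry table from [subscoreRegistry()].
#' @return Character vector of sub-score names.
#' @export
domainConstituents <- function(domain, registry = subscoreRegistry()) {
  domain <- match.arg(domain, COGNITIVE_DOMAINS)
  registry$subscore[registry$constituent & registry$domain %in% domain]
}

# +1 when higher raw scores are better, -1 for timed scores
direction_sign <- function(registry, subscores = registry$subscore) {
  sgn <- ifelse(registry[subscores, "direction"] == "higher", 1, -1)
  names(sgn) <- subscores
  sgn
}

# reference demographics at which registry ref_mean values are anchored
REF_DEMOGRAPHICS <- c(age = 46, sex_male = 0.4, education = 5.5)

# generator truth prediction for modelled sub-scores
truth_predict <- function(registry, subscore, age, sex_male, education) {
  row <- registry[subscore, ]
  if (is.na(row$ref_mean)) {
    stop("sub-score '", subscore, "' has no generator truth model")
  }
  row$ref_mean +
    row$age_slope * (age - REF_DEMOGRAPHICS[["age"]]) +
    row$sex_slope * (sex_male - REF_DEMOGRAPHICS[["sex_male"]]) +
    row$edu_slope * (education - REF_DEMOGRAPHICS[["education"]])
}
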