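#' Configuration for the synthetic-cohort generator
#'
#' Builds and validates the configuration object consumed by
#' [generateControls()], [generatePatients()] and [simulateCohort()].  The
#' defaults emulate the study conditions the pipeline is designed for: a
#' normative sample of 96 healthy controls, 348 patients with ten-year
#' disease duration split over six phenotype groups, 71% retention at a
#' mean 4.9-year follow-up, and group-wise demographic/MRI distributions
#' on published clinical scales.
#'
#' @param n_controls,n_patients Cohort sizes.
#' @param seed Integer master seed; all generator randomness flows from it.
#' @param group_mix Named proportions over [PHENOTYPE_CATEGORIES]; must sum
#'   to 1.
#' @param domain_effects Named list, group -> named numeric over
#'   [COGNITIVE_DOMAINS]: the group's mean domain Z shift in normative SD
#'   units at baseline.
#' @param domain_drift Named list like `domain_effects`: additional mean
#'   shift at follow-up (negative = decline).  A single numeric recycles
#'   over groups and domains.
#' @param practice_effect Named numeric of per-sub-score mean raw-score
#'   change between healthy-control timepoints (overrides the registry).
#' @param test_retest_r Named numeric in (0,1) of per-sub-score
#'   test-retest correlations (overrides the registry).
#' @param subscore_scatter SD of the within-domain sub-score scatter
#'   around a subject's latent domain score (the scatter is centred within
#'   each domain so the domain mean equals the latent exactly).
#' @param domain_corr Residual correlation between the four latent domain
#'   scores.
#' @param domain_stability Correlation of the latent domain residual
#'   between timepoints.
#' @param attrition Fraction of patients retained at follow-up.
#' @param mri_params Named list, group -> list(mean=, sd=) over
#'   [MRI_MEASURES] (cortical-lesion counts parameterised by
#'   `clc_medlog`, the log of median count + 1).
#' @param mri_corr Correlation matrix (7 x 7, [MRI_MEASURES] order) of the
#'   latent Gaussian generating the MRI scalars.
#' @param mri_cog_slopes Named list, domain -> named numeric of
#'   standardized slopes: the latent domain score receives
#'   `sum(slope * standardized MRI)` so regression modelling has signal.
#' @param clc_available Fraction of patients with cortical-lesion counts.
#' @param followup_years `c(mean, sd)` of follow-up interval.
#' @param group_params Per-group demographic parameters; see
#'   [defaultGroupParams()].
#' @return A validated list of class `"cohort_config"`.
#' @export
#' @examples
#' cfg <- cohortConfig(n_controls = 96, n_patients = 348, seed = 7)
#' cfg$group_mix
cohortConfig <- function(n_controls = 96,
                         n_patients = 348,
                         seed = 1L,
                         group_mix = c(isolated_ips = 25, isolated_memory = 23,
                                       isolated_efwm = 37, isolated_attention = 23,
                                       multidomain = 148, preserved = 92) / 348,
                         domain_effects = defaultDomainEffects(),
                         domain_drift = -0.25,
                         practice_effect = NULL,
                         test_retest_r = NULL,
                         subscore_scatter = 0.5,
                         domain_corr = 0.4,
                         domain_stability = 0.8,
                         attrition = 0.71,
                         mri_params = defaultMriParams(),
                         mri_corr = defaultMriCorr(),
                         mri_cog_slopes = defaultMriCogSlopes(),
                         clc_available = 0.6,
                         followup_years = c(4.9, 0.9),
                         group_params = defaultGroupParams()) {
  registry <- subscoreRegistry()
  cfg <- list(n_controls = n_controls, n_patients = n_patients,
              seed = as.integer(seed), group_mix = group_mix,
              domain_effects = domain_effects,
              domain_drift = domain_drift,
              practice_effect = practice_effect,
              test_retest_r = test_retest_r,
              subscore_scatter = subscore_scatter,
              domain_corr = domain_corr,
              domain_stability = domain_stability,
              attrition = attrition, mri_params = mri_params,
              mri_corr = mri_corr, mri_cog_slopes = mri_cog_slopes,
              clc_available = clc_available,
              followup_years = followup_years,
              group_params = group_params)
  class(cfg) <- "cohort_config"
  validateCohortConfig(cfg, registry)
  cfg
}

#' @rdname cohortConfig
#' @param config An object to validate.
#' @param registry Sub-score registry.
#' @export
validateCohortConfig <- function(config, registry = subscoreRegistry()) {
  err <- function(field, msg) {
    stop("invalid cohort configuration: field '", field, "' ", msg,
         call. = FALSE)
  }
  if (!is.numeric(config$n_controls) || config$n_controls < 0) {
    err("n_controls", "must be a non-negative count")
  }
  if (!is.numeric(config$n_patients) || config$n_patients < 0) {
    err("n_patients", "must be a non-negative count")
  }
  if (!is.numeric(config$seed) || is.na(config$seed) ||
      abs(config$seed) >= 2^30) {
    err("seed", "must be an integer below 2^30 in magnitude")
  }
  gm <- config$group_mix
  if (length(setdiff(names(gm), PHENOTYPE_CATEGORIES)) > 0) {
    err("group_mix", paste0("references unknown group(s): ",
        paste(setdiff(names(gm), PHENOTYPE_CATEGORIES), collapse = ", ")))
  }
  if (any(gm < 0) || abs(sum(gm) - 1) > 1e-9) {
    err("group_mix", "must be non-negative proportions summing to 1")
  }
  de <- config$domain_effects
  if (length(setdiff(names(de), PHENOTYPE_CATEGORIES)) > 0) {
    err("domain_effects", "references unknown group(s)")
  }
  rr <- resolve_subscore_param(config$test_retest_r, registry, "retest_r")
  if (any(!is.na(rr) & (rr <= 0 | rr >= 1))) {
    err("test_retest_r", "must lie strictly in (0, 1)")
  }
  if (config$subscore_scatter < 0) err("subscore_scatter", "must be >= 0")
  if (config$domain_corr < 0 || config$domain_corr >= 1) {
    err("domain_corr", "must lie in [0, 1)")
  }
  if (config$domain_stability < 0 || config$domain_stability > 1) {
    err("domain_stability", "must lie in [0, 1]")
  }
  if (config$attrition < 0 || config$attrition > 1) {
    err("attrition", "must be a fraction in [0, 1]")
  }
  for (g in names(config$mri_params)) {
    sds <- config$mri_params[[g]]$sd
    if (any(sds <= 0, na.rm = TRUE)) err("mri_params", paste0("group '", g, "' has non-positive SD"))
  }
  mc <- config$mri_corr
  if (!isSymmetric(unname(mc)) || any(eigen(mc, symmetric = TRUE,
                                            only.values = TRUE)$values < -1e-8)) {
    err("mri_corr", "must be a symmetric positive semi-definite matrix")
  }
  if (config$followup_years[2] < 0) err("followup_years", "needs sd >= 0")
  invisible(config)
}

#' Default per-group mean domain Z shifts
#'
#' Isolated groups are markedly impaired (-2.2 SD) on their own domain and
#' mildly below average elsewhere; the multi-domain group is impaired on
#' several domains; the preserved group sits slightly above the patient
#' average.
#' @return Named list, group -> named numeric over domains.
#' @export
defaultDomainEffects <- function() {
  base <- c(ips = -0.3, memory = -0.3, efwm = -0.3, attention = -0.3)
  iso <- function(d) { e <- base; e[d] <- -2.2; e }
  list(
    isolated_ips = iso("ips"),
    isolated_memory = iso("memory"),
    isolated_efwm = iso("efwm"),
    isolated_attention = iso("attention"),
    multidomain = c(ips = -2.2, memory = -2.0, efwm = -2.0, attention = -1.2),
    preserved = c(ips = 0.3, memory = 0.3, efwm = 0.3, attention = 0.3)
  )
}

#' Default per-group demographic parameters
#'
#' Age (years, mean/SD), male fraction, disease-duration (years, mean/SD),
#' EDSS median, MS-type proportions (RR/SP/PP) and education-level
#' probabilities, for the six patient groups and the healthy-control
#' group, on the scales typical of long-standing MS cohorts.
#' @return Named list of per-group parameter lists.
#' @export
defaultGroupParams <- function() {
  edu_pat <- c(0.02, 0.05, 0.10, 0.20, 0.28, 0.20, 0.15)
  edu_hc <- c(0.01, 0.03, 0.07, 0.15, 0.27, 0.25, 0.22)
  g <- function(age_m, age_s, male, dur_m, dur_s, edss_med, mstype,
                edu = edu_pat) {
    list(age = c(age_m, age_s), male_p = male, duration = c(dur_m, dur_s),
         edss_median = edss_med, ms_type = mstype / sum(mstype), edu = edu)
  }
  list(
    isolated_ips = g(46.63, 9.95, 0.160, 11.40, 6.35, 3.0, c(16, 5, 2)),
    isolated_memory = g(49.74, 9.46, 0.565, 11.72, 8.02, 3.0, c(11, 4, 4)),
    isolated_efwm = g(45.96, 12.79, 0.351, 10.32, 6.70, 3.0, c(27, 6, 3)),
    isolated_attention = g(48.78, 8.33, 0.130, 13.30, 6.66, 3.5, c(16, 4, 3)),
    multidomain = g(47.23, 10.33, 0.365, 10.43, 7.30, 3.5, c(102, 27, 15)),
    preserved = g(47.23, 10.34, 0.293, 10.43, 5.92, 3.0, c(72, 6, 9)),
    control = g(45.87, 10.45, 0.417, NA, NA, NA, c(1, 0, 0), edu = edu_hc)
  )
}

#' Default per-group MRI distribution parameters
#'
#' Means and SDs per group for the seven MRI scalars: cortical grey-matter
#' and white-matter volume (L), log lesion volume, thalamus and
#' hippocampus volume (mL), cortical-lesion count (parameterised by
#' `clc_medlog = log(median + 1)` with log-scale SD 0.9) and fractional
#' anisotropy.  Multi-domain patients show the most atrophy; controls the
#' least; lesion measures are absent for controls.
#' @return Named list, group -> list(mean, sd, clc_medlog).
#' @export
defaultMriParams <- function() {
  m <- function(gmv, gmv_s, wm, wm_s, les, les_s, thal, thal_s,
                hip, hip_s, clc_med, fa, fa_s) {
    list(mean = c(cortical_gmv = gmv, wm_volume = wm, lesion_volume = les,
                  thalamus_volume = thal, hippocampus_volume = hip,
                  cortical_lesion_count = NA, fa = fa),
         sd = c(cortical_gmv = gmv_s, wm_volume = wm_s, lesion_volume = les_s,
                thalamus_volume = thal_s, hippocampus_volume = hip_s,
                cortical_lesion_count = NA, fa = fa_s),
         clc_medlog = log(clc_med + 1), clc_sdlog = 0.9)
  }
  list(
    isolated_ips = m(0.75, 0.06, 0.67, 0.03, 4.06, 0.40, 17.89, 2.02,
                     8.86, 1.53, 16, 0.39, 0.03),
    isolated_memory = m(0.74, 0.04, 0.68, 0.04, 4.00, 0.48, 18.61, 2.18,
                        9.22, 1.31, 10, 0.39, 0.03),
    isolated_efwm = m(0.76, 0.04, 0.67, 0.03, 3.79, 0.39, 19.05, 1.69,
                      9.60, 1.21, 7, 0.40, 0.02),
    isolated_attention = m(0.77, 0.05, 0.67, 0.04, 3.96, 0.36, 18.30, 1.96,
                           9.45, 1.36, 11, 0.39, 0.02),
    multidomain = m(0.73, 0.06, 0.66, 0.04, 4.08, 0.41, 17.41, 2.75,
                    8.76, 1.46, 14, 0.39, 0.03),
    preserved = m(0.76, 0.05, 0.68, 0.03, 3.90, 0.34, 19.19, 1.68,
                  9.69, 1.15, 6, 0.40, 0.02),
    control = m(0.78, 0.05, 0.70, 0.03, NA, NA, 20.64, 1.33,
                10.28, 0.97, NA, 0.42, 0.02)
  )
}

#' Default correlation structure of the MRI scalars
#'
#' Moderate positive correlations among the volumetric measures and FA,
#' negative correlations of lesion measures with volumes and FA --
#' realistic collinearity for the screening stage.
#' @return 7 x 7 correlation matrix in [MRI_MEASURES] order.
#' @export
defaultMriCorr <- function() {
  p <- length(MRI_MEASURES)
  R <- matrix(0, p, p, dimnames = list(MRI_MEASURES, MRI_MEASURES))
  vols <- c("cortical_gmv", "wm_volume", "thalamus_volume",
            "hippocampus_volume")
  R[vols, vols] <- 0.45
  R[vols, "fa"] <- R["fa", vols] <- 0.35
  R["lesion_volume", vols] <- R[vols, "lesion_volume"] <- -0.30
  R["lesion_volume", "fa"] <- R["fa", "lesion_volume"] <- -0.35
  R["cortical_lesion_count", "lesion_volume"] <-
    R["lesion_volume", "cortical_lesion_count"] <- 0.50
  R["cortical_lesion_count", vols] <-
    R[vols, "cortical_lesion_count"] <- -0.20
  R["cortical_lesion_count", "fa"] <-
    R["fa", "cortical_lesion_count"] <- -0.25
  diag(R) <- 1
  R
}

#' Default standardized MRI-to-domain slopes
#'
#' Latent domain scores receive modest contributions from standardized MRI
#' measures: processing speed from cortical grey matter and FA, memory
#' from cortical grey matter and hippocampus, executive function from
#' thalamus; attention has no structural driver.
#' @return Named list, domain -> named numeric.
#' @export
defaultMriCogSlopes <- function() {
  list(ips = c(cortical_gmv = 0.25, fa = 0.20),
       memory = c(cortical_gmv = 0.20, hippocampus_volume = 0.25),
       efwm = c(thalamus_volume = 0.15),
       attention = numeric(0))
}

# named per-subscore parameter with registry fallback
resolve_subscore_param <- function(override, registry, column) {
  vals <- stats::setNames(registry[[column]], registry$subscore)
  if (!is.null(override)) {
    unknown <- setdiff(names(override), registry$subscore)
    if (length(unknown)) {
      stop("unknown sub-score in override: ", paste(unknown, collapse = ", "))
    }
    vals[names(override)] <- override
  }
  vals
}

# equicorrelation matrix
equi_corr <- function(k, rho) {
  R <- matrix(rho, k, k)
  diag(R) <- 1
  R
}

# sample demographics for n subjects of one group
sample_demographics <- function(n, gp) {
  age <- rnorm(n, gp$age[1], gp$age[2])
  age <- pmin(pmax(age, 18), 80)
  sex <- ifelse(runif(n) < gp$male_p, "male", "female")
  education <- sample(1:7, n, replace = TRUE, prob = gp$edu)
  if (is.na(gp$edss_median)) {
    edss <- rep(NA_real_, n); duration <- rep(NA_real_, n)
    ms_type <- rep("none", n)
  } else {
    edss <- round(pmin(pmax(rnorm(n, gp$edss_median, 1.2), 0), 8) * 2) / 2
    duration <- pmax(rnorm(n, gp$duration[1], gp$duration[2]), 1)
    ms_type <- sample(c("RR", "SP", "PP"), n, replace = TRUE,
                      prob = gp$ms_type)
  }
  data.frame(age = age, sex = sex, education = education, edss = edss,
             disease_duration = duration, ms_type = ms_type,
             stringsAsFactors = FALSE)
}

# Build the raw input-score matrix (inputs x n) from constituent values and
# auxiliary noise.  `cons` is a constituent x n matrix of target raw values
# (already on the raw scale, practice included); `aux` provides
# mct_1letter values and trial noise draws.
assemble_inputs <- function(cons, aux, registry) {
  n <- ncol(cons)
  inputs <- registry$subscore[registry$input]
  m <- matrix(NA_real_, length(inputs), n,
              dimnames = list(inputs, colnames(cons)))
  direct <- c("sdmt", "srt_lts", "srt_ltr", "srt_cltr", "srt_delayed",
              "spart_delayed", "stroop_card1", "stroop_card2",
              "cst_numbers", "cst_letters", "cst_shifting")
  m[direct, ] <- cons[direct, ]
  sp_sd <- registry["spart_direct", "trial_sd"]
  m["spart_t1", ] <- cons["spart_direct", ] + aux$sp1 * sp_sd
  m["spart_t2", ] <- cons["spart_direct", ] + aux$sp2 * sp_sd
  m["spart_t3", ] <- 3 * cons["spart_direct", ] -
    m["spart_t1", ] - m["spart_t2", ]
  wl_sd <- registry["wlg_total", "trial_sd"]
  m["wlg_animals", ] <- cons["wlg_total", ] / 3 + aux$wl1 * wl_sd
  m["wlg_professions", ] <- cons["wlg_total", ] / 3 + aux$wl2 * wl_sd
  m["wlg_m", ] <- cons["wlg_total", ] -
    m["wlg_animals", ] - m["wlg_professions", ]
  m["stroop_card3", ] <- cons["stroop_interference", ] +
    (m["stroop_card1", ] + m["stroop_card2", ]) / 2
  m["mct_1letter", ] <- aux$mct1
  m["mct_4letter", ] <- aux$mct1 + cons["mct_slope", ]
  m
}

# fresh auxiliary draws; mct_1letter correlated across timepoints
draw_aux <- function(n, registry, covars, tp, prev = NULL, retest) {
  pred1 <- truth_predict(registry, "mct_1letter", covars$age,
                         covars$sex_male, covars$education)
  sdm <- registry["mct_1letter", "sd"]
  r <- retest[["mct_1letter"]]
  z_new <- rnorm(n)
  z <- if (is.null(prev)) z_new else prev$mct_z * r + sqrt(1 - r^2) * z_new
  practice <- if (tp == 2) registry["mct_1letter", "practice"] else 0
  list(sp1 = rnorm(n), sp2 = rnorm(n), wl1 = rnorm(n), wl2 = rnorm(n),
       mct1 = pred1 + practice + sdm * z, mct_z = z)
}

#' Generate a healthy-control normative sample
#'
#' Controls' raw sub-scores are drawn from the registry truth models:
#' linear in age, sex and education with Gaussian noise, independently per
#' sub-score.  Follow-up scores correlate with baseline at the per-test
#' test-retest correlation and are shifted by the per-test practice
#' effect; all controls have both timepoints.
#'
#' @param config A [cohortConfig()].
#' @return A [CognitiveCohort-class] of `config$n_controls` subjects.
#' @export
#' @examples
#' hc <- generateControls(cohortConfig(n_controls = 30, seed = 7))
#' dim(rawScores(hc))
generateControls <- function(config) {
  validateCohortConfig(config)
  registry <- subscoreRegistry()
  n <- config$n_controls
  local_seed(config$seed)
  gp <- config$group_params$control
  demo <- sample_demographics(n, gp)
  covars <- data.frame(age = demo$age,
                       sex_male = as.numeric(demo$sex == "male"),
                       education = demo$education)
  retest <- resolve_subscore_param(config$test_retest_r, registry, "retest_r")
  practice <- resolve_subscore_param(config$practice_effect, registry,
                                     "practice")
  cons_names <- registry$subscore[registry$constituent]
  ids <- sprintf("HC%03d", seq_len(n))

  z1 <- matrix(rnorm(length(cons_names) * n), length(cons_names), n,
               dimnames = list(cons_names, ids))
  eps <- matrix(rnorm(length(cons_names) * n), length(cons_names), n)
  r <- retest[cons_names]
  z2 <- z1 * r + eps * sqrt(1 - r^2)

  to_raw <- function(z, tp) {
    cons <- z
    for (s in cons_names) {
      pred <- truth_predict(registry, s, covars$age, covars$sex_male,
                            covars$education)
      sgn <- if (registry[s, "direction"] == "higher") 1 else -1
      pr <- if (tp == 2) practice[[s]] else 0
      cons[s, ] <- pred + pr + sgn * registry[s, "sd"] * z[s, ]
    }
    cons
  }
  aux1 <- draw_aux(n, registry, covars, 1, retest = retest)
  aux2 <- draw_aux(n, registry, covars, 2, prev = aux1, retest = retest)
  t1 <- assemble_inputs(to_raw(z1, 1), aux1, registry)
  t2 <- assemble_inputs(to_raw(z2, 2), aux2, registry)

  subjects <- data.frame(subject_id = ids, group_truth = "control", demo,
                         followup = TRUE, followup_years = NA_real_,
                         stringsAsFactors = FALSE)
  for (mm in MRI_MEASURES) subjects[[mm]] <- NA_real_
  mri <- draw_mri(n, config$mri_params$control, config$mri_corr)
  subjects[, MRI_MEASURES] <- mri
  CognitiveCohort(t1, t2, subjects, registry = registry)
}

# draw MRI scalars for one group; lesion measures may be NA (controls)
draw_mri <- function(n, pars, R) {
  z <- MASS::mvrnorm(n, mu = rep(0, nrow(R)), Sigma = R)
  if (n == 1) z <- matrix(z, nrow = 1)
  colnames(z) <- MRI_MEASURES
  out <- matrix(NA_real_, n, length(MRI_MEASURES),
                dimnames = list(NULL, MRI_MEASURES))
  for (mm in setdiff(MRI_MEASURES, "cortical_lesion_count")) {
    if (!is.na(pars$mean[[mm]])) {
      out[, mm] <- pars$mean[[mm]] + pars$sd[[mm]] * z[, mm]
    }
  }
  if (!is.na(pars$clc_medlog)) {
    out[, "cortical_lesion_count"] <- pmax(0, round(
      exp(pars$clc_medlog + pars$clc_sdlog * z[, "cortical_lesion_count"]) - 1))
  }
  attr(out, "z") <- z
  out
}

#' Generate an MS patient cohort with injected domain effects
#'
#' Each patient is assigned a phenotype group by `group_mix`.  A latent
#' domain-score vector is drawn around the group's `domain_effects` (plus
#' standardized-MRI contributions per `mri_cog_slopes`), with unit
#' marginal variance and residual cross-domain correlation `domain_corr`;
#' constituent sub-score Z-targets scatter around the latent with
#' within-domain centring, so a subject's expected pipeline domain Z
#' equals the injected effect.  Z-targets are converted to raw scores by
#' inverting the *fitted* normative models, which expresses effects in
#' normative SD units.  An `attrition` fraction lacks timepoint 2.
#'
#' @param config A [cohortConfig()].
#' @param norms A [NormativeModelSet-class] fitted on controls at
#'   timepoint 1 (see [fitNorms()]).
#' @return A [CognitiveCohort-class] of `config$n_patients` subjects.
#' @export
generatePatients <- function(config, norms) {
  validateCohortConfig(config)
  stopifnot(is(norms, "NormativeModelSet"))
  registry <- subscoreRegistry()
  n <- config$n_patients
  local_seed(config$seed + 1L)

  groups <- sample(names(config$group_mix), n, replace = TRUE,
                   prob = config$group_mix)
  ids <- sprintf("MS%04d", seq_len(n))
  # draw demographics group-blockwise but keep subject order
  demo <- data.frame(age = numeric(n), sex = character(n),
                     education = integer(n), edss = numeric(n),
                     disease_duration = numeric(n), ms_type = character(n),
                     stringsAsFactors = FALSE)
  mri <- matrix(NA_real_, n, length(MRI_MEASURES),
                dimnames = list(NULL, MRI_MEASURES))
  mri_z <- matrix(NA_real_, n, length(MRI_MEASURES),
                  dimnames = list(NULL, MRI_MEASURES))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    demo[idx, ] <- sample_demographics(length(idx), config$group_params[[g]])
    drawn <- draw_mri(length(idx), config$mri_params[[g]], config$mri_corr)
    mri[idx, ] <- drawn
    mri_z[idx, ] <- attr(drawn, "z")
  }
  covars <- data.frame(age = demo$age,
                       sex_male = as.numeric(demo$sex == "male"),
                       education = demo$education)

  # latent domain scores, unit marginal variance
  k <- length(COGNITIVE_DOMAINS)
  mu <- matrix(0, n, k, dimnames = list(NULL, COGNITIVE_DOMAINS))
  drift <- matrix(0, n, k, dimnames = list(NULL, COGNITIVE_DOMAINS))
  resid_sd <- matrix(1, n, k, dimnames = list(NULL, COGNITIVE_DOMAINS))
  Rmri <- config$mri_corr
  for (g in unique(groups)) {
    idx <- which(groups == g)
    eff <- config$domain_effects[[g]]
    if (is.null(eff)) eff <- stats::setNames(rep(0, k), COGNITIVE_DOMAINS)
    dft <- config$domain_drift
    if (is.list(dft)) dft <- dft[[g]]
    if (is.null(dft)) dft <- 0
    if (length(dft) == 1) dft <- stats::setNames(rep(dft, k), COGNITIVE_DOMAINS)
    for (d in COGNITIVE_DOMAINS) {
      s <- config$mri_cog_slopes[[d]]
      contrib <- 0
      expl <- 0
      if (length(s)) {
        contrib <- as.vector(mri_z[idx, names(s), drop = FALSE] %*% s)
        expl <- as.numeric(t(s) %*% Rmri[names(s), names(s)] %*% s)
        if (expl >= 0.95) stop("mri_cog_slopes explain >= 95% of domain '",
                               d, "' variance; reduce slopes")
      }
      mu[idx, d] <- eff[[d]] + contrib
      drift[idx, d] <- dft[[d]]
      resid_sd[idx, d] <- sqrt(1 - expl)
    }
  }
  Rdom <- equi_corr(k, config$domain_corr)
  u1 <- MASS::mvrnorm(n, mu = rep(0, k), Sigma = Rdom)
  u2new <- MASS::mvrnorm(n, mu = rep(0, k), Sigma = Rdom)
  if (n == 1) { u1 <- matrix(u1, 1); u2new <- matrix(u2new, 1) }
  a <- config$domain_stability
  u2 <- a * u1 + sqrt(1 - a^2) * u2new
  Z1 <- mu + resid_sd * u1
  Z2 <- mu + drift + resid_sd * u2
  colnames(Z1) <- colnames(Z2) <- COGNITIVE_DOMAINS

  # constituent Z targets: latent + centred within-domain scatter
  cons_names <- registry$subscore[registry$constituent]
  retest <- resolve_subscore_param(config$test_retest_r, registry, "retest_r")
  practice <- resolve_subscore_param(config$practice_effect, registry,
                                     "practice")
  sigma_e <- config$subscore_scatter
  zt <- function(Z, eta) {
    m <- matrix(NA_real_, length(cons_names), n,
                dimnames = list(cons_names, ids))
    for (d in COGNITIVE_DOMAINS) {
      cs <- intersect(cons_names, domainConstituents(d, registry))
      e <- eta[cs, , drop = FALSE]
      e <- sweep(e, 2, colMeans(e))          # centre within domain
      m[cs, ] <- matrix(Z[, d], length(cs), n, byrow = TRUE) + sigma_e * e
    }
    m
  }
  eta1 <- matrix(rnorm(length(cons_names) * n), length(cons_names), n,
                 dimnames = list(cons_names, ids))
  eta_new <- matrix(rnorm(length(cons_names) * n), length(cons_names), n,
                    dimnames = list(cons_names, ids))
  r <- retest[cons_names]
  eta2 <- eta1 * r + eta_new * sqrt(1 - r^2)
  z1 <- zt(Z1, eta1)
  z2 <- zt(Z2, eta2)

  # invert fitted norms: raw = predicted + practice + sign * z * residual SD
  to_raw <- function(z, tp) {
    cons <- z
    for (s in cons_names) {
      mod <- normModel(norms, s)
      pred <- norm_predict(mod, covars)
      sgn <- if (mod$direction == "higher") 1 else -1
      pr <- if (tp == 2) practice[[s]] else 0
      cons[s, ] <- pred + pr + sgn * mod$residual_sd * z[s, ]
    }
    cons
  }
  aux1 <- draw_aux(n, registry, covars, 1, retest = retest)
  aux2 <- draw_aux(n, registry, covars, 2, prev = aux1, retest = retest)
  t1 <- assemble_inputs(to_raw(z1, 1), aux1, registry)
  t2 <- assemble_inputs(to_raw(z2, 2), aux2, registry)

  retained <- runif(n) < config$attrition
  t2[, !retained] <- NA_real_
  fu_years <- ifelse(retained,
                     pmax(rnorm(n, config$followup_years[1],
                                config$followup_years[2]), 1), NA_real_)
  if (config$clc_available < 1) {
    drop_clc <- runif(n) >= config$clc_available
    mri[drop_clc, "cortical_lesion_count"] <- NA_real_
  }
  subjects <- data.frame(subject_id = ids, group_truth = groups, demo,
                         followup = retained, followup_years = fu_years,
                         stringsAsFactors = FALSE)
  subjects[, MRI_MEASURES] <- mri
  CognitiveCohort(t1, t2, subjects, registry = registry)
}

#' One-call cohort simulation
#'
#' Generates controls, fits timepoint-1 norms on them, and generates the
#' patient cohort against those norms.
#'
#' @param config A [cohortConfig()].
#' @return List with elements `controls`, `patients` (both
#'   [CognitiveCohort-class], composites derived) and `norms`.
#' @export
#' @examples
#' sim <- simulateCohort(cohortConfig(n_controls = 40, n_patients = 60,
#'                                    seed = 11))
#' sim$patients
simulateCohort <- function(config) {
  controls <- deriveComposites(generateControls(config))
  norms <- fitNorms(controls, timepoint = 1)
  patients <- deriveComposites(generatePatients(config, norms))
  list(controls = controls, patients = patients, norms = norms)
}

# seed the RNG for the calling frame; the caller's stream is restored on exit
local_seed <- function(seed, envir = parent.frame()) {
  withr::local_seed(seed, .local_envir = envir)
}
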