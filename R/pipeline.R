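#' End-to-end pipeline configuration
#'
#' Houses the analysis constants (impairment boundary Z < -1.5,
#' reliable-change criterion |RCI| >= 1.64) and the switches for the
#' ambiguous methodological choices, each documented at the stage that
#' consumes it.
#'
#' @param cohort A [cohortConfig()] for simulation, or `NULL` when
#'   `paths` point at input CSVs.
#' @param paths Named list `scores`, `subjects`, optionally `mri` and
#'   `controls_scores`/`controls_subjects` for a measured cohort.
#' @param impairment_threshold Domain-Z impairment boundary.
#' @param rci_threshold Reliable-change criterion.
#' @param sed_estimator `"jacobson_truax"` or `"sd_of_differences"`.
#' @param rci_gated Gate count-based decline/improve labels on a reliable
#'   domain change?
#' @param multidomain_all_decline Count every multi-domain-to-multi-domain
#'   subject as declining in the transition table?
#' @param entry_alpha Forward-selection entry threshold.
#' @param multiplicity `"bonferroni"` or `"none"` for the univariate
#'   screen.
#' @param seed Integer seed for all pipeline randomness.
#' @return List of class `"pipeline_config"`.
#' @export
pipelineConfig <- function(cohort = cohortConfig(),
                           paths = NULL,
                           impairment_threshold = -1.5,
                           rci_threshold = 1.64,
                           sed_estimator = "jacobson_truax",
                           rci_gated = FALSE,
                           multidomain_all_decline = FALSE,
                           entry_alpha = 0.05,
                           multiplicity = "bonferroni",
                           seed = 1L) {
  stopifnot(is.finite(impairment_threshold), is.finite(rci_threshold))
  if (!is.null(paths)) {
    for (p in unlist(paths)) {
      if (!file.exists(p)) stop("input file does not exist: ", p)
    }
  }
  if (!is.null(cohort)) cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, paths = paths,
                 impairment_threshold = impairment_threshold,
                 rci_threshold = rci_threshold,
                 sed_estimator = sed_estimator, rci_gated = rci_gated,
                 multidomain_all_decline = multidomain_all_decline,
                 entry_alpha = entry_alpha, multiplicity = multiplicity,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full cognitive-phenotyping pipeline
#'
#' Executes simulate/ingest, composite derivation, normative fitting,
#' Z-scoring, phenotype classification at both timepoints, domain-level
#' reliable change, trajectory classification, the transition
#' cross-tabulation, the frequency report, per-domain MRI forward
#' regressions within the matching isolated group, and the
#' decline-vs-stable logistic model.  Any stage error halts the run with
#' the stage name.  All outputs (CSV/JSON), the resolved configuration
#' (YAML, with its MD5 hash in every file name-stamped log line) and a
#' run log are written under `out_dir`.
#'
#' @param config A [pipelineConfig()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return Invisibly, a list with all stage results.
#' @export
#' @examples
#' cfg <- pipelineConfig(cohort = cohortConfig(n_controls = 40,
#'                                             n_patients = 80, seed = 3))
#' res <- runPipeline(cfg, out_dir = NULL)
#' res$frequencies$isolated_share_of_impaired_pct
runPipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  cfg_yaml <- yaml::as.yaml(strip_functions(unclass(config)))
  tf <- tempfile(); writeLines(cfg_yaml, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)
  logmsg("run start, seed = ", config$seed, ", config hash = ", cfg_hash)

  data <- run_stage("ingest", {
    if (!is.null(config$paths)) {
      patients <- deriveComposites(readCohort(config$paths$scores,
                                              config$paths$subjects,
                                              config$paths$mri))
      controls <- deriveComposites(readCohort(config$paths$controls_scores,
                                              config$paths$controls_subjects))
      list(controls = controls, patients = patients)
    } else {
      cc <- deriveComposites(generateControls(config$cohort))
      list(controls = cc, patients = NULL)
    }
  })
  norms1 <- run_stage("norms", fitNorms(data$controls, timepoint = 1))
  norms2 <- run_stage("norms", fitNorms(data$controls, timepoint = 2))
  if (is.null(data$patients)) {
    data$patients <- run_stage("simulate",
      deriveComposites(generatePatients(config$cohort, norms1)))
  }
  logmsg("cohort: ", ncol(data$patients), " patients, ",
         ncol(data$controls), " controls")

  z1 <- run_stage("score", scoreZ(data$patients, norms1, timepoint = 1))
  z2 <- run_stage("score", scoreZ(data$patients, norms1, timepoint = 2))

  thr <- config$impairment_threshold
  prof1 <- run_stage("phenotype",
    classifyPhenotypes(composeDomains(z1, threshold = thr), z = z1))
  fu_ids <- colnames(z2)[colSums(is.finite(z2)) > 0]
  prof2 <- run_stage("phenotype", {
    p <- classifyPhenotypes(composeDomains(z2[, fu_ids, drop = FALSE],
                                           threshold = thr),
                            z = z2[, fu_ids, drop = FALSE])
    p
  })
  freq <- run_stage("phenotype", phenotypeFrequencies(prof1))
  logmsg("baseline phenotypes: ",
         paste(freq$categories$category, freq$categories$n,
               sep = "=", collapse = ", "))

  rci <- run_stage("rci", {
    # domain-level RCI: each timepoint scored against its own-timepoint
    # norms; the numerator subtracts the residual HC mean change
    hz1 <- scoreZ(data$controls, norms1, timepoint = 1)
    hz2 <- scoreZ(data$controls, norms2, timepoint = 2)
    pz2 <- scoreZ(data$patients, norms2, timepoint = 2)
    d1 <- domain_matrix(composeDomains(z1, threshold = thr))
    d2 <- domain_matrix(composeDomains(pz2, threshold = thr))
    h1 <- domain_matrix(composeDomains(hz1, threshold = thr))
    h2 <- domain_matrix(composeDomains(hz2, threshold = thr))
    computeRCI(d1[, fu_ids, drop = FALSE], d2[, fu_ids, drop = FALSE],
               h1, h2, estimator = config$sed_estimator,
               threshold = config$rci_threshold, level = "domain")
  })

  traj <- run_stage("transitions",
    classifyTrajectories(prof1, prof2, rci = rci,
                         rci_gated = config$rci_gated,
                         rci_threshold = config$rci_threshold))
  ttab <- run_stage("transitions",
    buildTransitionTable(traj,
      multidomain_all_decline = config$multidomain_all_decline))
  logmsg("followed up: ", nrow(traj), " (",
         attr(traj, "n_no_followup"), " lost)")

  mri_reports <- run_stage("mri-model", {
    si <- subjectInfo(data$patients)
    mri <- as.data.frame(mriMeasures(data$patients))
    prep <- preparePredictors(mri)
    reports <- list()
    for (d in COGNITIVE_DOMAINS) {
      dz <- domain_matrix(prof1)[d, si$subject_id]
      screen <- univariatePreselect(dz, prep$values,
                                    si[, c("age", "sex", "education")],
                                    multiplicity = config$multiplicity)
      cands <- screen$candidate[screen$kept]
      iso <- prof1$subject_id[prof1$category6 == paste0("isolated_", d) &
                                !is.na(prof1$category6)]
      rep_d <- if (length(cands) && length(iso) > 5) {
        forwardRegression(dz[iso], prep$values[si$subject_id %in% iso,
                                               cands, drop = FALSE],
                          entry_alpha = config$entry_alpha)
      } else NULL
      reports[[d]] <- list(screen = screen, predictor_set = prep,
                           model = rep_d, n_isolated = length(iso))
    }
    reports
  })

  logistic <- run_stage("mri-model", {
    si <- subjectInfo(data$patients)
    iso <- prof1$subject_id[prof1$category == "isolated" &
                              !is.na(prof1$category)]
    tt <- traj[traj$subject_id %in% iso &
                 traj$change %in% c("declining", "stable"), ]
    feats <- si[match(tt$subject_id, si$subject_id),
                c("age", "sex", "edss", "cortical_gmv", "thalamus_volume",
                  "hippocampus_volume", "fa")]
    feats$sex <- as.numeric(feats$sex == "male")
    if (length(unique(tt$change)) == 2 && nrow(tt) >= 30) {
      declineLogistic(feats, factor(tt$change,
                                    levels = c("stable", "declining")))
    } else NULL
  })

  results <- list(config = config, config_hash = cfg_hash,
                  controls = data$controls, patients = data$patients,
                  norms_t1 = norms1, norms_t2 = norms2,
                  z_baseline = z1, z_followup = z2,
                  phenotypes_baseline = prof1, phenotypes_followup = prof2,
                  frequencies = freq, rci = rci, trajectories = traj,
                  transition_table = ttab, mri_models = mri_reports,
                  decline_logistic = logistic)
  if (!is.null(out_dir)) {
    run_stage("write", write_outputs(results, out_dir, cfg_yaml, cfg_hash,
                                     logmsg))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  invisible(results)
}

# domain x subject matrix from a profile table
domain_matrix <- function(profiles) {
  m <- t(as.matrix(profiles[, COGNITIVE_DOMAINS]))
  colnames(m) <- profiles$subject_id
  m
}

strip_functions <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_functions)
    x[!vapply(x, is.null, logical(1))]
  } else if (is.function(x)) NULL
  else if (is.matrix(x)) apply(x, 1, as.list, simplify = FALSE)
  else x
}

write_outputs <- function(results, out_dir, cfg_yaml, cfg_hash, logmsg) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(cfg_yaml, file.path(out_dir, "config.yaml"))
  writeCohort(results$patients, file.path(out_dir, "patients"))
  writeCohort(results$controls, file.path(out_dir, "controls"))
  writeNorms(results$norms_t1, file.path(out_dir, "norms_t1.json"))
  writeNorms(results$norms_t2, file.path(out_dir, "norms_t2.json"))
  zl <- function(z, tp) data.frame(subject_id = rep(colnames(z), each = nrow(z)),
                                   timepoint = tp,
                                   subscore = rep(rownames(z), ncol(z)),
                                   z = as.vector(z))
  write.csv(rbind(zl(results$z_baseline, 1), zl(results$z_followup, 2)),
            file.path(out_dir, "zscores.csv"), row.names = FALSE)
  write.csv(results$phenotypes_baseline,
            file.path(out_dir, "phenotypes_baseline.csv"), row.names = FALSE)
  write.csv(results$phenotypes_followup,
            file.path(out_dir, "phenotypes_followup.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(results$frequencies),
                       file.path(out_dir, "frequencies.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write.csv(results$rci, file.path(out_dir, "rci.csv"), row.names = FALSE)
  write.csv(results$trajectories, file.path(out_dir, "trajectories.csv"),
            row.names = FALSE)
  writeTransitionTable(results$transition_table,
                       csv = file.path(out_dir, "transition_table.csv"),
                       json = file.path(out_dir, "transition_table.json"))
  reg_json <- lapply(results$mri_models, function(r) {
    list(n_isolated = r$n_isolated,
         screen = r$screen,
         dropped_collinear = r$predictor_set$dropped,
         log_transformed = r$predictor_set$transform_log,
         model = if (is.null(r$model)) NULL else unclass(r$model)[
           c("selected", "std_beta", "coef_p", "F", "df", "p_model",
             "adj_r_squared", "n", "significant")])
  })
  jsonlite::write_json(reg_json, file.path(out_dir, "mri_models.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  if (!is.null(results$decline_logistic)) {
    jsonlite::write_json(unclass(results$decline_logistic),
                         file.path(out_dir, "decline_logistic.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  logmsg("outputs written to ", out_dir, " [config ", cfg_hash, "]")
  invisible(out_dir)
}
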