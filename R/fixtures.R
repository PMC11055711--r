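#' Worked-example transition counts from a long-standing MS cohort
#'
#' A baseline-by-follow-up phenotype cross-tabulation (counts transcribed
#' from the clinical literature on five-year cognitive follow-up in
#' multiple sclerosis; 240 followed-up patients), shipped as a plain-text
#' fixture.  Useful for exercising the trajectory accounting without any
#' simulation: 73 patients had isolated impairment at baseline, of whom
#' 26 declined, 32 remained stable and 15 improved under the count-based
#' rules.
#'
#' @return `data.frame` with columns `baseline`, `followup`
#'   ([PHENOTYPE_CATEGORIES]) and `count`.
#' @export
#' @examples
#' head(exampleTransitionCounts())
exampleTransitionCounts <- function() {
  read.csv(system.file("extdata", "example_transition_counts.csv",
                       package = "cogpheno", mustWork = TRUE),
           stringsAsFactors = FALSE)
}

#' Expand transition counts into per-subject phenotype tables
#'
#' Turns a `(baseline, followup, count)` table into the pair of
#' per-subject baseline/follow-up phenotype tables consumed by
#' [classifyTrajectories()], assigning the minimal impaired-domain count
#' per category (0 for preserved, 1 for isolated, 2 for multi-domain).
#'
#' @param counts `data.frame` as returned by [exampleTransitionCounts()].
#' @return List with elements `bl` and `fu`.
#' @export
#' @examples
#' traj <- do.call(classifyTrajectories, expandTransitionCounts(
#'   exampleTransitionCounts()))
#' table(traj$change)
expandTransitionCounts <- function(counts) {
  stopifnot(all(c("baseline", "followup", "count") %in% names(counts)))
  bad <- setdiff(unique(c(counts$baseline, counts$followup)),
                 PHENOTYPE_CATEGORIES)
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  bl_cat <- rep(counts$baseline, counts$count)
  fu_cat <- rep(counts$followup, counts$count)
  ids <- sprintf("S%04d", seq_along(bl_cat))
  n_imp <- function(cat6) {
    ifelse(cat6 == "preserved", 0L, ifelse(cat6 == "multidomain", 2L, 1L))
  }
  mk <- function(cat6) {
    data.frame(subject_id = ids, category6 = cat6,
               n_impaired = n_imp(cat6), stringsAsFactors = FALSE)
  }
  list(bl = mk(bl_cat), fu = mk(fu_cat))
}

#' Worked-example baseline phenotype labels
#'
#' A label table realizing published baseline frequencies in a cohort of
#' 348 patients: 92 preserved, 108 isolated (25 processing speed, 23
#' memory, 37 executive/working memory, 23 attention) and 148
#' multi-domain of whom 108 involve processing speed.  Used to exercise
#' the frequency arithmetic of [phenotypeFrequencies()] on known counts.
#'
#' @return `data.frame` in the format produced by [classifyPhenotypes()].
#' @export
#' @examples
#' phenotypeFrequencies(examplePhenotypeLabels())
examplePhenotypeLabels <- function() {
  iso_n <- c(isolated_ips = 25, isolated_memory = 23, isolated_efwm = 37,
             isolated_attention = 23)
  md_ips <- 108          # multi-domain subjects with processing speed hit
  md_other <- 148 - md_ips
  cat6 <- c(rep("preserved", 92),
            rep(names(iso_n), iso_n),
            rep("multidomain", 148))
  n <- length(cat6)
  flags <- matrix(FALSE, n, 4,
                  dimnames = list(NULL, paste0("impaired_",
                                               COGNITIVE_DOMAINS)))
  iso_rows <- grepl("^isolated_", cat6)
  flags[cbind(which(iso_rows),
              match(sub("^isolated_", "", cat6[iso_rows]),
                    COGNITIVE_DOMAINS))] <- TRUE
  md_rows <- which(cat6 == "multidomain")
  flags[md_rows[seq_len(md_ips)], c("impaired_ips", "impaired_memory")] <- TRUE
  flags[md_rows[md_ips + seq_len(md_other)],
        c("impaired_memory", "impaired_efwm")] <- TRUE
  out <- data.frame(subject_id = sprintf("P%04d", seq_len(n)),
                    flags,
                    n_impaired = as.integer(rowSums(flags)),
                    classifiable = TRUE,
                    category = ifelse(cat6 == "preserved", "preserved",
                                      ifelse(cat6 == "multidomain",
                                             "multidomain", "isolated")),
                    isolated_domain = ifelse(iso_rows,
                                             sub("^isolated_", "", cat6),
                                             NA_character_),
                    category6 = cat6, stringsAsFactors = FALSE)
  out
}
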