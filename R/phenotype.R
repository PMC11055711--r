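#' Compose the four cognitive domain scores
#'
#' Each domain score is the unweighted mean of its constituent sub-score
#' Z-scores (Table-style a-priori composition: IPS is the SDMT Z alone;
#' memory averages the four SRT sub-scores and the two SPART recalls;
#' EF/WM averages Stroop interference, CST shifting, WLG total and MCT
#' slope; attention averages Stroop cards 1 and 2 and the CST number and
#' letter conditions).  When some constituents are missing the mean is
#' taken over the present ones provided at least half are present;
#' otherwise the domain is missing and the subject is flagged
#' unclassifiable at that timepoint.
#'
#' @param z Z-score matrix from [scoreZ()] (sub-scores x subjects,
#'   oriented higher = better).
#' @param threshold Impairment boundary on the domain Z scale; a domain is
#'   impaired when Z is strictly below it (default -1.5; Z exactly at the
#'   boundary counts as preserved).
#' @param min_present Minimum fraction of a domain's constituents that
#'   must be non-missing (default 0.5).
#' @param registry Sub-score registry.
#' @return `data.frame` with one row per subject: `subject_id`, the four
#'   domain Z columns, `impaired_<domain>` flags, `n_impaired` and
#'   `classifiable`.
#' @export
#' @examples
#' sim <- simulateCohort(cohortConfig(n_controls = 40, n_patients = 30,
#'                                    seed = 9))
#' prof <- composeDomains(scoreZ(sim$patients, sim$norms))
#' head(prof)
composeDomains <- function(z, threshold = -1.5, min_present = 0.5,
                           registry = subscoreRegistry()) {
  stopifnot(is.matrix(z))
  out <- data.frame(subject_id = colnames(z), stringsAsFactors = FALSE)
  for (d in COGNITIVE_DOMAINS) {
    cs <- intersect(domainConstituents(d, registry), rownames(z))
    k <- length(domainConstituents(d, registry))
    if (!length(cs)) {
      out[[d]] <- NA_real_
      next
    }
    sub <- z[cs, , drop = FALSE]
    n_ok <- colSums(is.finite(sub))
    dz <- colSums(sub, na.rm = TRUE) / n_ok
    dz[n_ok < max(1, ceiling(min_present * k))] <- NA_real_
    out[[d]] <- unname(dz)
  }
  for (d in COGNITIVE_DOMAINS) {
    out[[paste0("impaired_", d)]] <- out[[d]] < threshold
  }
  flags <- out[, paste0("impaired_", COGNITIVE_DOMAINS)]
  out$n_impaired <- as.integer(rowSums(flags))
  out$classifiable <- stats::complete.cases(out[, COGNITIVE_DOMAINS])
  out
}

#' Classify subjects into cognitive phenotypes
#'
#' Applies the phenotype rules to domain profiles: `preserved` when no
#' domain is impaired, `isolated` when exactly one is (recording which),
#' `multidomain` when two or more are.  The impairment boundary is strict:
#' a domain Z exactly equal to the threshold is preserved.
#'
#' @param profiles Output of [composeDomains()].
#' @param z Optional Z-score matrix; when given, an EF/WM sub-profile
#'   (impaired executive facets: inhibition = Stroop interference,
#'   flexibility = CST shifting, fluency = WLG total, working memory =
#'   MCT slope) is reported.
#' @param on_missing `"error"` to fail on subjects with a missing domain,
#'   `"na"` (default) to label them `NA` with a warning.
#' @return `profiles` with columns `category`, `isolated_domain`,
#'   `category6` (one of [PHENOTYPE_CATEGORIES]) and optionally
#'   `efwm_subprofile` appended.
#' @export
classifyPhenotypes <- function(profiles, z = NULL,
                               on_missing = c("na", "error")) {
  on_missing <- match.arg(on_missing)
  bad <- !profiles$classifiable
  if (any(bad)) {
    msg <- paste0("subject(s) with missing domain score: ",
                  paste(profiles$subject_id[bad], collapse = ", "))
    if (on_missing == "error") stop("cannot classify ", msg)
    warning(msg, "; classified as NA")
  }
  n <- profiles$n_impaired
  category <- ifelse(n == 0, "preserved",
                     ifelse(n == 1, "isolated", "multidomain"))
  flags <- as.matrix(profiles[, paste0("impaired_", COGNITIVE_DOMAINS)])
  iso_idx <- apply(flags, 1, function(f) {
    w <- which(f)
    if (length(w) == 1) COGNITIVE_DOMAINS[w] else NA_character_
  })
  isolated_domain <- ifelse(category == "isolated", iso_idx, NA_character_)
  category[bad] <- NA_character_
  isolated_domain[bad] <- NA_character_
  profiles$category <- category
  profiles$isolated_domain <- isolated_domain
  profiles$category6 <- ifelse(category == "isolated",
                               paste0("isolated_", isolated_domain),
                               category)
  if (!is.null(z)) {
    facets <- c(inhibition = "stroop_interference",
                flexibility = "cst_shifting",
                fluency = "wlg_total",
                working_memory = "mct_slope")
    have <- facets[facets %in% rownames(z)]
    profiles$efwm_subprofile <- vapply(profiles$subject_id, function(id) {
      if (!id %in% colnames(z)) return(NA_character_)
      imp <- names(have)[z[have, id] < -1.5 & is.finite(z[have, id])]
      paste(imp, collapse = "+")
    }, character(1), USE.NAMES = FALSE)
  }
  profiles
}

#' Phenotype frequency report
#'
#' Counts and percentages per phenotype category, the isolated phenotypes
#' per domain, per-domain involvement among multi-domain subjects, and
#' the distribution of the number of impaired domains.
#'
#' @param labels Output of [classifyPhenotypes()].
#' @return A list of class `"phenotype_frequencies"` with components
#'   `n_total`, `n_classifiable`, `categories` (data.frame), `isolated`
#'   (data.frame), `isolated_share_of_impaired_pct`,
#'   `multidomain_involvement` (data.frame), `n_impaired_distribution`.
#' @export
#' @examples
#' sim <- simulateCohort(cohortConfig(n_controls = 40, n_patients = 120,
#'                                    seed = 9))
#' lab <- classifyPhenotypes(composeDomains(scoreZ(sim$patients, sim$norms)))
#' phenotypeFrequencies(lab)
phenotypeFrequencies <- function(labels) {
  if (!nrow(labels)) stop("empty phenotype collection")
  ok <- !is.na(labels$category)
  lab <- labels[ok, , drop = FALSE]
  if (!nrow(lab)) stop("no classifiable subjects")
  n_total <- nrow(lab)
  cat_n <- vapply(c("preserved", "isolated", "multidomain"),
                  function(k) sum(lab$category == k), numeric(1))
  n_impaired_subjects <- n_total - cat_n[["preserved"]]
  iso <- lab[lab$category == "isolated", , drop = FALSE]
  iso_n <- vapply(COGNITIVE_DOMAINS,
                  function(d) sum(iso$isolated_domain == d), numeric(1))
  md <- lab[lab$category == "multidomain", , drop = FALSE]
  md_n <- vapply(COGNITIVE_DOMAINS, function(d) {
    sum(md[[paste0("impaired_", d)]])
  }, numeric(1))
  ndist <- vapply(2:4, function(k) sum(md$n_impaired == k), numeric(1))
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(
    n_total = n_total,
    n_classifiable = n_total,
    n_unclassifiable = sum(!ok),
    categories = data.frame(
      category = names(cat_n), n = as.vector(cat_n),
      pct_of_total = pct(as.vector(cat_n), n_total)),
    n_impaired_subjects = n_impaired_subjects,
    impaired_pct_of_total = pct(n_impaired_subjects, n_total),
    isolated = data.frame(
      domain = COGNITIVE_DOMAINS, n = as.vector(iso_n),
      pct_of_isolated = pct(as.vector(iso_n), cat_n[["isolated"]])),
    isolated_share_of_impaired_pct = pct(cat_n[["isolated"]],
                                         n_impaired_subjects),
    multidomain_involvement = data.frame(
      domain = COGNITIVE_DOMAINS, n = as.vector(md_n),
      pct_of_multidomain = pct(as.vector(md_n), cat_n[["multidomain"]])),
    n_impaired_distribution = data.frame(
      n_domains = 2:4, n = as.vector(ndist))
  ), class = "phenotype_frequencies")
}

#' @export
print.phenotype_frequencies <- function(x, ...) {
  cat("Phenotype frequencies (", x$n_total, " classifiable subjects)\n",
      sep = "")
  df <- x$categories
  df$pct_of_total <- sprintf("%.1f%%", df$pct_of_total)
  print(df, row.names = FALSE)
  cat(sprintf("isolated share of impaired: %.1f%%\n",
              x$isolated_share_of_impaired_pct))
  invisible(x)
}

#' Half-up rounding
#'
#' The display convention for reported percentages (2.5 -> 3), as used by
#' [declineSummary()].
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
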