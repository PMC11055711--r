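#' Reliable change indices against healthy-control retest data
#'
#' For every score (row) the index is the practice-corrected change
#' divided by the standard error of the difference estimated from the
#' healthy controls:
#' `RCI = ((x2 - x1) - (mean(HC2) - mean(HC1))) / SEd`.
#' The default SEd is the Jacobson-Truax practice-corrected form
#' `sqrt(SEM1^2 + SEM2^2)` with `SEM_i = SD_i * sqrt(1 - r12)`; the
#' alternative `"sd_of_differences"` uses the SD of the controls' change
#' scores.  `|RCI| >= threshold` (default 1.64, boundary inclusive) marks
#' reliable change.
#'
#' @param x1,x2 Score matrices (scores x subjects) at timepoints 1 and 2,
#'   e.g. domain Z-scores or sub-score Z/raw matrices; rows must match.
#' @param hc1,hc2 Matching matrices for healthy controls (both timepoints
#'   required; pairs with missing values are dropped per score).
#' @param estimator `"jacobson_truax"` (default) or
#'   `"sd_of_differences"`.
#' @param threshold Reliable-change criterion (default 1.64).
#' @param level Free-text label stored with the results (e.g. `"domain"`).
#' @return `data.frame` with one row per subject x score: `subject_id`,
#'   `level`, `name`, `x1`, `x2`, `hc_mean_change`, `se_diff`, `rci`,
#'   `reliable`.
#' @export
#' @examples
#' hc1 <- matrix(rnorm(50), 1, dimnames = list("d", NULL))
#' hc2 <- hc1 * 0.5 + matrix(rnorm(50, sd = sqrt(0.75)), 1)
#' x1 <- matrix(0, 1, 2, dimnames = list("d", c("a", "b")))
#' x2 <- matrix(c(0, 2), 1, 2, dimnames = list("d", c("a", "b")))
#' computeRCI(x1, x2, hc1, hc2)
computeRCI <- function(x1, x2, hc1, hc2,
                       estimator = c("jacobson_truax", "sd_of_differences"),
                       threshold = 1.64, level = "score") {
  estimator <- match.arg(estimator)
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  hc1 <- as.matrix(hc1); hc2 <- as.matrix(hc2)
  stopifnot(identical(rownames(x1), rownames(x2)),
            identical(rownames(hc1), rownames(hc2)))
  miss <- setdiff(rownames(x1), rownames(hc1))
  if (length(miss)) {
    stop("no control retest data for score(s): ", paste(miss, collapse = ", "))
  }
  out <- vector("list", nrow(x1))
  for (i in seq_len(nrow(x1))) {
    nm <- rownames(x1)[i]
    h1 <- hc1[nm, ]; h2 <- hc2[nm, ]
    ok <- is.finite(h1) & is.finite(h2)
    if (sum(ok) < 20) {
      stop("fewer than 20 controls with both timepoints for '", nm, "'")
    }
    h1 <- h1[ok]; h2 <- h2[ok]
    mc <- mean(h2) - mean(h1)
    se <- if (estimator == "jacobson_truax") {
      r12 <- cor(h1, h2)
      sqrt(sd(h1)^2 * (1 - r12) + sd(h2)^2 * (1 - r12))
    } else {
      sd(h2 - h1)
    }
    if (!is.finite(se) || se <= 0) {
      stop("zero standard error of the difference for '", nm, "'")
    }
    rci <- ((x2[nm, ] - x1[nm, ]) - mc) / se
    out[[i]] <- data.frame(
      subject_id = colnames(x1), level = level, name = nm,
      x1 = x1[nm, ], x2 = x2[nm, ], hc_mean_change = mc, se_diff = se,
      rci = rci, reliable = is.finite(rci) & abs(rci) >= threshold,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Classify five-year cognitive trajectories
#'
#' Count-based rules on the number of impaired domains: *declining* when
#' a subject is impaired in more domains at follow-up than at baseline,
#' *stable* when the counts are equal (this includes switching the
#' isolated domain), and *improving* when moving from multi-domain to
#' isolated impairment or from isolated impairment to preserved (a jump
#' from multi-domain straight to preserved is also labelled improving).
#' A multi-domain subject whose impaired-domain count drops but stays
#' >= 2 remains in the multi-domain category and is labelled stable, with
#' a note.  With `rci_gated = TRUE` a decline/improve label additionally
#' requires a reliable change (|RCI| >= `rci_threshold`) in the matching
#' direction on at least one domain; otherwise the label is downgraded to
#' stable.
#'
#' @param bl,fu Baseline and follow-up phenotype tables from
#'   [classifyPhenotypes()] (columns `subject_id`, `category6`,
#'   `n_impaired`).  Subjects absent from `fu` are excluded and counted;
#'   a subject present at follow-up but not baseline is an error.
#' @param rci Optional domain-level RCI table from [computeRCI()], needed
#'   when `rci_gated = TRUE`.
#' @param rci_gated Logical; see above.
#' @param rci_threshold Reliable-change criterion (default 1.64).
#' @return `data.frame` with `subject_id`, `baseline_phenotype`,
#'   `followup_phenotype`, `n_impaired_bl`, `n_impaired_fu`, `change`,
#'   `note`; the number of subjects lost to follow-up is in
#'   `attr(, "n_no_followup")`.
#' @export
classifyTrajectories <- function(bl, fu, rci = NULL, rci_gated = FALSE,
                                 rci_threshold = 1.64) {
  orphan <- setdiff(fu$subject_id, bl$subject_id)
  if (length(orphan)) {
    stop("subject(s) present at follow-up but not baseline: ",
         paste(orphan, collapse = ", "))
  }
  followed <- intersect(bl$subject_id, fu$subject_id)
  n_lost <- length(setdiff(bl$subject_id, followed))
  b <- bl[match(followed, bl$subject_id), ]
  f <- fu[match(followed, fu$subject_id), ]
  ok <- !is.na(b$category6) & !is.na(f$category6)
  b <- b[ok, ]; f <- f[ok, ]
  n_bl <- b$n_impaired; n_fu <- f$n_impaired
  change <- rep("stable", nrow(b))
  note <- rep("", nrow(b))
  change[n_fu > n_bl] <- "declining"
  improved <- n_fu < n_bl
  to_improving <- improved &
    ((b$category6 == "multidomain" & startsWith(f$category6, "isolated")) |
     (startsWith(b$category6, "isolated") & f$category6 == "preserved") |
     (b$category6 == "multidomain" & f$category6 == "preserved"))
  change[to_improving] <- "improving"
  md_md_fewer <- improved & b$category6 == "multidomain" &
    f$category6 == "multidomain"
  note[md_md_fewer] <- "fewer impaired domains but still multi-domain"
  if (rci_gated) {
    if (is.null(rci)) stop("rci_gated = TRUE requires an RCI table")
    gate <- function(ids, dir) {
      vapply(ids, function(id) {
        v <- rci$rci[rci$subject_id == id & is.finite(rci$rci)]
        if (!length(v)) return(FALSE)
        if (dir < 0) min(v) <= -rci_threshold else max(v) >= rci_threshold
      }, logical(1))
    }
    dec <- change == "declining"
    change[dec][!gate(b$subject_id[dec], -1)] <- "stable"
    imp <- change == "improving"
    change[imp][!gate(b$subject_id[imp], +1)] <- "stable"
  }
  out <- data.frame(subject_id = b$subject_id,
                    baseline_phenotype = b$category6,
                    followup_phenotype = f$category6,
                    n_impaired_bl = n_bl, n_impaired_fu = n_fu,
                    change = change, note = note,
                    stringsAsFactors = FALSE)
  attr(out, "n_no_followup") <- n_lost
  out
}

#' TransitionTable: baseline-by-follow-up phenotype cross-tabulation
#'
#' @slot counts 6 x 6 integer matrix of subjects per (baseline,
#'   follow-up) phenotype pair, in [PHENOTYPE_CATEGORIES] order.
#' @slot decline,stable,improve Named per-baseline-row counts.
#' @slot decline_pct Exact per-row decline percentages.
#' @slot n_followed Number of followed-up subjects.
#' @aliases TransitionTable-class
#' @export
setClass("TransitionTable",
         representation(counts = "matrix", decline = "numeric",
                        stable = "numeric", improve = "numeric",
                        decline_pct = "numeric", n_followed = "numeric"))

setValidity("TransitionTable", function(object) {
  msgs <- character()
  if (!identical(dim(object@counts), c(6L, 6L))) {
    msgs <- c(msgs, "counts must be 6 x 6")
  }
  if (any(object@counts < 0)) msgs <- c(msgs, "counts must be non-negative")
  if (sum(object@counts) != object@n_followed) {
    msgs <- c(msgs, "cell counts must sum to the followed-up total")
  }
  if (length(msgs)) msgs else TRUE
})

#' Build the transition cross-tabulation
#'
#' Tabulates baseline-by-follow-up phenotype categories with per-row
#' decline/stable/improve accounting.  With
#' `multidomain_all_decline = TRUE` every multi-domain-to-multi-domain
#' subject is counted in the decline column (the published-table
#' footnote convention); by default only count-based decliners are.
#'
#' @param trajectories Output of [classifyTrajectories()].
#' @param multidomain_all_decline Logical, see above.
#' @return A [TransitionTable-class].
#' @export
buildTransitionTable <- function(trajectories,
                                 multidomain_all_decline = FALSE) {
  if (!nrow(trajectories)) stop("empty trajectory collection")
  lev <- PHENOTYPE_CATEGORIES
  counts <- table(factor(trajectories$baseline_phenotype, levels = lev),
                  factor(trajectories$followup_phenotype, levels = lev))
  counts <- matrix(as.integer(counts), 6, 6, dimnames = list(lev, lev))
  change <- trajectories$change
  if (multidomain_all_decline) {
    md <- trajectories$baseline_phenotype == "multidomain" &
      trajectories$followup_phenotype == "multidomain"
    change[md] <- "declining"
  }
  per_row <- function(what) {
    vapply(lev, function(g) {
      sum(trajectories$baseline_phenotype == g & change == what)
    }, numeric(1))
  }
  decline <- per_row("declining")
  stable <- per_row("stable")
  improve <- per_row("improving")
  row_tot <- rowSums(counts)
  pct <- ifelse(row_tot > 0, 100 * decline / row_tot, NA_real_)
  new("TransitionTable", counts = counts, decline = decline,
      stable = stable, improve = improve, decline_pct = pct,
      n_followed = nrow(trajectories))
}

#' @describeIn TransitionTable-class cell counts.
#' @param x A `TransitionTable`.
#' @export
transitionCounts <- function(x) x@counts

#' @describeIn TransitionTable-class per-baseline-row decline counts and
#'   percentages (exact and half-up rounded to whole percent).
#' @export
declineSummary <- function(x) {
  data.frame(baseline = rownames(x@counts), n = rowSums(x@counts),
             decline = x@decline, stable = x@stable, improve = x@improve,
             decline_pct = x@decline_pct,
             decline_pct_display = round_half_up(x@decline_pct),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @describeIn TransitionTable-class plain-data export.
#' @export
as.data.frame.TransitionTable <- function(x, ...) {
  as.data.frame(as.table(x@counts), stringsAsFactors = FALSE) |>
    stats::setNames(c("baseline", "followup", "n"))
}

setMethod("show", "TransitionTable", function(object) {
  cat("TransitionTable:", object@n_followed, "followed-up subjects\n")
  print(object@counts)
  cat("\nPer-row decline:\n")
  print(declineSummary(object), row.names = FALSE)
})

#' Write a transition table as CSV and JSON
#'
#' @param x A [TransitionTable-class].
#' @param csv,json Output paths (either may be `NULL` to skip).
#' @return Invisibly, the list of written paths.
#' @export
writeTransitionTable <- function(x, csv = NULL, json = NULL) {
  if (!is.null(csv)) write.csv(as.data.frame(x), csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(list(counts = x@counts,
                              decline = as.list(x@decline),
                              decline_pct = as.list(x@decline_pct),
                              n_followed = x@n_followed),
                         json, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(csv = csv, json = json))
}
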