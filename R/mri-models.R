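#' Normality gate with log-transform fallback
#'
#' Lilliefors-corrected Kolmogorov-Smirnov test of composite normality;
#' when rejected at `alpha` the values are natural-log transformed
#' (shifted above zero first when necessary, with a warning).
#'
#' @param values Numeric vector (>= 20 finite values).
#' @param alpha Rejection level (default 0.05).
#' @return List with `values` (possibly transformed), `transformed`,
#'   `p_value`, `statistic`, `shift` (0 when none was needed).
#' @export
#' @examples
#' normalityGate(rlnorm(200))$transformed
normalityGate <- function(values, alpha = 0.05) {
  v <- values[is.finite(values)]
  if (length(v) < 20) stop("need at least 20 finite values")
  if (sd(v) < 1e-12) stop("constant vector: normality is undefined")
  ks <- nortest::lillie.test(v)
  transformed <- ks$p.value < alpha
  shift <- 0
  out <- values
  if (transformed) {
    if (min(v) <= 0) {
      shift <- -min(v) + 1e-6 * max(abs(v), 1)
      warning("non-positive values shifted by ", signif(shift, 4),
              " before log transform")
    }
    out <- log(values + shift)
  }
  list(values = out, transformed = transformed, p_value = ks$p.value,
       statistic = unname(ks$statistic), shift = shift)
}

#' Iterative collinearity screen on Pearson correlations
#'
#' While any candidate pair has `|r| >=` the cutoff, the candidate with
#' the most such partners is dropped (ties broken by larger mean absolute
#' correlation, then by name), and the screen repeats on the survivors.
#'
#' @param predictors Numeric matrix or data.frame of candidates
#'   (pairwise-complete correlations).
#' @param cutoff Absolute-correlation threshold (default 0.7).
#' @return List of class `"predictor_set"`: `surviving`, `dropped`
#'   (ordered data.frame with the correlation evidence), `cutoff`,
#'   `transform_log` (filled by [preparePredictors()]).
#' @export
#' @examples
#' x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' collinearityScreen(cbind(x, d = x[, "a"] + rnorm(100, sd = 0.1)))
collinearityScreen <- function(predictors, cutoff = 0.7) {
  X <- as.matrix(predictors)
  if (ncol(X) < 2) {
    return(structure(list(surviving = colnames(X),
                          dropped = dropped_frame(), cutoff = cutoff,
                          transform_log = character(0)),
                     class = "predictor_set"))
  }
  surviving <- colnames(X)
  dropped <- dropped_frame()
  repeat {
    R <- abs(cor(X[, surviving, drop = FALSE],
                 use = "pairwise.complete.obs"))
    diag(R) <- 0
    if (all(R < cutoff, na.rm = TRUE) || length(surviving) < 2) break
    partners <- rowSums(R >= cutoff, na.rm = TRUE)
    meanr <- rowMeans(R, na.rm = TRUE)
    ord <- order(-partners, -meanr, names(partners))
    victim <- names(partners)[ord][1]
    dropped <- rbind(dropped, data.frame(
      name = victim, n_partners = partners[[victim]],
      mean_abs_r = meanr[[victim]], max_abs_r = max(R[victim, ]),
      stringsAsFactors = FALSE))
    surviving <- setdiff(surviving, victim)
  }
  structure(list(surviving = surviving, dropped = dropped, cutoff = cutoff,
                 transform_log = character(0)),
            class = "predictor_set")
}

dropped_frame <- function() {
  data.frame(name = character(0), n_partners = numeric(0),
             mean_abs_r = numeric(0), max_abs_r = numeric(0),
             stringsAsFactors = FALSE)
}

#' Normality-gate then collinearity-screen a candidate matrix
#'
#' @param predictors Candidate matrix/data.frame.
#' @param cutoff Collinearity cutoff (default 0.7).
#' @param alpha Normality-test level (default 0.05).
#' @param log_gate Apply [normalityGate()] per column first?
#' @return A `"predictor_set"` as in [collinearityScreen()], with
#'   `values` (the possibly-transformed surviving matrix) and
#'   `transform_log` (names of log-transformed candidates, with the
#'   trigger statistic in `gate_evidence`).
#' @export
preparePredictors <- function(predictors, cutoff = 0.7, alpha = 0.05,
                              log_gate = TRUE) {
  X <- as.matrix(predictors)
  gates <- list()
  if (log_gate) {
    for (j in colnames(X)) {
      g <- normalityGate(X[, j], alpha = alpha)
      if (g$transformed) {
        X[, j] <- g$values
        gates[[j]] <- c(statistic = g$statistic, p_value = g$p_value,
                        shift = g$shift)
      }
    }
  }
  ps <- collinearityScreen(X, cutoff = cutoff)
  ps$transform_log <- names(gates)
  ps$gate_evidence <- gates
  ps$values <- X[, ps$surviving, drop = FALSE]
  ps
}

# standardized coefficient(s): b * sd(x) / sd(y)
std_beta <- function(fit, data, terms, outcome) {
  vapply(terms, function(t) {
    unname(coef(fit)[t]) * sd(data[[t]]) / sd(data[[outcome]])
  }, numeric(1))
}

#' Covariate-adjusted univariate preselection of MRI candidates
#'
#' For each candidate measure, fits `domain_z ~ candidate + age + sex +
#' education` on complete cases and reports the candidate's standardized
#' beta and p-value; candidates pass the screen when the (optionally
#' Bonferroni-corrected, per analysis family) p is at or below `alpha`.
#'
#' @param domain_z Outcome vector (one domain's Z-scores).
#' @param candidates Named matrix/data.frame of candidate measures.
#' @param covariates `data.frame` with `age`, `sex` (or numeric
#'   `sex_male`) and `education`.
#' @param alpha Significance level (default 0.05).
#' @param multiplicity `"bonferroni"` (over the candidates of this
#'   family, the default) or `"none"`.
#' @param min_n Minimum complete cases (default 30).
#' @return `data.frame`: candidate, n, std_beta, p, p_adj, kept.
#' @export
univariatePreselect <- function(domain_z, candidates, covariates,
                                alpha = 0.05,
                                multiplicity = c("bonferroni", "none"),
                                min_n = 30) {
  multiplicity <- match.arg(multiplicity)
  X <- as.data.frame(candidates)
  cov <- normalize_covariates(covariates)
  rows <- lapply(names(X), function(cand) {
    dat <- data.frame(y = domain_z, x = X[[cand]], cov)
    dat <- dat[complete.cases(dat), ]
    if (nrow(dat) < min_n) {
      stop("fewer than ", min_n, " complete cases for candidate '",
           cand, "'")
    }
    fit <- lm(y ~ x + age + sex_male + education, data = dat)
    if (anyNA(coef(fit))) {
      bad <- names(coef(fit))[is.na(coef(fit))]
      stop("rank-deficient fit for candidate '", cand,
           "'; collinear column(s): ", paste(bad, collapse = ", "))
    }
    sm <- summary(fit)$coefficients
    data.frame(candidate = cand, n = nrow(dat),
               std_beta = std_beta(fit, dat, "x", "y"),
               p = sm["x", "Pr(>|t|)"], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (multiplicity == "bonferroni") {
    pmin(1, out$p * nrow(out))
  } else out$p
  out$kept <- out$p_adj <= alpha
  rownames(out) <- NULL
  out
}

normalize_covariates <- function(covariates) {
  cov <- as.data.frame(covariates)
  if (!"sex_male" %in% names(cov)) {
    if (!"sex" %in% names(cov)) stop("covariates need sex or sex_male")
    cov$sex_male <- as.numeric(cov$sex == "male")
  }
  data.frame(age = as.numeric(cov$age), sex_male = cov$sex_male,
             education = as.numeric(cov$education))
}

#' Forward stepwise regression with an F-change entry criterion
#'
#' Standard forward selection: starting from the intercept-only model,
#' the remaining candidate with the smallest F-change p-value is added
#' while that p-value is below `entry_alpha`; selection stops otherwise.
#' Fitting is on the complete cases of the outcome and all candidates
#' (listwise deletion).  A model selecting no predictor is reported as
#' non-significant.
#'
#' @param y Outcome vector (e.g. one domain's Z-scores, typically within
#'   the matching isolated-phenotype group).
#' @param candidates Screened candidate matrix/data.frame (e.g.
#'   `$values` of [preparePredictors()]).
#' @param entry_alpha Entry threshold on the F-change p (default 0.05).
#' @return List of class `"regression_report"`: `selected`, `std_beta`,
#'   `coef_p`, `F`, `df`, `p_model`, `r_squared`, `adj_r_squared`, `n`,
#'   `steps` (per-step entry evidence).
#' @export
#' @examples
#' x <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- 0.7 * x[, "a"] + rnorm(200, sd = 0.5)
#' forwardRegression(y, x)$selected
forwardRegression <- function(y, candidates, entry_alpha = 0.05) {
  X <- as.data.frame(candidates)
  dat <- data.frame(y = y, X)
  dat <- dat[complete.cases(dat), ]
  n <- nrow(dat)
  if (n < 3) stop("too few complete cases (n = ", n, ")")
  remaining <- names(X)
  selected <- character(0)
  steps <- list()
  repeat {
    if (!length(remaining)) break
    base_formula <- if (length(selected)) {
      stats::reformulate(selected, "y")
    } else y ~ 1
    base_fit <- lm(base_formula, data = dat)
    ps <- vapply(remaining, function(cand) {
      fit <- lm(stats::reformulate(c(selected, cand), "y"), data = dat)
      a <- anova(base_fit, fit)
      a[["Pr(>F)"]][2]
    }, numeric(1))
    best <- names(ps)[which.min(ps)]
    if (!is.finite(ps[best]) || ps[best] >= entry_alpha) break
    steps[[length(steps) + 1]] <- data.frame(
      step = length(selected) + 1, entered = best,
      f_change_p = ps[[best]], stringsAsFactors = FALSE)
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    if (n <= length(selected) + 2) break   # guard residual df
  }
  if (!length(selected)) {
    return(structure(list(selected = character(0), std_beta = numeric(0),
                          coef_p = numeric(0), F = NA_real_,
                          df = c(NA_real_, NA_real_), p_model = NA_real_,
                          r_squared = 0, adj_r_squared = 0, n = n,
                          significant = FALSE,
                          steps = do.call(rbind, steps)),
                     class = "regression_report"))
  }
  fit <- lm(stats::reformulate(selected, "y"), data = dat)
  if (n <= length(selected) + 1) {
    stop("too few cases for the selected model (n = ", n, ", p = ",
         length(selected), ")")
  }
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(list(
    selected = selected,
    std_beta = std_beta(fit, dat, selected, "y"),
    coef_p = sm$coefficients[selected, "Pr(>|t|)"],
    F = unname(fstat["value"]),
    df = unname(fstat[c("numdf", "dendf")]),
    p_model = unname(pf(fstat["value"], fstat["numdf"], fstat["dendf"],
                        lower.tail = FALSE)),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    n = n, significant = TRUE,
    steps = do.call(rbind, steps)
  ), class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  if (!length(x$selected)) {
    cat("Forward regression: no predictor entered (non-significant model),",
        "n =", x$n, "\n")
    return(invisible(x))
  }
  cat(sprintf("Forward regression: F(%d,%d) = %.3f, p = %.4g, adj. R2 = %.3f (n = %d)\n",
              x$df[1], x$df[2], x$F, x$p_model, x$adj_r_squared, x$n))
  for (i in seq_along(x$selected)) {
    cat(sprintf("  %s: std. beta = %.3f, p = %.4g\n", x$selected[i],
                x$std_beta[i], x$coef_p[i]))
  }
  invisible(x)
}

#' Logistic regression of cognitive decline vs stability
#'
#' Maximum-likelihood logistic fit of a declining-vs-stable label on
#' baseline demographic and MRI features, reporting the model
#' likelihood-ratio chi-squared test, per-feature odds ratios with Wald
#' confidence intervals, and an explicit complete-separation flag.
#'
#' @param features `data.frame` of predictors (complete cases used).
#' @param labels Vector coercible to a two-level factor; the *second*
#'   level (alphabetically, e.g. `"declining"` after... supply a factor
#'   to control ordering) is modelled as the event.  A factor with
#'   levels `c("stable", "declining")` models decline.
#' @param conf_level Confidence level for the odds-ratio intervals.
#' @return List of class `"logistic_report"`: `lr_chisq`, `df`, `p`,
#'   `odds_ratios` (data.frame), `n`, `separation`.
#' @export
declineLogistic <- function(features, labels, conf_level = 0.95) {
  y <- if (is.factor(labels)) labels else factor(labels)
  if (nlevels(droplevels(y)) < 2) {
    stop("both outcome classes must be present; observed: ",
         paste(levels(droplevels(y)), collapse = ", "))
  }
  dat <- data.frame(.y = y, features)
  dat <- dat[complete.cases(dat), ]
  dat$.y <- droplevels(dat$.y)
  if (nrow(dat) < 30) stop("need at least 30 complete cases")
  if (nlevels(dat$.y) < 2) stop("both outcome classes must be present")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
          grepl("algorithm did not converge", msg)) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  separation <- sep_warn || any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)
  lr <- fit$null.deviance - fit$deviance
  df <- length(coef(fit)) - 1
  ci <- suppressMessages(confint.default(fit, level = conf_level))
  orr <- data.frame(feature = names(coef(fit))[-1],
                    odds_ratio = exp(coef(fit)[-1]),
                    ci_lower = exp(ci[-1, 1]), ci_upper = exp(ci[-1, 2]),
                    p = summary(fit)$coefficients[-1, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(lr_chisq = lr, df = df,
                 p = pchisq(lr, df, lower.tail = FALSE),
                 odds_ratios = orr, n = nrow(dat),
                 event_level = levels(dat$.y)[2],
                 separation = separation),
            class = "logistic_report")
}

#' @export
print.logistic_report <- function(x, ...) {
  cat(sprintf("Decline logistic model: Chi2(%d) = %.3f, p = %.4g (n = %d)\n",
              x$df, x$lr_chisq, x$p, x$n))
  if (x$separation) cat("  WARNING: complete or quasi-complete separation\n")
  print(x$odds_ratios, row.names = FALSE)
  invisible(x)
}

#' Group comparisons of demographic and MRI measures
#'
#' For each measure, routes to a general linear model (one-way ANOVA F)
#' when the pooled within-group residuals pass the Lilliefors normality
#' check, and to Kruskal-Wallis (or Mann-Whitney for two groups) with
#' Mann-Whitney pairwise follow-ups otherwise.  P-values are Bonferroni
#' adjusted over the measures; groups with fewer than two subjects are
#' excluded with a warning.
#'
#' @param data `data.frame` holding `group_col` and the measures.
#' @param measures Character vector of measure columns.
#' @param group_col Name of the grouping column.
#' @param alpha Flagging level on adjusted p (default 0.05).
#' @return List of class `"comparison_table"`: `table` (measure, test,
#'   statistic, p, p_adj, flagged), `pairwise` (per flagged non-normal
#'   measure, the Mann-Whitney p matrix).
#' @export
groupComparisons <- function(data, measures, group_col = "group",
                             alpha = 0.05) {
  g <- factor(data[[group_col]])
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("group(s) excluded (n < 2): ", paste(small, collapse = ", "))
    keep <- !(g %in% small)
    data <- data[keep, , drop = FALSE]
    g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2) stop("need at least two groups")
  rows <- list()
  pairwise <- list()
  for (m in measures) {
    v <- data[[m]]
    ok <- is.finite(v) & !is.na(g)
    vv <- v[ok]; gg <- droplevels(g[ok])
    if (nlevels(gg) < 2 || length(vv) < 8) next
    resid <- vv - ave(vv, gg)
    normal <- tryCatch(nortest::lillie.test(resid)$p.value >= 0.05,
                       error = function(e) FALSE)
    if (normal) {
      fit <- lm(vv ~ gg)
      a <- anova(fit)
      rows[[m]] <- data.frame(measure = m, test = "glm_f",
                              statistic = a[["F value"]][1],
                              p = a[["Pr(>F)"]][1], stringsAsFactors = FALSE)
    } else if (nlevels(gg) == 2) {
      w <- suppressWarnings(wilcox.test(vv ~ gg))
      rows[[m]] <- data.frame(measure = m, test = "mann_whitney",
                              statistic = unname(w$statistic),
                              p = w$p.value, stringsAsFactors = FALSE)
    } else {
      kw <- kruskal.test(vv, gg)
      rows[[m]] <- data.frame(measure = m, test = "kruskal_wallis",
                              statistic = unname(kw$statistic),
                              p = kw$p.value, stringsAsFactors = FALSE)
      pw <- suppressWarnings(
        stats::pairwise.wilcox.test(vv, gg, p.adjust.method = "bonferroni"))
      pairwise[[m]] <- pw$p.value
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$p_adj <- pmin(1, tab$p * nrow(tab))     # Bonferroni over measures
  tab$flagged <- tab$p_adj <= alpha
  structure(list(table = tab, pairwise = pairwise, alpha = alpha),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}
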