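test_that("normality gate passes Gaussians, transforms log-normals, rejects constants", {
  withr::local_seed(12)
  g <- normalityGate(rnorm(500))
  expect_false(g$transformed)
  expect_identical(g$shift, 0)
  # rejection power on clearly skewed data over repeated draws
  hits <- vapply(1:100, function(i) {
    normalityGate(rlnorm(500))$transformed
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # shifted log transform for non-positive values
  expect_warning(gs <- normalityGate(rlnorm(500) - 2), "shifted")
  expect_true(gs$transformed)
  expect_true(all(is.finite(gs$values)))
  expect_error(normalityGate(rep(3, 50)), "constant")
  expect_error(normalityGate(rnorm(10)), "20")
})

test_that("collinearity screen drops the most-connected predictor", {
  withr::local_seed(77)
  n <- 200
  a <- rnorm(n)
  b <- 0.95 * a + rnorm(n, sd = sqrt(1 - 0.95^2))   # r(a,b) ~ 0.95
  c_ <- 0.85 * a + rnorm(n, sd = sqrt(1 - 0.85^2))  # r(a,c) ~ 0.85
  ps <- collinearityScreen(cbind(a = a, b = b, c = c_))
  expect_equal(ps$dropped$name[1], "a")              # two strong partners
  expect_true(all(abs(cor(cbind(b, c_))[1, 2]) < 0.7) ==
                ("b" %in% ps$surviving && "c" %in% ps$surviving))
  # clean set untouched
  clean <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("x", "y", "z")))
  expect_equal(nrow(collinearityScreen(clean)$dropped), 0)
  expect_equal(collinearityScreen(clean)$surviving, c("x", "y", "z"))
  # three identical predictors: exactly one survives, no violating pair left
  ident <- cbind(p = a, q = a, r = a)
  ps3 <- collinearityScreen(ident)
  expect_equal(length(ps3$surviving), 1)
  expect_equal(nrow(ps3$dropped), 2)
})

test_that("surviving sets never contain a violating pair (property)", {
  withr::local_seed(303)
  for (i in 1:20) {
    p <- sample(3:7, 1)
    n <- 120
    L <- matrix(rnorm(p * p), p)
    X <- MASS::mvrnorm(n, rep(0, p), crossprod(L) + diag(p) * 0.1)
    colnames(X) <- letters[seq_len(p)]
    ps <- collinearityScreen(X)
    if (length(ps$surviving) >= 2) {
      R <- abs(cor(X[, ps$surviving]))
      diag(R) <- 0
      expect_lt(max(R), 0.7)
    }
  }
})

test_that("univariate preselection has calibrated size and unit limit", {
  withr::local_seed(555)
  cov <- data.frame(age = rnorm(1000, 47, 10),
                    sex_male = rbinom(1000, 1, 0.4),
                    education = sample(1:7, 1000, replace = TRUE))
  # null candidate: kept-rate ~ alpha over repeated draws (no correction)
  kept <- vapply(1:200, function(i) {
    y <- rnorm(1000)
    x <- rnorm(1000)
    univariatePreselect(y, data.frame(cand = x), cov,
                        multiplicity = "none")$kept
  }, logical(1))
  expect_lt(abs(mean(kept) - 0.05), 0.035)
  # candidate equal to the outcome up to scale
  y <- rnorm(1000)
  row <- suppressWarnings(
    univariatePreselect(y, data.frame(cand = 3 * y + 5), cov))
  expect_equal(row$std_beta, 1, tolerance = 1e-6)
  expect_lt(row$p, 1e-100)
  # rank deficiency is named
  expect_error(
    univariatePreselect(y, data.frame(cand = cov$age), cov),
    "rank-deficient|collinear")
  expect_error(
    univariatePreselect(y[1:10], data.frame(cand = rnorm(10)), cov[1:10, ]),
    "complete cases")
})

test_that("standardized betas are invariant to affine rescaling", {
  withr::local_seed(42)
  n <- 300
  x <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- 0.5 * x[, 1] - 0.3 * x[, 2] + rnorm(n)
  r1 <- forwardRegression(y, x, entry_alpha = 1)
  x2 <- x
  x2[, "a"] <- 100 + 7 * x2[, "a"]
  r2 <- forwardRegression(5 - 2 * y, x2, entry_alpha = 1)
  expect_equal(abs(r2$std_beta[r1$selected]), abs(r1$std_beta),
               tolerance = 1e-10)
  expect_equal(r2$adj_r_squared, r1$adj_r_squared, tolerance = 1e-10)
})

test_that("forward selection limits: threshold 1 gives the full model, 0 the empty one", {
  withr::local_seed(88)
  n <- 150
  X <- matrix(rnorm(4 * n), n, 4, dimnames = list(NULL, letters[1:4]))
  y <- 0.4 * X[, 1] + rnorm(n)
  full <- forwardRegression(y, X, entry_alpha = 1)
  expect_setequal(full$selected, letters[1:4])
  empty <- forwardRegression(y, X, entry_alpha = 0)
  expect_equal(empty$selected, character(0))
  expect_false(empty$significant)
  # near-duplicate of the outcome is picked first with high adj R2
  Xd <- cbind(X, dup = y + rnorm(n, sd = 0.1))
  r <- forwardRegression(y, Xd)
  expect_equal(r$selected[1], "dup")
  expect_gt(r$adj_r_squared, 0.9)
})

test_that("adjusted R-squared matches its closed form on every fit", {
  withr::local_seed(99)
  for (i in 1:10) {
    n <- sample(40:120, 1)
    p <- sample(1:4, 1)
    X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, letters[1:4]))
    y <- X[, seq_len(p), drop = FALSE] %*% runif(p, 0.2, 0.6) + rnorm(n)
    r <- forwardRegression(as.vector(y), X, entry_alpha = 1)
    k <- length(r$selected)
    expect_equal(r$adj_r_squared,
                 1 - (1 - r$r_squared) * (n - 1) / (n - k - 1),
                 tolerance = 1e-12)
  }
})

test_that("pure-noise candidates yield an empty model nearly always", {
  withr::local_seed(2468)
  empty <- vapply(1:200, function(i) {
    n <- 200
    y <- rnorm(n)
    X <- matrix(rnorm(5 * n), n, 5, dimnames = list(NULL, letters[1:5]))
    cov <- data.frame(age = rnorm(n, 47, 10), sex_male = rbinom(n, 1, 0.4),
                      education = sample(1:7, n, replace = TRUE))
    screen <- univariatePreselect(y, X, cov, multiplicity = "bonferroni")
    kept <- screen$candidate[screen$kept]
    if (!length(kept)) return(TRUE)
    length(forwardRegression(y, X[, kept, drop = FALSE])$selected) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.9)
})

test_that("known standardized MRI effects are recovered within 0.1", {
  # isolated-IPS group generated with cortical-GMV and FA slopes 0.5 / 0.4
  slopes <- list(ips = c(cortical_gmv = 0.5, fa = 0.4),
                 memory = numeric(0), efwm = numeric(0),
                 attention = numeric(0))
  cfg <- cohortConfig(
    n_controls = 300, n_patients = 500, seed = 91,
    group_mix = c(isolated_ips = 1, isolated_memory = 0, isolated_efwm = 0,
                  isolated_attention = 0, multidomain = 0, preserved = 0),
    mri_cog_slopes = slopes, clc_available = 1)
  sim <- simulateCohort(cfg)
  prof <- composeDomains(scoreZ(sim$patients, sim$norms))
  mri <- as.data.frame(mriMeasures(sim$patients))
  r <- forwardRegression(prof$ips, mri[, c("cortical_gmv", "fa")],
                         entry_alpha = 1)
  expect_lt(abs(r$std_beta[["cortical_gmv"]] - 0.5), 0.1)
  expect_lt(abs(r$std_beta[["fa"]] - 0.4), 0.1)
  # univariate sign contract: volumes relate positively to cognition
  si <- subjectInfo(sim$patients)
  row <- univariatePreselect(prof$ips, mri["cortical_gmv"],
                             si[, c("age", "sex", "education")])
  expect_gt(row$std_beta, 0)
})

test_that("decline logistic reports LR test, separation and class errors", {
  withr::local_seed(31415)
  # null: rejection rate ~ alpha over repeated fits
  rej <- vapply(1:200, function(i) {
    n <- 500
    f <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    y <- factor(sample(c("stable", "declining"), n, replace = TRUE),
                levels = c("stable", "declining"))
    declineLogistic(f, y)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.035)
  # strong effect: direction recovered as an odds ratio above 1
  n <- 300
  x <- rnorm(n)
  y <- factor(ifelse(runif(n) < plogis(2 * x), "declining", "stable"),
              levels = c("stable", "declining"))
  rep1 <- declineLogistic(data.frame(x = x), y)
  expect_gt(rep1$odds_ratios$odds_ratio[1], 1)
  expect_lt(rep1$p, 0.01)
  # one class absent
  expect_error(declineLogistic(data.frame(x = rnorm(40)),
                               factor(rep("stable", 40),
                                      levels = c("stable", "declining"))),
               "both outcome classes")
  # complete separation is reported, not hidden
  xs <- c(rnorm(20, -3), rnorm(20, 3))
  ys <- factor(rep(c("stable", "declining"), each = 20),
               levels = c("stable", "declining"))
  rsep <- declineLogistic(data.frame(x = xs), ys)
  expect_true(rsep$separation)
})

test_that("group comparisons route by normality and flag true shifts", {
  withr::local_seed(616)
  # one group shifted by 3 SD is flagged across repeated draws
  hits <- vapply(1:20, function(i) {
    d <- data.frame(group = rep(c("a", "b", "c"), each = 50),
                    m1 = c(rnorm(50), rnorm(50), rnorm(50, 3)),
                    m2 = rnorm(150))
    gc <- groupComparisons(d, c("m1", "m2"), group_col = "group")
    gc$table$flagged[gc$table$measure == "m1"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # non-normal data with two groups exercises the Mann-Whitney path
  d2 <- data.frame(group = rep(c("a", "b"), each = 60),
                   m = exp(rnorm(120)))
  gc2 <- groupComparisons(d2, "m", group_col = "group")
  expect_equal(gc2$table$test, "mann_whitney")
  # non-normal with three groups: Kruskal-Wallis plus pairwise follow-ups
  d3 <- data.frame(group = rep(c("a", "b", "c"), each = 60),
                   m = exp(rnorm(180)))
  gc3 <- groupComparisons(d3, "m", group_col = "group")
  expect_equal(gc3$table$test, "kruskal_wallis")
  expect_true("m" %in% names(gc3$pairwise))
  # undersized groups are excluded with a warning
  d4 <- rbind(d2, data.frame(group = "tiny", m = 1))
  expect_warning(groupComparisons(d4, "m", group_col = "group"),
                 "excluded")
})
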