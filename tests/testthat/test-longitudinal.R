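make_hc_pair <- function(n = 60, r = 0.5, sd1 = 1, sd2 = 1, seed = 404,
                         name = "d") {
  withr::local_seed(seed)
  h1 <- rnorm(n, sd = sd1)
  h2 <- r * (sd2 / sd1) * h1 + rnorm(n, sd = sd2 * sqrt(1 - r^2))
  list(h1 = matrix(h1, 1, dimnames = list(name, NULL)),
       h2 = matrix(h2, 1, dimnames = list(name, NULL)))
}

test_that("RCI follows the practice-corrected formula with 1.64 inclusive", {
  hc <- make_hc_pair()
  mc <- mean(hc$h2) - mean(hc$h1)
  r12 <- cor(hc$h1[1, ], hc$h2[1, ])
  se <- sqrt(sd(hc$h1[1, ])^2 * (1 - r12) + sd(hc$h2[1, ])^2 * (1 - r12))
  x1 <- matrix(0, 1, 3, dimnames = list("d", c("a", "b", "c")))
  x2 <- matrix(c(mc,                     # change equal to HC mean change
                 mc + 1.64 * se,         # exactly at the criterion
                 mc - 2.5 * se),         # clear decline
               1, 3, dimnames = list("d", c("a", "b", "c")))
  res <- computeRCI(x1, x2, hc$h1, hc$h2)
  expect_equal(res$rci, c(0, 1.64, -2.5), tolerance = 1e-10)
  expect_equal(res$reliable, c(FALSE, TRUE, TRUE))  # boundary inclusive
  expect_equal(res$hc_mean_change, rep(mc, 3))
  expect_equal(res$se_diff, rep(se, 3))
})

test_that("the Jacobson-Truax SEd has its closed form at r = 0.5", {
  # sqrt(2 * SD^2 * (1 - r)) = 1 when SD = 1, r = 0.5
  withr::local_seed(99)
  n <- 400
  h1 <- rnorm(n)
  h2 <- 0.5 * h1 + rnorm(n, sd = sqrt(0.75))
  # rescale the sample to the exact moments
  h1 <- (h1 - mean(h1)) / sd(h1)
  e <- residuals(lm(h2 ~ h1))
  h2 <- 0.5 * h1 + sqrt(0.75) * e / sd(e)
  hm <- matrix(h1, 1, dimnames = list("d", NULL))
  hm2 <- matrix(h2, 1, dimnames = list("d", NULL))
  x <- matrix(0, 1, 1, dimnames = list("d", "s"))
  res <- computeRCI(x, x, hm, hm2)
  expect_equal(res$se_diff, 1, tolerance = 1e-6)
  # the sd-of-differences estimator agrees at equal variances
  res2 <- computeRCI(x, x, hm, hm2, estimator = "sd_of_differences")
  expect_equal(res2$se_diff, 1, tolerance = 0.05)
})

test_that("RCI errors on insufficient or degenerate control data", {
  hc <- make_hc_pair(n = 10)
  x <- matrix(0, 1, 1, dimnames = list("d", "s"))
  expect_error(computeRCI(x, x, hc$h1, hc$h2), "20 controls")
  h <- matrix(rep(1, 30), 1, dimnames = list("d", NULL))
  expect_error(suppressWarnings(computeRCI(x, x, h, h)),
               "zero standard error|zero")
  expect_error(computeRCI(x, x, hc$h1[0, , drop = FALSE],
                          hc$h2[0, , drop = FALSE]), "no control")
})

test_that("null simulees show ~10% reliable change", {
  withr::local_seed(2024)
  n_hc <- 1000; n_pat <- 1000; r <- 0.6
  h1 <- rnorm(n_hc); h2 <- r * h1 + rnorm(n_hc, sd = sqrt(1 - r^2)) + 0.3
  p1 <- rnorm(n_pat); p2 <- r * p1 + rnorm(n_pat, sd = sqrt(1 - r^2)) + 0.3
  res <- computeRCI(matrix(p1, 1, dimnames = list("d", sprintf("p%d", 1:n_pat))),
                    matrix(p2, 1, dimnames = list("d", sprintf("p%d", 1:n_pat))),
                    matrix(h1, 1, dimnames = list("d", NULL)),
                    matrix(h2, 1, dimnames = list("d", NULL)))
  expect_lt(abs(mean(res$rci)), 0.1)
  rate <- mean(res$reliable)
  expect_lt(abs(rate - 2 * pnorm(-1.64)), 0.03)
})

test_that("trajectory rules label decline, stability and improvement", {
  bl <- rbind(
    data.frame(subject_id = "s1", category6 = "isolated_ips", n_impaired = 1L),
    data.frame(subject_id = "s2", category6 = "isolated_attention", n_impaired = 1L),
    data.frame(subject_id = "s3", category6 = "isolated_efwm", n_impaired = 1L),
    data.frame(subject_id = "s4", category6 = "multidomain", n_impaired = 3L),
    data.frame(subject_id = "s5", category6 = "multidomain", n_impaired = 2L),
    data.frame(subject_id = "s6", category6 = "preserved", n_impaired = 0L),
    data.frame(subject_id = "s7", category6 = "preserved", n_impaired = 0L))
  fu <- rbind(
    data.frame(subject_id = "s1", category6 = "multidomain", n_impaired = 2L),
    data.frame(subject_id = "s2", category6 = "isolated_memory", n_impaired = 1L),
    data.frame(subject_id = "s3", category6 = "preserved", n_impaired = 0L),
    data.frame(subject_id = "s4", category6 = "multidomain", n_impaired = 2L),
    data.frame(subject_id = "s5", category6 = "isolated_ips", n_impaired = 1L),
    data.frame(subject_id = "s6", category6 = "preserved", n_impaired = 0L))
  traj <- classifyTrajectories(bl, fu)
  expect_equal(attr(traj, "n_no_followup"), 1)   # s7 lost
  got <- setNames(traj$change, traj$subject_id)
  expect_equal(got[["s1"]], "declining")
  expect_equal(got[["s2"]], "stable")     # switched isolated domain
  expect_equal(got[["s3"]], "improving")  # isolated -> preserved
  expect_equal(got[["s4"]], "stable")     # fewer domains, still multidomain
  expect_match(traj$note[traj$subject_id == "s4"], "still multi-domain")
  expect_equal(got[["s5"]], "improving")  # multidomain -> isolated
  expect_equal(got[["s6"]], "stable")
  # exactly one label each; totals partition the followed-up set
  expect_equal(sum(table(traj$change)), 6)
  # follow-up-only subject is an error
  expect_error(classifyTrajectories(bl[1:2, ], fu), "not baseline")
})

test_that("RCI gating downgrades unconfirmed transitions", {
  bl <- data.frame(subject_id = c("s1", "s2"),
                   category6 = c("isolated_ips", "isolated_ips"),
                   n_impaired = c(1L, 1L))
  fu <- data.frame(subject_id = c("s1", "s2"),
                   category6 = c("multidomain", "multidomain"),
                   n_impaired = c(2L, 2L))
  rci <- data.frame(subject_id = c("s1", "s2"), level = "domain",
                    name = "ips", rci = c(-2.1, -0.4))
  traj <- classifyTrajectories(bl, fu, rci = rci, rci_gated = TRUE)
  expect_equal(traj$change, c("declining", "stable"))
})

test_that("the transition table reproduces prescribed counts cell-for-cell", {
  withr::local_seed(808)
  for (rep in 1:3) {
    target <- matrix(sample(0:9, 36, replace = TRUE), 6, 6,
                     dimnames = list(PHENOTYPE_CATEGORIES,
                                     PHENOTYPE_CATEGORIES))
    counts <- as.data.frame(as.table(target), stringsAsFactors = FALSE)
    names(counts) <- c("baseline", "followup", "count")
    tabs <- expandTransitionCounts(counts)
    ttab <- buildTransitionTable(do.call(classifyTrajectories, tabs))
    expect_equal(transitionCounts(ttab), target)
    expect_equal(sum(transitionCounts(ttab)), sum(target))
  }
})

test_that("per-row decline accounting matches the worked example", {
  tabs <- expandTransitionCounts(exampleTransitionCounts())
  traj <- classifyTrajectories(tabs$bl, tabs$fu)
  ttab <- buildTransitionTable(traj)
  ds <- declineSummary(ttab)
  iso <- ds[grepl("^isolated_", ds$baseline), ]
  expect_equal(sum(iso$decline), 26)
  expect_equal(sum(iso$improve), 15)
  expect_equal(sum(iso$stable), 32)
  expect_equal(sum(iso$n), 73)
  expect_equal(ds$decline_pct_display[ds$baseline == "isolated_ips"], 69)
  # multidomain-to-multidomain counted as declining under the footnote rule
  t4 <- declineSummary(buildTransitionTable(traj,
                                            multidomain_all_decline = TRUE))
  expect_equal(t4$decline[t4$baseline == "multidomain"], 80)
  # single-subject degenerate table
  one <- classifyTrajectories(
    data.frame(subject_id = "s", category6 = "preserved", n_impaired = 0L),
    data.frame(subject_id = "s", category6 = "preserved", n_impaired = 0L))
  tt1 <- buildTransitionTable(one)
  expect_equal(transitionCounts(tt1)["preserved", "preserved"], 1L)
  expect_equal(declineSummary(tt1)$decline_pct[6], 0)
  expect_error(buildTransitionTable(one[0, ]), "empty")
})
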