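test_that("composite derivation follows the battery definitions", {
  vals <- c(stroop_card1 = 40, stroop_card2 = 44, stroop_card3 = 80,
            mct_1letter = 9, mct_4letter = 15,
            wlg_animals = 22, wlg_professions = 18, wlg_m = 15,
            spart_t1 = 6, spart_t2 = 7, spart_t3 = 8,
            srt_lts = 50, srt_ltr = 44, srt_cltr = 38, srt_delayed = 8)
  co <- deriveComposites(tiny_cohort(vals))
  m <- rawScores(co, 1)[, 1]
  expect_equal(m[["stroop_interference"]], 38)   # 80 - mean(40, 44)
  expect_equal(m[["mct_slope"]], 6)
  expect_equal(m[["wlg_total"]], 55)
  expect_equal(m[["spart_direct"]], 7)
  expect_equal(m[["srt_average"]], 35)
})

test_that("missing constituents propagate to missing composites", {
  vals <- c(stroop_card1 = 40, stroop_card3 = 80,      # card2 absent
            srt_lts = 50, srt_ltr = 44, srt_cltr = 38) # delayed absent
  co <- deriveComposites(tiny_cohort(vals))
  m <- rawScores(co, 1)[, 1]
  expect_true(is.na(m[["stroop_interference"]]))
  expect_true(is.na(m[["srt_average"]]))
  expect_true(is.na(m[["mct_slope"]]))
})

test_that("norm fitting recovers generator slopes and flags degeneracy", {
  hc <- cached("hc500", deriveComposites(generateControls(
    cohortConfig(n_controls = 500, seed = 31))))
  norms <- fitNorms(hc, timepoint = 1)
  reg <- subscoreRegistry()
  for (s in c("sdmt", "srt_lts", "stroop_interference", "mct_slope")) {
    mod <- normModel(norms, s)
    expect_lt(abs(mod$coefficients[["age"]] - reg[s, "age_slope"]),
              3 * mod$se[["age"]])
    expect_lt(abs(mod$residual_sd - reg[s, "sd"]) / reg[s, "sd"], 0.15)
    expect_equal(mod$n_fit, 500)
  }
  # too few controls
  small <- deriveComposites(generateControls(
    cohortConfig(n_controls = 10, seed = 2)))
  expect_error(fitNorms(small), "sdmt.*20|20.*sdmt")
  # constant scores
  hc2 <- hc
  flat <- rawScores(hc2, 1)
  flat["sdmt", ] <- 50
  hc2 <- CognitiveCohort(flat, rawScores(hc2, 2), subjectInfo(hc2))
  expect_error(fitNorms(hc2), "constant|zero residual")
  # absent sub-score
  expect_error(fitNorms(hc, subscores = "sdmt_bogus"), "absent")
})

test_that("scoring is linear in residual-SD units and respects direction", {
  hc <- cached("hc500", deriveComposites(generateControls(
    cohortConfig(n_controls = 500, seed = 31))))
  norms <- fitNorms(hc)
  covars <- data.frame(age = 50, sex_male = 1, education = 4)
  mk_subject <- function(shifts) {
    reg <- subscoreRegistry()
    inputs <- reg$subscore[reg$input]
    t1 <- matrix(NA_real_, length(inputs), 1, dimnames = list(inputs, "S1"))
    # every constituent exactly at its predicted value, then shifted
    for (s in normedSubscores(norms)) {
      mod <- normModel(norms, s)
      val <- norm_pred <- mod$coefficients[["(Intercept)"]] +
        mod$coefficients[["age"]] * covars$age +
        mod$coefficients[["sex_male"]] * covars$sex_male +
        mod$coefficients[["education"]] * covars$education
      val <- val + (shifts[[s]] %||% 0)
      switch(s,
        spart_direct = { t1[c("spart_t1", "spart_t2", "spart_t3"), 1] <- val },
        wlg_total = { t1[c("wlg_animals", "wlg_professions", "wlg_m"), 1] <- val / 3 },
        stroop_interference = { t1["stroop_card3", 1] <- val +
          (t1["stroop_card1", 1] + t1["stroop_card2", 1]) / 2 },
        mct_slope = { t1["mct_1letter", 1] <- 9
                      t1["mct_4letter", 1] <- 9 + val },
        t1[s, 1] <- val)
    }
    deriveComposites(CognitiveCohort(t1, NULL, data.frame(
      subject_id = "S1", age = 50, sex = "male", education = 4,
      followup = FALSE)))
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  # observed == predicted -> z = 0 everywhere
  z0 <- scoreZ(mk_subject(list()), norms)
  expect_true(all(abs(z0[, 1]) < 1e-8))
  # +1.5 residual SDs on a higher-is-better score -> z = +1.5
  mod <- normModel(norms, "sdmt")
  z <- scoreZ(mk_subject(list(sdmt = 1.5 * mod$residual_sd)), norms)
  expect_equal(unname(z["sdmt", 1]), 1.5, tolerance = 1e-8)
  # timed score 10 s above prediction -> z = -10 / residual SD
  modi <- normModel(norms, "stroop_interference")
  zi <- scoreZ(mk_subject(list(stroop_interference = 10)), norms)
  expect_equal(unname(zi["stroop_interference", 1]), -10 / modi$residual_sd,
               tolerance = 1e-8)
})

test_that("controls score to mean 0, SD 1, with worse performance lower", {
  hc <- cached("hc500", deriveComposites(generateControls(
    cohortConfig(n_controls = 500, seed = 31))))
  norms <- fitNorms(hc)
  z <- scoreZ(hc, norms)
  expect_lt(max(abs(rowMeans(z))), 0.05)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 0.05)
  # orientation: a raw decrement on counts and a raw increment on times
  # both lower z
  raw <- rawScores(hc, 1)
  worse <- raw
  worse["sdmt", ] <- worse["sdmt", ] - 5
  worse["stroop_card1", ] <- worse["stroop_card1", ] + 5
  hc_w <- deriveComposites(CognitiveCohort(
    raw[subscoreRegistry()$subscore[subscoreRegistry()$input], ] |>
      (\(m) { m["sdmt", ] <- m["sdmt", ] - 5
              m["stroop_card1", ] <- m["stroop_card1", ] + 5; m })(),
    NULL, subjectInfo(hc)))
  zw <- scoreZ(hc_w, norms)
  expect_true(all(zw["sdmt", ] < z["sdmt", ]))
  expect_true(all(zw["stroop_card1", ] < z["stroop_card1", ]))
})

test_that("z-scores are invariant to affine rescaling of a raw score", {
  hc <- cached("hc500", deriveComposites(generateControls(
    cohortConfig(n_controls = 500, seed = 31))))
  raw <- rawScores(hc, 1)
  inputs <- subscoreRegistry()$subscore[subscoreRegistry()$input]
  scaled <- raw[inputs, ]
  scaled["sdmt", ] <- 10 + 2.5 * scaled["sdmt", ]
  hc_s <- deriveComposites(CognitiveCohort(scaled, NULL, subjectInfo(hc)))
  z <- scoreZ(hc, fitNorms(hc))
  zs <- scoreZ(hc_s, fitNorms(hc_s))
  expect_equal(zs["sdmt", ], z["sdmt", ], tolerance = 1e-8)
})

test_that("missing demographics exclude the subject with a warning", {
  hc <- cached("hc500", deriveComposites(generateControls(
    cohortConfig(n_controls = 500, seed = 31))))
  norms <- fitNorms(hc)
  si <- subjectInfo(hc)
  si$age[1] <- NA
  broken <- CognitiveCohort(
    rawScores(hc, 1)[subscoreRegistry()$subscore[subscoreRegistry()$input], ],
    NULL, si)
  expect_warning(z <- scoreZ(deriveComposites(broken), norms),
                 "missing demographics")
  expect_true(all(is.na(z[, 1])))
  expect_false(anyNA(z[, 2]))
})

test_that("norms survive a JSON round trip", {
  hc <- cached("hc500", deriveComposites(generateControls(
    cohortConfig(n_controls = 500, seed = 31))))
  norms <- fitNorms(hc)
  path <- withr::local_tempfile(fileext = ".json")
  writeNorms(norms, path)
  back <- readNorms(path)
  z1 <- scoreZ(hc, norms)
  z2 <- scoreZ(hc, back)
  expect_equal(z2, z1, tolerance = 1e-12)
})
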