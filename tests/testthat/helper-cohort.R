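# shared fixtures, built once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# a medium cohort under the default (study-like) conditions
default_sim <- function() {
  cached("default_sim", simulateCohort(
    cohortConfig(n_controls = 96, n_patients = 200, seed = 1301)))
}

# zero-effect patients scored against norms from the same generator
null_sim <- function(n_patients = 2000, n_controls = 500, seed = 7701) {
  key <- paste0("null_sim_", n_patients, "_", n_controls, "_", seed)
  cached(key, {
    eff0 <- lapply(defaultDomainEffects(), function(e) { e[] <- 0; e })
    no_slopes <- lapply(defaultMriCogSlopes(), function(s) numeric(0))
    simulateCohort(cohortConfig(
      n_controls = n_controls, n_patients = n_patients, seed = seed,
      domain_effects = eff0, domain_drift = 0,
      mri_cog_slopes = no_slopes))
  })
}

# hand-built tiny cohort: one subject with prescribed raw inputs
tiny_cohort <- function(values, age = 46, sex = "female", education = 6) {
  reg <- subscoreRegistry()
  inputs <- reg$subscore[reg$input]
  t1 <- matrix(NA_real_, length(inputs), 1,
               dimnames = list(inputs, "S1"))
  t1[names(values), 1] <- values
  CognitiveCohort(t1, NULL, data.frame(
    subject_id = "S1", age = age, sex = sex, education = education,
    followup = FALSE, stringsAsFactors = FALSE))
}

# domain-profile row constructor for classification tests
profile_row <- function(ips = 0, memory = 0, efwm = 0, attention = 0,
                        id = "X", threshold = -1.5) {
  z <- c(ips = ips, memory = memory, efwm = efwm, attention = attention)
  df <- data.frame(subject_id = id, t(z))
  for (d in names(z)) df[[paste0("impaired_", d)]] <- z[[d]] < threshold
  df$n_impaired <- as.integer(sum(z < threshold))
  df$classifiable <- all(is.finite(z))
  df
}
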