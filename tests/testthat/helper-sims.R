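# shared simulation cache: several test files interrogate the same
# reference runs, so build each one once per test session
.sims <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sims)) assign(key, force(expr), envir = .sims)
  get(key, envir = .sims)
}

sim_single <- function(dose_mg, population = "healthy", phenotype = "EM",
                       dt = 0.05, horizon = 24) {
  key <- paste("single", dose_mg, population, phenotype, dt, horizon)
  cached(key, simulate_pbpk(
    scenario(dose_mg, horizon = horizon, dt = dt),
    build_parameters(population, phenotype)))
}

trough_ipa <- function(population, phenotype, maintenance, loading = 0,
                       n_days = 30) {
  key <- paste("trough", population, phenotype, maintenance, loading, n_days)
  cached(key, {
    reg <- build_regimen(loading, maintenance, 24, n_days)
    scn <- scenario(reg, horizon = n_days * 24, dt = 0.5)
    as.numeric(steady_ipa(scn, build_parameters(population, phenotype)))
  })
}

auc24_am <- function(res) nca_from_sim(res, "AM", c(0, 24))$auc
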