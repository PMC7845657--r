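# Core whole-body model: parameter packing, right-hand side assembly,
# integration and mass-balance checks.
#
# Reporting convention: the circulating partition ratio is
# Kt/b = Kt/p * Rbp, and reported "plasma" concentrations are venous
# blood concentrations converted to mass units directly.  Both choices
# are isolated here (pack_parms() and venous_conc()); see the methods
# vignette for why this pairing is adopted.

.N_COMP <- 18L
.N_STATE <- 67L  # 3 species x 18 compartments + 6 lumen + M + 6 bookkeeping

# state index helpers (1-based)
.state_names <- local({
  conc <- as.vector(outer(.clop_compartments, .clop_species,
                          function(c, s) paste(s, c, sep = ".")))
  c(conc,
    "lumen.stomach", paste0("lumen.", .gut_regions),
    "M",
    "cum.ces1.CLOP", "cum.ces1.OXO", "cum.ces1.AM",
    "cum.fecal", "cum.cyp.CLOP", "cum.cyp.OXO")
})

.ix <- local({
  ci <- function(s, c) (match(s, .clop_species) - 1L) * .N_COMP +
    match(c, .clop_compartments)
  list(
    conc = function(s, c) ci(s, c),
    vein = vapply(.clop_species, function(s) ci(s, "vein"), 1L),
    liver = vapply(.clop_species, function(s) ci(s, "liver"), 1L),
    lumen = 3L * .N_COMP + 1:6,
    M = 3L * .N_COMP + 7L,
    ces1 = 3L * .N_COMP + 7L + 1:3,
    fecal = 3L * .N_COMP + 11L,
    cyp = 3L * .N_COMP + 11L + 1:2)
})

# tissue:blood partition ratio per compartment and species
ktb_matrix <- function(mp) {
  out <- matrix(NA_real_, .N_COMP, 3,
                dimnames = list(.clop_compartments, .clop_species))
  for (s in .clop_species)
    out[names(.ktp_key), s] <- mp$ktp[.ktp_key, s] * mp$species[[s]]$rbp
  out
}

# flatten a clop_params object into the double vector consumed by the
# compiled right-hand side (layout documented in src/rhs.c)
pack_parms <- function(mp) {
  ktb <- ktb_matrix(mp)
  ktb[is.na(ktb)] <- 1  # vein/artery slots, never referenced
  gw <- paste0("gw_", .gut_regions)
  qliv_out <- sum(mp$tissues[c("liver", "spleen", "stomach", gw),
                             "blood_flow"])
  vc <- kmf <- matrix(0, 2, 5)
  ncyp <- numeric(2)
  for (si in 1:2) {
    sp <- mp$species[[.clop_species[si]]]
    n <- nrow(sp$cyp)
    ncyp[si] <- n
    # Vmax [pmol/min/pmol P450] x content [pmol P450/mg] -> nmol/h/mg
    vc[si, seq_len(n)] <- sp$cyp$vmax * sp$cyp$content * 60 / 1000
    # Km [uM] -> nmol/L, times the microsomal free fraction
    kmf[si, seq_len(n)] <- sp$cyp$km * 1000 * sp$fumic
  }
  c(mp$cardiac_output, qliv_out, mp$pbsf, mp$fugut, mp$kt0,
    mp$gut$kt, mp$gut$ka, mp$gut$kb,
    mp$pd$kin, mp$pd$kout, mp$pd$kirre, mp$species$AM$fub,
    mp$tissues$volume, mp$tissues$blood_flow,
    as.vector(ktb),
    vapply(.clop_species, function(s) mp$species[[s]]$fub, 1),
    vapply(.clop_species, function(s) mp$species[[s]]$clint_ces1, 1),
    ncyp, as.vector(t(vc)), as.vector(t(kmf)))
}

#' Concentration-dependent CYP intrinsic clearance per mg microsomes
#'
#' Michaelis-Menten intrinsic clearance summed over the isoforms acting
#' on one species, at a given free liver concentration: each isoform
#' contributes `Vmax * content / (Km * fumic + cfree)` with
#' Vmax x content converted to nmol/h/mg and Km to nmol/L, so the
#' result is in L/h per mg microsomal protein.  Multiplying by the
#' total microsomal protein (PBSF) gives whole-liver clearance.
#'
#' @param species_params one element of `mp$species` (parent or 2-oxo).
#' @param cfree free concentration in the liver, nmol/L.
#' @return intrinsic clearance, L/h/mg.
#' @export
#' @examples
#' mp <- default_parameters()
#' cyp_intrinsic_clearance(mp$species$CLOP, 0) * mp$pbsf  # ~46,100 L/h
cyp_intrinsic_clearance <- function(species_params, cfree = 0) {
  cyp <- species_params$cyp
  if (is.null(cyp)) return(0)
  if (cfree < 0) stop("free concentration must be non-negative")
  vc <- cyp$vmax * cyp$content * 60 / 1000
  kmf <- cyp$km * 1000 * species_params$fumic
  sum(vc / (kmf + cfree))
}

#' Assemble the model right-hand side as an R function
#'
#' Returns `function(t, y, parms)` computing all state derivatives in
#' plain R, mirroring the compiled routine exactly (same state layout
#' and packed parameter vector).  The compiled engine is the default
#' for simulation; this assembly exists for inspection, for unit tests
#' of individual terms, and as an independent cross-check of the C
#' implementation.
#'
#' @param mp a `clop_params` object.
#' @return a deSolve-style derivative function over the 67-element
#'   state (named per `clopbpk:::.state_names`).
#' @export
assemble_rhs <- function(mp) {
  p <- pack_parms(mp)
  V <- mp$tissues$volume
  Q <- mp$tissues$blood_flow
  ktb <- ktb_matrix(mp)
  qtot <- mp$cardiac_output
  gwi <- match(paste0("gw_", .gut_regions), .clop_compartments)
  systemic <- match(c("adipose", "muscle", "kidney", "brain", "heart",
                      "skin", "rob"), .clop_compartments)
  iliv <- match("liver", .clop_compartments)
  isp <- match("spleen", .clop_compartments)
  ist <- match("stomach", .clop_compartments)
  ilun <- match("lung", .clop_compartments)
  iven <- match("vein", .clop_compartments)
  iart <- match("artery", .clop_compartments)
  qliv_out <- Q[iliv] + Q[isp] + Q[ist] + sum(Q[gwi])
  fub <- vapply(.clop_species, function(s) mp$species[[s]]$fub, 1)
  ces1 <- vapply(.clop_species, function(s) mp$species[[s]]$clint_ces1, 1)
  vc <- lapply(mp$species[1:2], function(sp)
    sp$cyp$vmax * sp$cyp$content * 60 / 1000)
  kmf <- lapply(mp$species[1:2], function(sp)
    sp$cyp$km * 1000 * sp$fumic)
  gut <- mp$gut

  function(t, y, parms = NULL) {
    d <- numeric(.N_STATE)
    for (si in 1:3) {
      off <- (si - 1L) * .N_COMP
      C <- y[off + 1:.N_COMP]
      k <- ktb[, si]
      perf <- c(systemic, isp, ist, gwi)
      d[off + perf] <- Q[perf] * (C[iart] - C[perf] / k[perf]) / V[perf]
      d[off + ilun] <- qtot * (C[iven] - C[ilun] / k[ilun]) / V[ilun]
      d[off + iart] <- qtot * (C[ilun] / k[ilun] - C[iart]) / V[iart]
      d[off + iven] <- (sum(Q[systemic] * C[systemic] / k[systemic]) +
                          qliv_out * C[iliv] / k[iliv] -
                          qtot * C[iven]) / V[iven]
      inflow <- Q[iliv] * C[iart] + Q[ist] * C[ist] / k[ist] +
        Q[isp] * C[isp] / k[isp] + sum(Q[gwi] * C[gwi] / k[gwi])
      d[off + iliv] <- (inflow - qliv_out * C[iliv] / k[iliv]) / V[iliv]
    }
    # gut lumen (parent only); inlined so solver probe steps with tiny
    # negative excursions do not trip the exported helper's guard
    a0 <- y[.ix$lumen[1]]
    a <- y[.ix$lumen[2:6]]
    absorbed <- gut$ka * a
    efflux <- gut$kb * y[gwi] * V[gwi] * mp$fugut
    d[.ix$lumen[1]] <- -mp$kt0 * a0
    d[.ix$lumen[2:6]] <- c(mp$kt0 * a0, gut$kt[1:4] * a[1:4]) -
      gut$kt * a - absorbed + efflux
    d[gwi] <- d[gwi] + (absorbed - efflux) / V[gwi]
    d[.ix$fecal] <- gut$kt[5] * a[5]
    # hepatic metabolism cascade
    for (si in 1:3) {
      off <- (si - 1L) * .N_COMP
      cfree <- y[off + iliv] * fub[si] / ktb[iliv, si]
      clcyp <- if (si < 3) mp$pbsf * sum(vc[[si]] / (kmf[[si]] + cfree)) else 0
      rcyp <- clcyp * cfree
      rces <- ces1[si] * cfree
      d[off + iliv] <- d[off + iliv] - (rcyp + rces) / V[iliv]
      d[.ix$ces1[si]] <- rces
      if (si < 3) {
        d[si * .N_COMP + iliv] <- d[si * .N_COMP + iliv] + rcyp / V[iliv]
        d[.ix$cyp[si]] <- rcyp
      }
    }
    # platelet turnover on free venous active metabolite (nmol/ml)
    cam <- y[.ix$vein[3]] / 1000
    d[.ix$M] <- mp$pd$kin - mp$pd$kout * y[.ix$M] -
      mp$pd$kirre * cam * mp$species$AM$fub * y[.ix$M]
    list(d)
  }
}

#' Define a simulation scenario
#'
#' @param doses data frame with columns `time` (h, sorted, >= 0) and
#'   `amount` (mg), e.g. from [build_regimen()]; a single number is
#'   taken as one dose at time 0.
#' @param horizon simulation end time, h (must exceed the last dose).
#' @param dt output grid step, h.
#' @param rtol,atol solver tolerances (stiff integrator; atol is on the
#'   nmol/L scale).
#' @return a `clop_scenario` object.
#' @export
scenario <- function(doses, horizon = 24, dt = 0.05,
                     rtol = 1e-8, atol = 1e-10) {
  if (is.numeric(doses))
    doses <- data.frame(time = 0, amount = doses)
  stopifnot(all(c("time", "amount") %in% names(doses)))
  if (any(doses$time < 0) || is.unsorted(doses$time))
    stop("dose times must be sorted and non-negative")
  if (nrow(doses) && horizon <= max(doses$time))
    stop("horizon must exceed the last dose time")
  structure(list(doses = doses, horizon = horizon, dt = dt,
                 rtol = rtol, atol = atol),
            class = "clop_scenario")
}

#' Simulate a dosing scenario
#'
#' Integrates the full three-species PBPK system plus the platelet
#' state with a stiff solver (lsoda).  Each dose is an impulse into the
#' stomach-lumen amount at its event time (mg converted to nmol via the
#' parent molecular weight); the integration is restarted at dose
#' events.
#'
#' @param scn a [scenario()].
#' @param mp a `clop_params` subject.
#' @param engine `"compiled"` (default, C right-hand side) or `"R"`
#'   (plain-R assembly; identical results, much slower).
#' @param init_state optional full initial state vector (length 67,
#'   order per `clopbpk:::.state_names`); defaults to drug-free baseline
#'   with M = m0.
#' @return a `clop_sim` object: `time`, the raw state matrix `state`
#'   (deSolve output without the time column), the scenario, subject
#'   and total dose (nmol).  Use [venous_conc()], [ipa_trace()] and
#'   [mass_balance()] to extract results.
#' @export
#' @examples
#' \donttest{
#' mp <- build_parameters("healthy", "EM")
#' res <- simulate_pbpk(scenario(300, horizon = 24), mp)
#' max(venous_conc(res, "AM"))   # Cmax of the active metabolite, ng/ml
#' }
simulate_pbpk <- function(scn, mp, engine = c("compiled", "R"),
                          init_state = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(scn, "clop_scenario"), inherits(mp, "clop_params"))
  y0 <- if (is.null(init_state)) numeric(.N_STATE) else init_state
  stopifnot(length(y0) == .N_STATE)
  if (is.null(init_state)) y0[.ix$M] <- mp$pd$m0
  names(y0) <- .state_names

  amt <- scn$doses$amount * 1e6 / mp$species$CLOP$mw  # mg -> nmol
  at0 <- scn$doses$time <= 0
  y0[.ix$lumen[1]] <- y0[.ix$lumen[1]] + sum(amt[at0])
  ev <- NULL
  if (any(!at0))
    ev <- list(data = data.frame(var = "lumen.stomach",
                                 time = scn$doses$time[!at0],
                                 value = amt[!at0], method = "add"))
  times <- sort(unique(c(seq(0, scn$horizon, by = scn$dt),
                         scn$doses$time[!at0], scn$horizon)))
  out <- if (engine == "compiled")
    deSolve::ode(y0, times, func = "clopbpk_rhs", parms = pack_parms(mp),
                 dllname = "clopbpk", initfunc = "clopbpk_init",
                 method = "lsoda", rtol = scn$rtol, atol = scn$atol,
                 hini = 1e-6, events = ev)
  else
    deSolve::ode(y0, times, assemble_rhs(mp), parms = NULL,
                 method = "lsoda", rtol = scn$rtol, atol = scn$atol,
                 hini = 1e-6, events = ev)
  diagn <- attr(out, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop("ODE solver failed (istate = ", diagn[1], ")")
  state <- out[, -1, drop = FALSE]
  neg <- min(state[, 1:(3 * .N_COMP)])
  if (neg < -1e3 * scn$atol)
    warning("negative concentration excursion beyond tolerance: ", neg)
  structure(list(time = out[, 1], state = state, scenario = scn,
                 mp = mp, dose_nmol = sum(amt)),
            class = "clop_sim")
}

#' @export
print.clop_sim <- function(x, ...) {
  cat("<clop_sim> ", length(x$time), "time points over",
      max(x$time), "h;", nrow(x$scenario$doses), "dose(s),",
      sum(x$scenario$doses$amount), "mg total\n")
  cat("  subject:", x$mp$population, x$mp$phenotype,
      " peak venous AM:", signif(max(venous_conc(x, "AM")), 4), "ng/ml",
      " peak IPA:", signif(max(ipa_trace(x)), 4), "%\n")
  invisible(x)
}

#' Venous concentration trace of one species
#'
#' The reported concentration is the venous-blood concentration
#' expressed in mass units via the species molecular weight (the
#' reporting convention of the model; see the methods vignette).
#'
#' @param res a `clop_sim` result.
#' @param species `"CLOP"`, `"OXO"` or `"AM"`.
#' @param units `"ng/ml"` (default) or `"nmol/L"`.
#' @return numeric vector along `res$time` (clipped at zero).
#' @export
venous_conc <- function(res, species = "AM", units = c("ng/ml", "nmol/L")) {
  units <- match.arg(units)
  cb <- pmax(res$state[, .ix$vein[match(species, .clop_species)]], 0)
  if (units == "nmol/L") cb else cb * res$mp$species[[species]]$mw / 1000
}

#' Inhibition of platelet aggregation trace
#'
#' `IPA(%) = (1 - M) * 100`, clipped to \[0, 100\] for reporting.
#'
#' @param res a `clop_sim` result.
#' @return IPA in percent along `res$time`.
#' @export
ipa_trace <- function(res) ipa_from_m(res$state[, .ix$M])

#' Mass-balance check of a simulation
#'
#' At every output time the dose administered so far must equal the
#' molar amount still in the system (all compartments, all species,
#' lumen) plus the cumulative amounts hydrolysed by CES1 and lost in
#' faeces.  Returns the maximum relative violation over the trajectory;
#' values at the solver-tolerance scale (< 1e-6) indicate a consistent
#' right-hand side and adequate integration accuracy.
#'
#' @param res a `clop_sim` result.
#' @param mp subject parameters (defaults to those stored in `res`).
#' @return maximum relative mass-balance error.
#' @export
mass_balance <- function(res, mp = res$mp) {
  V <- mp$tissues$volume
  total <- numeric(length(res$time))
  for (si in 1:3) {
    cols <- (si - 1L) * .N_COMP + 1:.N_COMP
    total <- total + as.vector(res$state[, cols] %*% V)
  }
  total <- total + rowSums(res$state[, .ix$lumen, drop = FALSE]) +
    rowSums(res$state[, .ix$ces1, drop = FALSE]) +
    res$state[, .ix$fecal]
  amt <- res$scenario$doses$amount * 1e6 / mp$species$CLOP$mw
  dosed <- vapply(res$time, function(t)
    sum(amt[res$scenario$doses$time <= t]), 1)
  if (all(dosed == 0)) return(max(abs(total)))
  max(abs(total - dosed) / max(dosed))
}
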