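# Forward Monte-Carlo virtual population and visual-predictive-check
# percentile bands.

#' Sample a virtual population with lognormal variability
#'
#' Draws `n` subjects, each obtained from the base subject by applying
#' independent lognormal multipliers (median 1, the stated coefficient
#' of variation) to the listed parameter groups.  The default groups -
#' CYP2C19 activity, CES1 clearance (all species jointly), all
#' gastrointestinal transit rates jointly, and platelet responsiveness
#' kirre - are the ones with reported inter-individual variability;
#' their variances are not published, so a default CV of 30% is used
#' and can be overridden.
#'
#' @param n number of subjects.
#' @param cvs named numeric vector of coefficients of variation per
#'   parameter key (keys as in [perturb_parameters()]).
#' @param seed integer seed; sampling is deterministic given the seed.
#' @param mp base subject.
#' @return list of `n` `clop_params` objects; the multiplier matrix is
#'   attached as attribute `multipliers`.
#' @export
sample_population <- function(n,
                              cvs = c(vmax_cyp2c19 = 0.3,
                                      clint_ces1 = 0.3,
                                      kt_all = 0.3, kirre = 0.3),
                              seed, mp = build_parameters()) {
  stopifnot(n > 0, all(cvs >= 0))
  bad <- setdiff(names(cvs),
                 c("kt_all", "vmax_cyp2c9", "vmax_cyp2c19",
                   "vmax_cyp3a4", "clint_ces1", "kirre"))
  if (length(bad)) stop("unknown parameter key(s): ",
                        paste(bad, collapse = ", "))
  set.seed(seed)
  sdlog <- sqrt(log(1 + cvs^2))  # lognormal with median 1 and given CV
  mult <- vapply(sdlog, function(s) exp(rnorm(n, 0, s)), numeric(n))
  mult <- matrix(mult, nrow = n, dimnames = list(NULL, names(cvs)))
  pop <- lapply(seq_len(n), function(i) {
    mpi <- mp
    for (key in names(cvs))
      mpi <- perturb_parameters(mpi, key, mult[i, key])
    mpi
  })
  attr(pop, "multipliers") <- mult
  pop
}

#' Simulate every subject of a virtual population
#'
#' @param scn the common [scenario()].
#' @param population list of subjects from [sample_population()].
#' @param engine passed to [simulate_pbpk()].
#' @return list of `clop_sim` results sharing one time grid.
#' @export
simulate_population <- function(scn, population, engine = "compiled") {
  lapply(population, function(mp) simulate_pbpk(scn, mp, engine = engine))
}

#' Pointwise percentile bands across a simulated population
#'
#' Computes, at every time point, percentiles of the venous
#' active-metabolite concentration and of the IPA across subjects -
#' the bands plotted in a visual predictive check.
#'
#' @param results list of `clop_sim` results on a common time grid.
#' @param percentiles percent levels (default 5, 50, 95).
#' @return data frame: `time`, `quantity` (`"am_conc"` in ng/ml or
#'   `"ipa"` in %), `percentile`, `value`.
#' @export
vpc_bands <- function(results, percentiles = c(5, 50, 95)) {
  stopifnot(length(results) >= 1)
  tgrid <- results[[1]]$time
  for (r in results)
    if (!isTRUE(all.equal(r$time, tgrid)))
      stop("population results do not share a time grid")
  band_of <- function(mat, label) {
    qs <- apply(mat, 1, quantile, probs = percentiles / 100, names = FALSE)
    qs <- matrix(qs, nrow = length(percentiles))
    do.call(rbind, lapply(seq_along(percentiles), function(i)
      data.frame(time = tgrid, quantity = label,
                 percentile = percentiles[i], value = qs[i, ])))
  }
  conc <- vapply(results, venous_conc, numeric(length(tgrid)),
                 species = "AM")
  ipa <- vapply(results, ipa_trace, numeric(length(tgrid)))
  rbind(band_of(matrix(conc, nrow = length(tgrid)), "am_conc"),
        band_of(matrix(ipa, nrow = length(tgrid)), "ipa"))
}
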