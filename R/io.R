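# Delimited-text readers/writers and the JSON run manifest.

#' Read an observed time series from delimited text
#'
#' Expects a header row with a `time_h` column plus exactly one value
#' column; the field separator (tab, comma or whitespace) is sniffed
#' from the header line.  The value unit is taken from the value
#' column's name suffix (e.g. `conc_ng_ml`, `ipa_percent`) and attached
#' as an attribute.  Unsorted times are sorted with a warning.
#'
#' @param path file path.
#' @return data frame with columns `time` and `value`; attributes
#'   `value_name` and `unit`.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty observations file: ", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
  df <- tryCatch(
    read.table(path, header = TRUE, sep = sep, strip.white = TRUE),
    error = function(e) stop("malformed observations file (", path, "): ",
                             conditionMessage(e)))
  if (!"time_h" %in% names(df))
    stop("observations file must have a 'time_h' column")
  value_col <- setdiff(names(df), "time_h")
  if (length(value_col) != 1)
    stop("expected exactly one value column, found: ",
         paste(value_col, collapse = ", "))
  bad <- which(!is.finite(df$time_h) | !is.finite(df[[value_col]]))
  if (length(bad))
    stop("non-numeric or missing values on data row(s) ",
         paste(bad, collapse = ", "))
  if (is.unsorted(df$time_h)) {
    warning("observation times were unsorted; sorting")
    df <- df[order(df$time_h), ]
  }
  unit <- sub("^[a-zA-Z]+_", "", value_col)
  structure(data.frame(time = df$time_h, value = df[[value_col]]),
            value_name = value_col, unit = unit)
}

#' Write a simulation as a long delimited time series
#'
#' One row per (time, series): venous concentrations of the three
#' species in ng/ml and the IPA trace in percent; optionally every
#' compartment concentration in nmol/L.
#'
#' @param res a `clop_sim` result.
#' @param path output file (tab-separated).
#' @param all_compartments also write every compartment (nmol/L).
#' @return the path, invisibly.
#' @export
write_timeseries <- function(res, path, all_compartments = FALSE) {
  rows <- list()
  for (s in .clop_species)
    rows[[s]] <- data.frame(time_h = res$time, species = s,
                            compartment = "vein",
                            value = venous_conc(res, s), unit = "ng/ml")
  rows$ipa <- data.frame(time_h = res$time, species = "-",
                         compartment = "platelet", value = ipa_trace(res),
                         unit = "percent")
  if (all_compartments)
    for (s in .clop_species)
      for (cmp in .clop_compartments)
        rows[[paste(s, cmp)]] <- data.frame(
          time_h = res$time, species = s, compartment = cmp,
          value = res$state[, .ix$conc(s, cmp)], unit = "nmol/L")
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# md5 of a serialized object (used for the manifest parameter hash)
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Write a JSON run manifest
#'
#' Records everything needed to reproduce a run bit-identically under
#' the same package version: the scenario, subject labels, a hash of
#' the full parameter state, solver settings and the seed.
#'
#' @param path output file.
#' @param scn the [scenario()].
#' @param mp the subject.
#' @param seed the seed used for any randomness (NA for deterministic
#'   runs).
#' @param extra optional named list merged into the manifest.
#' @return the path, invisibly.
#' @export
write_manifest <- function(path, scn, mp, seed = NA, extra = NULL) {
  man <- list(
    package = "clopbpk",
    version = as.character(utils::packageVersion("clopbpk")),
    population = mp$population,
    phenotype = mp$phenotype,
    doses = scn$doses,
    horizon_h = scn$horizon,
    grid_dt_h = scn$dt,
    solver = list(method = "lsoda", rtol = scn$rtol, atol = scn$atol),
    parameter_hash = object_hash(mp),
    seed = seed)
  if (!is.null(extra)) man <- c(man, extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write an NCA summary as delimited text
#'
#' @param res a `clop_sim` result.
#' @param path output file (tab-separated).
#' @param window NCA window, h.
#' @return the path, invisibly.
#' @export
write_nca_summary <- function(res, path, window = NULL) {
  if (is.null(window)) window <- range(res$time)
  rows <- lapply(.clop_species, function(s) {
    m <- nca_from_sim(res, s, window)
    data.frame(species = s, compartment = "vein",
               window_start_h = window[1], window_end_h = window[2],
               cmax_ng_ml = m$cmax, tmax_h = m$tmax,
               auc_ng_h_ml = m$auc)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
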