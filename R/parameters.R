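# Parameter state for one virtual subject: physiology, per-species drug
# properties, enzyme kinetics, absorption and platelet turnover, plus
# phenotype and population scaling.

# internal compartment order; must match the compiled right-hand side
.clop_compartments <- c("spleen", "liver", "adipose", "muscle", "lung",
                        "kidney", "brain", "heart", "skin", "rob",
                        "vein", "artery", "stomach",
                        "gw_duodenum", "gw_jejunum", "gw_ileum",
                        "gw_caecum", "gw_colon")

.clop_species <- c("CLOP", "OXO", "AM")

.gut_regions <- c("duodenum", "jejunum", "ileum", "caecum", "colon")

# tissue:plasma row used for each perfused compartment (stomach and the
# gut wall share the intestinal value; vein/artery are blood pools)
.ktp_key <- c(spleen = "spleen", liver = "liver", adipose = "adipose",
              muscle = "muscle", lung = "lung", kidney = "kidney",
              brain = "brain", heart = "heart", skin = "skin", rob = "rob",
              stomach = "gut",
              gw_duodenum = "gut", gw_jejunum = "gut", gw_ileum = "gut",
              gw_caecum = "gut", gw_colon = "gut")

#' Reference parameter set for a healthy CYP2C19 extensive metabolizer
#'
#' Returns the complete model parameter state for one healthy
#' extensive-metabolizer (EM) subject: organ volumes and blood flows,
#' per-species physicochemistry and tissue:plasma partition
#' coefficients, hepatic enzyme kinetics, gut transit/absorption rate
#' constants and the platelet turnover constants.  All other subjects
#' (phenotypes, disease populations, perturbed parameter sets) are
#' derived from this set by [apply_phenotype()], [apply_population()]
#' and [perturb_parameters()].
#'
#' Internal unit conventions: time in hours, volumes in liters, blood
#' flows in liters/hour, amounts in nanomoles and concentrations in
#' nmol/L; mass-based reporting (ng/ml) happens only at the output
#' boundary via the molecular weights.  Enzyme Vmax is in
#' pmol product/min/pmol P450, Km in micromolar and isoform content in
#' pmol P450/mg microsomal protein, exactly as tabulated; the conversion
#' to volume clearance happens inside the model right-hand side.
#'
#' Molecular weights are not part of the tabulated parameter record and
#' are supplied from standard chemistry references (free-base parent
#' 321.82 g/mol); they can be overridden by editing the returned object.
#'
#' @return An object of class `clop_params`: a list with elements
#'   `tissues` (data frame: name, volume \[L\], blood_flow \[L/h\]),
#'   `ktp` (matrix of tissue:plasma ratios, one column per species),
#'   `species` (per-compound list: `mw`, `fup`, `rbp`, `fumic`, `fub`,
#'   `clint_ces1` \[L/h\], `cyp` data frame with `enzyme`, `vmax`, `km`,
#'   `content`), `gut` (data frame: region, radius \[cm\], tsf, kt, ka,
#'   kb \[1/h\]), `kt0` (gastric emptying, 1/h), `pbsf` (total hepatic
#'   microsomal protein, mg), `fugut`, `pd` (kin, kout \[1/h\], kirre
#'   \[ml/nmol/h\], m0), `cardiac_output` \[L/h\], and the `population`
#'   and `phenotype` labels.
#' @seealso [build_parameters()] for a one-call population x phenotype
#'   constructor, [param_provenance()] for the value-by-value record.
#' @export
#' @examples
#' mp <- default_parameters()
#' mp$tissues["liver", "volume"]          # 1.38 L
#' mp$species$AM$clint_ces1               # 529 L/h
default_parameters <- function() {
  lmin <- 60  # tabulated blood flows are L/min; internal unit is L/h

  tissues <- data.frame(
    name = .clop_compartments,
    volume = c(0.16, 1.38, 22.20, 17.51, 0.94, 0.23, 1.53, 0.27, 1.65,
               17.75, 1.91, 3.83, 0.15, 0.02, 0.06, 0.04, 0.04, 0.34),
    blood_flow = c(0.16, 0.42, 0.46, 0.54, 5.27, 0.89, 0.80, 0.20, 0.21,
                   0.68, 5.27, 5.27, 0.13, 0.08, 0.30, 0.17, 0.03,
                   0.20) * lmin,
    row.names = .clop_compartments, stringsAsFactors = FALSE)

  # tissue:plasma partition coefficients per species; the residual
  # rest-of-body compartment is assigned a nominal 0.001 (no uptake)
  ktp <- matrix(c(
    # CLOP   OXO    AM
    5.182, 8.748, 3.243,   # spleen
    5.625, 7.988, 3.640,   # liver
    6.634, 0.151, 0.098,   # adipose
    6.171, 9.525, 2.802,   # muscle
    3.566, 6.810, 1.624,   # lung
    5.309, 7.933, 3.597,   # kidney
    6.675, 8.784, 3.544,   # brain
    6.065, 6.864, 2.805,   # heart
    5.309, 1.390, 0.601,   # skin
    0.001, 0.001, 0.001,   # rest of body (assumed)
    6.586, 4.866, 1.811),  # gut (stomach + gut wall)
    ncol = 3, byrow = TRUE,
    dimnames = list(c("spleen", "liver", "adipose", "muscle", "lung",
                      "kidney", "brain", "heart", "skin", "rob", "gut"),
                    .clop_species))

  species <- list(
    CLOP = list(
      species = "CLOP", mw = 321.82,
      fup = 0.02, rbp = 0.57, fumic = 0.015,
      clint_ces1 = 276650,  # L/h; ~85% of total parent intrinsic clearance
      cyp = data.frame(
        enzyme  = c("CYP1A2", "CYP2B6", "CYP2C19"),
        vmax    = c(2.27, 7.66, 7.52),
        km      = c(1.58, 2.08, 1.12),
        content = c(52, 11, 14),
        stringsAsFactors = FALSE)),
    OXO = list(
      species = "OXO", mw = 337.82,
      fup = 0.0742, rbp = 0.68, fumic = 0.180,
      clint_ces1 = 2200,
      cyp = data.frame(
        enzyme  = c("CYP2B6", "CYP2C9", "CYP3A4", "CYP2C19"),
        vmax    = c(2.48, 0.855, 3.63, 9.06),
        km      = c(1.62, 18.1, 27.8, 12.1),
        content = c(11, 73, 155, 14),
        stringsAsFactors = FALSE)),
    AM = list(
      species = "AM", mw = 355.82,
      fup = 0.0791, rbp = 0.58, fumic = NA_real_,
      clint_ces1 = 529,
      cyp = NULL))
  for (s in names(species))
    species[[s]]$fub <- species[[s]]$fup / species[[s]]$rbp

  gut <- derive_absorption_rates()

  mp <- list(
    tissues = tissues,
    ktp = ktp,
    species = species,
    gut = gut,
    kt0 = 4.8,            # gastric emptying, 1/h
    pbsf = 55120,         # total hepatic microsomal protein, mg
    fugut = 0.02,         # free fraction in the gut wall (parent)
    pd = list(kin = 0.007804, kout = 0.007804, kirre = 47.576, m0 = 1),
    cardiac_output = 5.27 * lmin,
    population = "healthy",
    phenotype = "EM")
  class(mp) <- "clop_params"
  validate_parameters(mp)
  mp
}

#' @export
print.clop_params <- function(x, ...) {
  cat("<clop_params> population:", x$population,
      " phenotype:", x$phenotype, "\n")
  cat("  cardiac output:", x$cardiac_output, "L/h;  PBSF:", x$pbsf, "mg\n")
  cat("  CYP2C19 Vmax (parent):",
      x$species$CLOP$cyp$vmax[x$species$CLOP$cyp$enzyme == "CYP2C19"],
      "pmol/pmol P450/min;  kirre:", x$pd$kirre, "ml/nmol/h\n")
  invisible(x)
}

# structural invariants; called on construction and after scaling
validate_parameters <- function(mp) {
  stopifnot(
    identical(mp$tissues$name, .clop_compartments),
    all(mp$tissues$volume > 0),
    all(mp$tissues$blood_flow >= 0),
    mp$pbsf > 0, mp$fugut > 0, mp$kt0 > 0,
    all(mp$gut$kt > 0), all(mp$gut$ka >= 0), all(mp$gut$kb >= 0),
    mp$pd$kout >= 0, mp$pd$kirre >= 0,
    abs(mp$pd$kin - mp$pd$kout * mp$pd$m0) < 1e-12)
  for (s in .clop_species) {
    sp <- mp$species[[s]]
    stopifnot(sp$fup > 0, sp$fup <= 1, sp$rbp > 0,
              abs(sp$fub - sp$fup / sp$rbp) < 1e-12,
              sp$clint_ces1 >= 0)
    if (!is.null(sp$cyp))
      stopifnot(all(sp$cyp$vmax >= 0), all(sp$cyp$km > 0),
                all(sp$cyp$content > 0))
    # every perfused compartment must have a partition ratio
    stopifnot(all(.ktp_key %in% rownames(mp$ktp)))
  }
  # non-absorptive caecum and colon
  stopifnot(all(mp$gut[c("caecum", "colon"), c("ka", "kb")] == 0))
  invisible(mp)
}

#' CYP2C19 phenotype activity multipliers
#'
#' Activity of CYP2C19 relative to the extensive metabolizer (EM):
#' ultrarapid (UM) 1.58, EM 1, intermediate (IM) 0.5, poor (PM) 0.
#'
#' @param phenotype one of `"UM"`, `"EM"`, `"IM"`, `"PM"`.
#' @return the scalar Vmax multiplier.
#' @export
phenotype_multiplier <- function(phenotype) {
  mult <- c(UM = 1.58, EM = 1, IM = 0.5, PM = 0)
  if (!phenotype %in% names(mult))
    stop("unknown CYP2C19 phenotype: ", phenotype)
  unname(mult[phenotype])
}

#' Apply a CYP2C19 metabolizer phenotype
#'
#' Scales Vmax of CYP2C19 for both oxidation steps (parent -> 2-oxo and
#' 2-oxo -> active metabolite) by the phenotype activity multiplier.
#' Km and all other isoforms are untouched: the phenotypes are modeled
#' as pure activity differences with unchanged substrate affinity.
#'
#' @param mp a `clop_params` object (EM basis).
#' @param phenotype `"UM"`, `"EM"`, `"IM"` or `"PM"`.
#' @return the scaled `clop_params` object.
#' @export
#' @examples
#' pm <- apply_phenotype(default_parameters(), "PM")
#' subset(pm$species$CLOP$cyp, enzyme == "CYP2C19")$vmax   # 0
apply_phenotype <- function(mp, phenotype) {
  mult <- phenotype_multiplier(phenotype)
  for (s in c("CLOP", "OXO")) {
    i <- mp$species[[s]]$cyp$enzyme == "CYP2C19"
    mp$species[[s]]$cyp$vmax[i] <- mp$species[[s]]$cyp$vmax[i] * mult
  }
  mp$phenotype <- phenotype
  mp
}

#' Population presets: healthy, CAD, CAD with diabetes
#'
#' A preset is a set of multiplicative/override rules converting the
#' healthy parameter set into a patient population:
#' * `healthy` - the identity.
#' * `CAD` - coronary artery disease: all tissue blood flows scaled by
#'   the cardiac-output ratio 0.90 and platelet responsiveness
#'   (`kirre`) scaled by 0.7.
#' * `CAD_DM` - CAD with diabetes: the CAD changes plus hepatic enzyme
#'   activity multipliers (CYP1A2 1.23, CYP2B6 0.55, CYP2C9 1.26,
#'   CYP2C19 0.54, CYP3A4 0.62), CES1 activity x 1.27 for all three
#'   species, and diabetic gastrointestinal transit rates (stomach
#'   2.31, duodenum 2.30, jejunum 0.99, ileum 1.32, caecum 0.20, colon
#'   0.04 per hour).
#'
#' @param name `"healthy"`, `"CAD"` or `"CAD_DM"`.
#' @return a `clop_preset` list with fields `name`, `flow_multiplier`,
#'   `enzyme_multipliers`, `ces1_multiplier`, `kt_overrides` (named,
#'   stomach + gut regions, 1/h) and `kirre_multiplier`.
#' @export
population_preset <- function(name = c("healthy", "CAD", "CAD_DM")) {
  name <- match.arg(name)
  pre <- list(name = name, flow_multiplier = 1,
              enzyme_multipliers = NULL, ces1_multiplier = 1,
              kt_overrides = NULL, kirre_multiplier = 1)
  if (name %in% c("CAD", "CAD_DM")) {
    pre$flow_multiplier <- 0.90
    pre$kirre_multiplier <- 0.7
  }
  if (name == "CAD_DM") {
    pre$enzyme_multipliers <- c(CYP1A2 = 1.23, CYP2B6 = 0.55,
                                CYP2C9 = 1.26, CYP2C19 = 0.54,
                                CYP3A4 = 0.62)
    pre$ces1_multiplier <- 1.27
    pre$kt_overrides <- c(stomach = 2.31, duodenum = 2.30,
                          jejunum = 0.99, ileum = 1.32,
                          caecum = 0.20, colon = 0.04)
  }
  class(pre) <- "clop_preset"
  pre
}

#' Scale a healthy parameter set to a patient population
#'
#' Applies a [population_preset()] (or a user-defined preset with the
#' same fields): tissue blood flows and cardiac output are scaled by
#' the flow multiplier, CYP Vmax values by the per-enzyme multipliers,
#' CES1 clearances of all three species by the CES1 multiplier, transit
#' rates are replaced where overridden, and `kirre` is scaled.
#' Population scaling and phenotype scaling commute (both act
#' multiplicatively on Vmax of CYP2C19); the packaged convention is
#' population first, phenotype second.
#'
#' @param mp a healthy `clop_params` set.
#' @param preset a `clop_preset` or the name of a packaged preset.
#' @return the scaled `clop_params` object.
#' @export
#' @examples
#' cad <- apply_population(default_parameters(), "CAD")
#' cad$pd$kirre                        # 0.7 * 47.576 = 33.3032
apply_population <- function(mp, preset) {
  if (is.character(preset)) preset <- population_preset(preset)
  mp$tissues$blood_flow <- mp$tissues$blood_flow * preset$flow_multiplier
  mp$cardiac_output <- mp$cardiac_output * preset$flow_multiplier
  if (!is.null(preset$enzyme_multipliers)) {
    known <- unique(c(mp$species$CLOP$cyp$enzyme, mp$species$OXO$cyp$enzyme))
    bad <- setdiff(names(preset$enzyme_multipliers), known)
    if (length(bad))
      stop("preset names enzymes absent from the model: ",
           paste(bad, collapse = ", "))
    for (s in c("CLOP", "OXO")) {
      cyp <- mp$species[[s]]$cyp
      m <- preset$enzyme_multipliers[cyp$enzyme]
      m[is.na(m)] <- 1
      mp$species[[s]]$cyp$vmax <- cyp$vmax * as.numeric(m)
    }
  }
  for (s in .clop_species)
    mp$species[[s]]$clint_ces1 <-
      mp$species[[s]]$clint_ces1 * preset$ces1_multiplier
  if (!is.null(preset$kt_overrides)) {
    kt <- preset$kt_overrides
    if ("stomach" %in% names(kt)) mp$kt0 <- unname(kt[["stomach"]])
    reg <- intersect(names(kt), rownames(mp$gut))
    mp$gut[reg, "kt"] <- unname(kt[reg])
  }
  mp$pd$kirre <- mp$pd$kirre * preset$kirre_multiplier
  mp$population <- preset$name
  mp
}

#' Construct a subject for a population and CYP2C19 phenotype
#'
#' Convenience wrapper: healthy reference set, population preset, then
#' phenotype scaling.
#'
#' @param population `"healthy"`, `"CAD"` or `"CAD_DM"`.
#' @param phenotype `"UM"`, `"EM"`, `"IM"` or `"PM"`.
#' @return a `clop_params` object.
#' @export
build_parameters <- function(population = "healthy", phenotype = "EM") {
  apply_phenotype(apply_population(default_parameters(), population),
                  phenotype)
}

#' Total hepatic microsomal protein from liver weight and yield
#'
#' The physiological-based scaling factor (PBSF) that converts per-mg
#' microsomal clearance to whole-liver clearance is liver weight times
#' microsomal protein yield.  The packaged default corresponds to
#' 55,120 mg.
#'
#' @param liver_weight_g total liver weight, g.
#' @param microsomal_yield_mg_per_g microsomal protein yield, mg/g liver.
#' @return total microsomal protein, mg.
#' @export
#' @examples
#' pbsf_from_liver(1378, 40)   # 55120
pbsf_from_liver <- function(liver_weight_g, microsomal_yield_mg_per_g) {
  if (liver_weight_g <= 0 || microsomal_yield_mg_per_g <= 0)
    stop("liver weight and microsomal yield must be positive")
  liver_weight_g * microsomal_yield_mg_per_g
}

#' Perturb one scalable parameter group
#'
#' Multiplies one of the named parameter groups by `multiplier`; used by
#' the sensitivity scans and the virtual-population sampler.
#'
#' @param mp a `clop_params` object.
#' @param key one of `"kt_all"` (every transit rate including gastric
#'   emptying), `"vmax_cyp2c9"`, `"vmax_cyp2c19"`, `"vmax_cyp3a4"`
#'   (the isoform's Vmax wherever it acts), `"clint_ces1"` (all three
#'   species jointly) or `"kirre"`.
#' @param multiplier positive scalar (0 permitted for Vmax keys).
#' @return the perturbed `clop_params` object.
#' @export
perturb_parameters <- function(mp, key, multiplier) {
  multiplier <- unname(multiplier)
  if (multiplier < 0) stop("multiplier must be non-negative")
  scale_enzyme <- function(mp, enzyme) {
    for (s in c("CLOP", "OXO")) {
      i <- mp$species[[s]]$cyp$enzyme == enzyme
      mp$species[[s]]$cyp$vmax[i] <- mp$species[[s]]$cyp$vmax[i] * multiplier
    }
    mp
  }
  switch(key,
    kt_all = {
      if (multiplier == 0) stop("transit rates must stay positive")
      mp$kt0 <- mp$kt0 * multiplier
      mp$gut$kt <- mp$gut$kt * multiplier
      mp
    },
    vmax_cyp2c9  = scale_enzyme(mp, "CYP2C9"),
    vmax_cyp2c19 = scale_enzyme(mp, "CYP2C19"),
    vmax_cyp3a4  = scale_enzyme(mp, "CYP3A4"),
    clint_ces1 = {
      for (s in .clop_species)
        mp$species[[s]]$clint_ces1 <- mp$species[[s]]$clint_ces1 * multiplier
      mp
    },
    kirre = { mp$pd$kirre <- mp$pd$kirre * multiplier; mp },
    stop("unknown parameter key: ", key))
}

#' Parameter provenance table
#'
#' One row per packaged constant: parameter path, value, units and the
#' kind of source it was transcribed or derived from.  Exported as
#' delimited text by the `params` CLI subcommand.
#'
#' @param mp parameter set to tabulate (default: the healthy EM set).
#' @return a data frame with columns `parameter`, `value`, `units`,
#'   `source`.
#' @export
param_provenance <- function(mp = default_parameters()) {
  rows <- list()
  add <- function(parameter, value, units, source)
    rows[[length(rows) + 1]] <<- data.frame(
      parameter = parameter, value = value, units = units,
      source = source, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mp$tissues))) {
    nm <- mp$tissues$name[i]
    add(paste0("tissues.", nm, ".volume"), mp$tissues$volume[i], "L",
        "tabulated physiology")
    add(paste0("tissues.", nm, ".blood_flow"),
        mp$tissues$blood_flow[i] / 60, "L/min", "tabulated physiology")
  }
  for (s in .clop_species) {
    sp <- mp$species[[s]]
    add(paste0("species.", s, ".mw"), sp$mw, "g/mol",
        "external literature (not tabulated)")
    add(paste0("species.", s, ".fup"), sp$fup, "-", "tabulated")
    add(paste0("species.", s, ".rbp"), sp$rbp, "-", "tabulated")
    if (!is.na(sp$fumic))
      add(paste0("species.", s, ".fumic"), sp$fumic, "-", "tabulated")
    add(paste0("species.", s, ".clint_ces1"), sp$clint_ces1, "L/h",
        "in-text constant")
    if (!is.null(sp$cyp))
      for (j in seq_len(nrow(sp$cyp))) {
        e <- sp$cyp$enzyme[j]
        add(paste0("species.", s, ".cyp.", e, ".vmax"), sp$cyp$vmax[j],
            "pmol/pmol P450/min", "tabulated enzyme kinetics")
        add(paste0("species.", s, ".cyp.", e, ".km"), sp$cyp$km[j],
            "uM", "tabulated enzyme kinetics")
        add(paste0("species.", s, ".cyp.", e, ".content"),
            sp$cyp$content[j], "pmol P450/mg", "tabulated enzyme kinetics")
      }
    for (tt in rownames(mp$ktp))
      add(paste0("ktp.", tt, ".", s), mp$ktp[tt, s], "-",
          if (tt == "rob") "assumed" else "tabulated partition coefficient")
  }
  for (r in rownames(mp$gut)) {
    g <- mp$gut[r, ]
    if (!is.na(g$radius)) {
      add(paste0("gut.", r, ".radius"), g$radius, "cm", "in-text constant")
      add(paste0("gut.", r, ".tsf"), g$tsf, "-", "in-text constant")
    }
    add(paste0("gut.", r, ".kt"), g$kt, "1/h", "in-text constant")
    add(paste0("gut.", r, ".ka"), g$ka, "1/h",
        "derived (permeability correlation)")
    add(paste0("gut.", r, ".kb"), g$kb, "1/h", "in-text constant")
  }
  add("kt0", mp$kt0, "1/h", "in-text constant")
  add("pbsf", mp$pbsf, "mg", "in-text constant")
  add("fugut", mp$fugut, "-", "in-text constant")
  add("pd.kin", mp$pd$kin, "1/h", "derived (kout * m0)")
  add("pd.kout", mp$pd$kout, "1/h", "derived (platelet half-life 3.7 d)")
  add("pd.kirre", mp$pd$kirre, "ml/nmol/h", "in-text constant")
  add("cardiac_output", mp$cardiac_output / 60, "L/min",
      "tabulated physiology")
  do.call(rbind, rows)
}
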