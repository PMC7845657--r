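# Transcription fidelity of the packaged constants and correctness of
# phenotype/population scaling.

test_that("physiology, partition and enzyme tables are transcribed exactly", {
  mp <- default_parameters()
  vol <- c(spleen = 0.16, liver = 1.38, adipose = 22.20, muscle = 17.51,
           lung = 0.94, kidney = 0.23, brain = 1.53, heart = 0.27,
           skin = 1.65, rob = 17.75, vein = 1.91, artery = 3.83,
           stomach = 0.15, gw_duodenum = 0.02, gw_jejunum = 0.06,
           gw_ileum = 0.04, gw_caecum = 0.04, gw_colon = 0.34)
  flow_lmin <- c(spleen = 0.16, liver = 0.42, adipose = 0.46,
                 muscle = 0.54, lung = 5.27, kidney = 0.89, brain = 0.80,
                 heart = 0.20, skin = 0.21, rob = 0.68, vein = 5.27,
                 artery = 5.27, stomach = 0.13, gw_duodenum = 0.08,
                 gw_jejunum = 0.30, gw_ileum = 0.17, gw_caecum = 0.03,
                 gw_colon = 0.20)
  expect_identical(unname(vol[mp$tissues$name]), mp$tissues$volume)
  expect_equal(mp$tissues$blood_flow, unname(flow_lmin[mp$tissues$name]) * 60)

  ktp_expect <- rbind(
    adipose = c(6.634, 0.151, 0.098), brain = c(6.675, 8.784, 3.544),
    gut = c(6.586, 4.866, 1.811), heart = c(6.065, 6.864, 2.805),
    kidney = c(5.309, 7.933, 3.597), liver = c(5.625, 7.988, 3.640),
    lung = c(3.566, 6.810, 1.624), muscle = c(6.171, 9.525, 2.802),
    skin = c(5.309, 1.390, 0.601), spleen = c(5.182, 8.748, 3.243),
    rob = c(0.001, 0.001, 0.001))
  for (tt in rownames(ktp_expect))
    expect_identical(unname(mp$ktp[tt, ]), unname(ktp_expect[tt, ]),
                     label = paste("ktp", tt))

  clop <- mp$species$CLOP
  expect_identical(c(clop$fup, clop$rbp, clop$fumic), c(0.02, 0.57, 0.015))
  expect_identical(clop$clint_ces1, 276650)
  expect_identical(clop$cyp$vmax, c(2.27, 7.66, 7.52))
  expect_identical(clop$cyp$km, c(1.58, 2.08, 1.12))
  expect_identical(clop$cyp$content, c(52, 11, 14))
  oxo <- mp$species$OXO
  expect_identical(c(oxo$fup, oxo$rbp, oxo$fumic), c(0.0742, 0.68, 0.180))
  expect_identical(oxo$clint_ces1, 2200)
  expect_identical(oxo$cyp$vmax, c(2.48, 0.855, 3.63, 9.06))
  expect_identical(oxo$cyp$km, c(1.62, 18.1, 27.8, 12.1))
  expect_identical(oxo$cyp$content, c(11, 73, 155, 14))
  am <- mp$species$AM
  expect_identical(c(am$fup, am$rbp), c(0.0791, 0.58))
  expect_identical(am$clint_ces1, 529)

  expect_identical(mp$gut$kt, c(4.2, 1.8, 2.4, 0.18, 0.06))
  expect_identical(mp$kt0, 4.8)
  expect_identical(mp$pbsf, 55120)
  expect_identical(mp$fugut, 0.02)
  expect_identical(mp$pd$kirre, 47.576)
  expect_identical(mp$pd$kout, 0.007804)
})

test_that("flow bookkeeping is internally consistent", {
  mp <- default_parameters()
  # residual compartment closes the circulation: all systemic + portal
  # organ flows (everything except lung and the blood pools) sum to the
  # cardiac output
  organs <- setdiff(mp$tissues$name, c("lung", "vein", "artery"))
  expect_equal(sum(mp$tissues[organs, "blood_flow"]), mp$cardiac_output)
  # free fractions in blood derive from fup and Rbp
  for (s in c("CLOP", "OXO", "AM"))
    expect_equal(mp$species[[s]]$fub,
                 mp$species[[s]]$fup / mp$species[[s]]$rbp)
})

test_that("phenotype scaling matches the tabulated Vmax values", {
  mp <- default_parameters()
  v2c19 <- function(m, s) m$species[[s]]$cyp$vmax[
    m$species[[s]]$cyp$enzyme == "CYP2C19"]
  expect_equal(v2c19(mp, "CLOP"), 7.52)          # EM basis
  um <- apply_phenotype(mp, "UM")
  expect_equal(v2c19(um, "CLOP"), 11.88, tolerance = 0.005 / 11.88)
  expect_equal(v2c19(um, "OXO"), 14.31, tolerance = 0.005 / 14.31)
  im <- apply_phenotype(mp, "IM")
  expect_equal(v2c19(im, "CLOP"), 3.76)
  expect_equal(v2c19(im, "OXO"), 4.53)
  pm <- apply_phenotype(mp, "PM")
  expect_identical(v2c19(pm, "CLOP"), 0)
  expect_identical(v2c19(pm, "OXO"), 0)
  # affinity never changes with phenotype
  expect_identical(pm$species$CLOP$cyp$km[
    pm$species$CLOP$cyp$enzyme == "CYP2C19"], 1.12)
  expect_identical(pm$species$OXO$cyp$km[
    pm$species$OXO$cyp$enzyme == "CYP2C19"], 12.1)
  expect_error(apply_phenotype(mp, "XX"), "unknown")
})

test_that("phenotype activity is strictly ordered in every population", {
  for (pop in c("healthy", "CAD", "CAD_DM")) {
    v <- vapply(c("UM", "EM", "IM", "PM"), function(ph) {
      m <- build_parameters(pop, ph)
      m$species$CLOP$cyp$vmax[m$species$CLOP$cyp$enzyme == "CYP2C19"]
    }, 1)
    expect_true(all(diff(v) < 0), label = pop)
    expect_identical(unname(v["PM"]), 0)
  }
})

test_that("healthy preset is the identity", {
  mp <- default_parameters()
  expect_identical(apply_population(mp, "healthy")[names(mp) != "population"],
                   mp[names(mp) != "population"])
})

test_that("CAD preset scales flows by the cardiac-output ratio", {
  cad <- apply_population(default_parameters(), "CAD")
  # reference CAD flow column (printed to 2 decimals, L/min)
  printed <- c(spleen = 0.14, liver = 0.38, adipose = 0.41, muscle = 0.49,
               lung = 4.74, kidney = 0.80, brain = 0.72, heart = 0.18,
               skin = 0.19, rob = 0.61, vein = 4.74, artery = 4.74,
               stomach = 0.12, gw_duodenum = 0.07, gw_jejunum = 0.27,
               gw_ileum = 0.15, gw_caecum = 0.03, gw_colon = 0.18)
  expect_lt(max(abs(cad$tissues$blood_flow / 60 -
                      unname(printed[cad$tissues$name]))), 0.005)
  expect_equal(cad$pd$kirre, 0.7 * 47.576)
  # volumes, enzymes and transit untouched
  expect_identical(cad$tissues$volume, default_parameters()$tissues$volume)
  expect_identical(cad$gut$kt, default_parameters()$gut$kt)
})

test_that("diabetic preset composes CAD changes with enzyme/CES1/transit", {
  dm <- apply_population(default_parameters(), "CAD_DM")
  expect_equal(dm$species$CLOP$cyp$vmax[
    dm$species$CLOP$cyp$enzyme == "CYP2C19"], 7.52 * 0.54)
  expect_equal(dm$species$CLOP$cyp$vmax[
    dm$species$CLOP$cyp$enzyme == "CYP1A2"], 2.27 * 1.23)
  expect_equal(dm$species$OXO$cyp$vmax[
    dm$species$OXO$cyp$enzyme == "CYP3A4"], 3.63 * 0.62)
  expect_equal(dm$species$CLOP$clint_ces1, 276650 * 1.27)
  expect_equal(dm$species$AM$clint_ces1, 529 * 1.27)
  expect_identical(dm$kt0, 2.31)
  expect_identical(dm$gut$kt, c(2.30, 0.99, 1.32, 0.20, 0.04))
  expect_equal(dm$pd$kirre, 0.7 * 47.576)      # same platelet response as CAD
  expect_equal(dm$cardiac_output, 5.27 * 60 * 0.9)  # same flows as CAD
})

test_that("population and phenotype scaling commute", {
  a <- apply_phenotype(apply_population(default_parameters(), "CAD_DM"), "IM")
  b <- apply_population(apply_phenotype(default_parameters(), "IM"), "CAD_DM")
  expect_equal(a$species$CLOP$cyp$vmax, b$species$CLOP$cyp$vmax)
  expect_equal(a$species$OXO$cyp$vmax, b$species$OXO$cyp$vmax)
})

test_that("microsomal scaling factor is liver weight times yield", {
  expect_identical(pbsf_from_liver(1378, 40), 55120)
  expect_identical(pbsf_from_liver(1000, 40), 40000)
  expect_error(pbsf_from_liver(0, 40), "positive")
  expect_error(pbsf_from_liver(1378, -1), "positive")
  expect_identical(default_parameters()$pbsf, 55120)
})

test_that("perturbation helper scales the right group and nothing else", {
  mp <- default_parameters()
  p <- perturb_parameters(mp, "kt_all", 2)
  expect_equal(p$kt0, 9.6)
  expect_equal(p$gut$kt, mp$gut$kt * 2)
  expect_identical(p$gut$ka, mp$gut$ka)
  p <- perturb_parameters(mp, "clint_ces1", 0.5)
  expect_equal(p$species$OXO$clint_ces1, 1100)
  expect_identical(p$species$OXO$cyp, mp$species$OXO$cyp)
  expect_error(perturb_parameters(mp, "nope", 1), "unknown")
  expect_error(perturb_parameters(mp, "kt_all", 0), "positive")
  # unknown enzyme in a user preset is rejected
  pre <- population_preset("CAD_DM")
  pre$enzyme_multipliers <- c(CYP9Z9 = 2)
  expect_error(apply_population(default_parameters(), pre), "absent")
})

test_that("provenance table covers the headline constants", {
  tab <- param_provenance()
  expect_true(all(c("parameter", "value", "units", "source") %in% names(tab)))
  get1 <- function(p) tab$value[tab$parameter == p]
  expect_identical(get1("tissues.liver.volume"), 1.38)
  expect_identical(get1("tissues.liver.blood_flow"), 0.42)
  expect_identical(get1("pbsf"), 55120)
  expect_identical(get1("species.AM.clint_ces1"), 529)
  expect_identical(get1("gut.duodenum.kt"), 4.2)
  expect_identical(get1("pd.kirre"), 47.576)
})
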