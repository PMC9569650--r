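rc <- randomCoilModel()

test_that("secondary shifts subtract the residue-specific random-coil value", {
  obs <- makeShiftTable("p", c(1, 1, 2), c("GLU", "GLU", "LYS"),
                        c("CA", "HA", "CA"), c(56.6, 4.10, 56.2))
  sec <- secondaryShifts(obs, rc)
  d <- secondaryDeltas(sec)
  # identity case: observed equals the reference
  expect_equal(d$delta_ppm[d$residue_index == 1 & d$atom_name == "CA"], 0)
  expect_equal(d$delta_ppm[d$residue_index == 2 & d$atom_name == "CA"], 0)
  # hand subtraction against the packaged table entry (GLU HA = 4.35)
  expect_equal(d$delta_ppm[d$atom_name == "HA"], 4.10 - 4.35)
})

test_that("non-standard residues are referenced through the alias map", {
  obs <- makeShiftTable("p", c(1, 2), c("HCIT", "DGLU"), c("CA", "CA"),
                        c(56.2, 56.6))
  sec <- secondaryShifts(obs, rc)
  d <- secondaryDeltas(sec)
  expect_equal(d$delta_ppm, c(0, 0))  # LYS and GLU reference values
  bad <- makeShiftTable("p", 1, "XYZ", "CA", 50)
  expect_error(secondaryShifts(bad, rc), "XYZ")
})

test_that("missing cells propagate as missing and never become zero", {
  obs <- makeShiftTable("p", c(1, 2, 2), c("ALA", "ALA", "ALA"),
                        c("CA", "CA", "CB"), c(52.5, 54.5, 19.1))
  sec <- secondaryShifts(obs, rc)
  cc <- caCbDifference(sec)
  expect_true(is.na(cc$delta_ca_cb[cc$residue_index == 1]))  # CB unassigned
  expect_equal(cc$delta_ca_cb[cc$residue_index == 2], 2.0)
  expect_equal(nrow(secondaryDeltas(sec)), 3L)
})

test_that("secondary shifts are anti-symmetric in observation and reference", {
  set.seed(42)
  resn <- c("ALA", "LYS", "SER", "GLU")  # one residue per type so roles swap cleanly
  obsShift <- rnorm(4, 55, 3)
  obs <- makeShiftTable("p", 1:4, resn, rep("CA", 4), obsShift)
  d1 <- secondaryDeltas(secondaryShifts(obs, rc))$delta_ppm
  # swapped roles: observe the reference values against a model built from obs
  obs2 <- makeShiftTable("p", 1:4, resn, rep("CA", 4),
                         randomCoilShift(rc, resn, rep("CA", 4)))
  swapTab <- rc@table
  swapTab$shift_ppm[match(paste(resn, "CA"),
                          paste(swapTab$residue_name, swapTab$atom_name))] <- obsShift
  rc2 <- new("RandomCoilModel", id = "swap", table = swapTab,
             aliases = rc@aliases, temperatureK = 298, pH = 5)
  d2 <- secondaryDeltas(secondaryShifts(obs2, rc2))$delta_ppm
  expect_equal(d1, -d2, tolerance = 1e-12)
})

test_that("structure calling needs sustained runs beyond the 2 ppm band", {
  mk <- function(vals) {
    n <- length(vals)
    obs <- makeShiftTable("p", rep(1:n, 2), rep("ALA", 2 * n),
                          rep(c("CA", "CB"), each = n),
                          c(52.5 + vals, rep(19.1, n)))
    secondaryShifts(obs, rc)
  }
  # everything within +/-2 ppm: all coil
  allIn <- callSecondaryStructure(mk(c(1.5, -1.9, 0.3, 1.2, -0.5)), window = 3)
  expect_true(all(allIn$call == "coil"))
  # four consecutive values of +3 with window 3: helix
  hel <- callSecondaryStructure(mk(c(0, 3, 3, 3, 3, 0)), window = 3)
  expect_equal(hel$call, c("coil", rep("helix", 4), "coil"))
  # alternating +3/-3 never sustains a run of 3
  alt <- callSecondaryStructure(mk(rep(c(3, -3), 4)), window = 3)
  expect_true(all(alt$call == "coil"))
  # strand mirror
  str <- callSecondaryStructure(mk(c(-3, -3, -3, 0)), window = 3)
  expect_equal(str$call, c(rep("strand", 3), "coil"))
  expect_error(callSecondaryStructure(mk(c(0, 0)), window = 1), "window")
})

test_that("calls are stable under perturbations inside the coil band", {
  set.seed(7)
  base <- c(3, 3, 3, 0.5, -0.5, 1.0, -3, -3, -3)
  for (i in 1:5) {
    pert <- base
    inBand <- abs(base) < 2
    pert[inBand] <- runif(sum(inBand), -1.99, 1.99)
    obs <- makeShiftTable("p", rep(seq_along(pert), 2),
                          rep("ALA", 2 * length(pert)),
                          rep(c("CA", "CB"), each = length(pert)),
                          c(52.5 + pert, rep(19.1, length(pert))))
    calls <- callSecondaryStructure(secondaryShifts(obs, rc), window = 3)
    expect_equal(calls$call, c(rep("helix", 3), rep("coil", 3), rep("strand", 3)))
  }
})

test_that("proline configuration follows the Cb-Cg difference bands", {
  trans <- classifyProline(32.0, 27.0)
  expect_equal(trans$delta_bg_ppm, 5.0)
  expect_equal(trans$configuration, "trans")
  cis <- classifyProline(35.0, 25.0)
  expect_equal(cis$delta_bg_ppm, 10.0)
  expect_equal(cis$configuration, "cis")
  amb <- classifyProline(32.0, 25.0)
  expect_equal(amb$delta_bg_ppm, 7.0)
  expect_equal(amb$configuration, "ambiguous")
  expect_error(classifyProline(32, 27, residueName = "ALA"), "proline")
  # referencing offset cancels: adding a constant to both shifts changes nothing
  shifted <- classifyProline(32.0 + 1.7, 27.0 + 1.7)
  expect_equal(shifted$configuration, "trans")
  expect_equal(shifted$delta_bg_ppm, 5.0)
})

test_that("prolineRecords classifies every fully assigned proline in a table", {
  obs <- makeShiftTable("p", c(9, 9, 13, 13, 14),
                        c("PRO", "PRO", "PRO", "PRO", "HIS"),
                        c("CB", "CG", "CB", "CG", "CA"),
                        c(32.1, 27.2, 34.5, 24.8, 55.0))
  out <- prolineRecords(obs)
  expect_equal(out$residue_index, c(9L, 13L))
  expect_equal(out$configuration, c("trans", "cis"))
})

test_that("cis population is the intensity fraction and complements to one", {
  expect_equal(cisPopulation(1, 9), 0.10)
  expect_equal(cisPopulation(0, 5), 0)
  expect_equal(cisPopulation(0.05, 0.95), 0.05)
  f <- cisPopulation(0.37, 2.1)
  expect_equal(f + cisPopulation(2.1, 0.37), 1)  # trans fraction is 1 - cis
  expect_error(cisPopulation(-1, 2), "non-negative")
  expect_warning(res <- cisPopulation(0, 0), "undefined")
  expect_true(is.na(res))
})

test_that("combined CSP matches the weighted root-mean-square by hand", {
  a <- makeShiftTable("a", c(1, 1, 2), c("ALA", "ALA", "GLY"),
                      c("H", "N", "HA"), c(8.2, 120.0, 3.96))
  b <- makeShiftTable("b", c(1, 1, 2), c("ALA", "ALA", "GLY"),
                      c("H", "N", "HA"), c(8.5, 121.0, 3.96))
  p <- combinedCSP(a, b)
  # residue 1 by hand: sqrt(((1*0.3)^2 + (0.154*1.0)^2) / 2)
  expect_equal(cspProfile(p)$csp_ppm[1],
               sqrt(((1 * 0.3)^2 + (0.154 * 1.0)^2) / 2))
  expect_equal(cspProfile(p)$csp_ppm[2], 0)
  # single differing nucleus with weight 1 reduces to the plain difference
  p1 <- combinedCSP(makeShiftTable("a", 1, "ALA", "H", 8.0),
                    makeShiftTable("b", 1, "ALA", "H", 8.4))
  expect_equal(cspProfile(p1)$csp_ppm, 0.4)
  # symmetry and identity
  expect_equal(cspProfile(combinedCSP(b, a))$csp_ppm, cspProfile(p)$csp_ppm)
  expect_true(all(cspProfile(combinedCSP(a, a))$csp_ppm == 0))
  noShare <- makeShiftTable("c", 5, "ALA", "H", 8.0)
  expect_error(combinedCSP(a, noShare), "share no")
})

test_that("CSP flags are consistent with the profile mean and SD", {
  set.seed(11)
  n <- 10
  a <- makeShiftTable("a", 1:n, rep("ALA", n), rep("H", n), rnorm(n, 8.2, 0.01))
  b <- makeShiftTable("b", 1:n, rep("ALA", n), rep("H", n), rnorm(n, 8.2, 0.15))
  p <- combinedCSP(a, b)
  pr <- cspProfile(p)
  mu <- mean(pr$csp_ppm); s <- sd(pr$csp_ppm)
  expect_equal(p@mean, mu)
  expect_equal(pr$flag, ifelse(pr$csp_ppm >= mu + s, "above_avg_plus_sd",
                               ifelse(pr$csp_ppm >= mu, "above_avg", "below_avg")))
})
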