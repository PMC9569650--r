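test_that("the Karplus relation reduces, wraps, and matches a grid oracle", {
  const <- karplusParams(A = 0, B = 0, C = 1.6)
  expect_equal(karplusJ(c(-180, -60, 0, 55, 180), const), rep(1.6, 5))
  p <- karplusParams("bax1997")
  expect_equal(karplusJ(-65, p), karplusJ(-65 + 360, p))
  expect_equal(karplusJ(170, p), karplusJ(170 - 360, p))
  # independent 1-degree-grid trigonometric oracle over the full circle
  grid <- seq(-180, 180, by = 1)
  expect_equal(karplusJ(grid, p),
               oracleKarplus(grid, 7.09, -1.42, 1.55), tolerance = 1e-12)
  # extremes bounded by the analytic envelope, located by the grid
  expect_lte(max(karplusJ(grid, p)), 7.09 + abs(-1.42) + 1.55 + 1e-9)
  expect_gte(min(karplusJ(grid, p)), 1.55 - abs(-1.42) + min(0, 7.09) - 1e-9)
})

test_that("unknown presets fail and preset coefficients load as published", {
  expect_error(karplusParams("nope"), "preset")
  p93 <- karplusParams("bax1993")
  expect_equal(c(p93@A, p93@B, p93@C), c(6.51, -1.76, 1.60))
  expect_equal(p93@id, "bax1993")
})

test_that("circular mean averages on the circle, not the line", {
  expect_equal(circularMeanDeg(c(10, -10)), 0)
  expect_equal(circularMeanDeg(c(170, -170)), 180)
  expect_true(is.na(circularMeanDeg(numeric(0))))
  # independent complex-argument oracle on random angle sets
  set.seed(3)
  for (i in 1:10) {
    th <- runif(50, -180, 180)
    oracle <- Arg(mean(exp(1i * th * pi / 180))) * 180 / pi
    expect_equal(circularMeanDeg(th), oracle, tolerance = 1e-10)
  }
})

test_that("ensemble couplings use the circular mean phi per residue", {
  p <- karplusParams()
  seqv <- c("ALA", "LYS", "GLU", "SER")
  # single conformer: identical to the pointwise Karplus value
  e1 <- makeDihedralEnsemble(c(0, -63, -120, -70), c(-42, -40, 130, 150), seqv)
  j1 <- ensembleJ(e1, p)
  expect_equal(j1$j_pred_hz[2], karplusJ(-63, p), tolerance = 1e-6)
  expect_true(is.na(j1$j_pred_hz[1]))  # first residue has no phi
  # two conformers at +/-10 about -63: J at the circular mean -63
  e2 <- makeDihedralEnsemble(rbind(c(0, -53, -120, -70), c(0, -73, -120, -70)),
                             rbind(c(-42, -40, 130, 150), c(-42, -40, 130, 150)),
                             seqv)
  expect_equal(ensembleJ(e2, p)$j_pred_hz[2], karplusJ(-63, p), tolerance = 1e-6)
  # prolines are excluded (no amide proton)
  ePro <- makeDihedralEnsemble(c(0, -63, -70), c(-42, -40, 150),
                               c("ALA", "PRO", "ALA"))
  expect_true(is.na(ensembleJ(ePro, p)$j_pred_hz[2]))
})

test_that("wrapped-normal ensembles reproduce the vector-mean coupling", {
  p <- karplusParams()
  set.seed(21)
  M <- 50
  phi2 <- (rnorm(M, -170, 20) + 180) %% 360 - 180  # straddles the wrap
  phi <- cbind(0, phi2, -70)
  psi <- cbind(-40, 140, matrix(150, M, 1))
  e <- makeDihedralEnsemble(phi, psi, c("ALA", "LYS", "GLU"))
  oracleMean <- Arg(mean(exp(1i * phi2 * pi / 180))) * 180 / pi
  expect_equal(ensembleJ(e, p)$j_pred_hz[2], karplusJ(oracleMean, p),
               tolerance = 1e-6)
})

test_that("coupling validation reports r, rms deviation and degeneracies", {
  obs <- c(5.5, 6.2, 7.8, 6.9, 7.1)
  expect_equal(validateJ(obs, obs)$r, 1.0)
  expect_equal(validateJ(obs, -obs + 14)$r, -1.0)
  # five-point toy against the textbook covariance formula by hand
  pred <- c(5.9, 6.0, 7.5, 7.2, 6.8)
  rHand <- sum((obs - mean(obs)) * (pred - mean(pred))) /
    sqrt(sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2))
  v <- validateJ(obs, pred)
  expect_equal(v$r, rHand, tolerance = 1e-12)
  expect_equal(v$rmsd_hz, sqrt(mean((obs - pred)^2)))
  expect_equal(v$n, 5L)
  expect_warning(v2 <- validateJ(obs[1:2], pred[1:2]), "fewer than 3")
  expect_true(is.na(v2$r))
  expect_warning(v3 <- validateJ(obs, rep(7, 5)), "zero variance")
  expect_true(is.na(v3$r))
})

test_that("validation is invariant under common reordering of the pairs", {
  set.seed(9)
  obs <- runif(8, 5, 9); pred <- obs + rnorm(8, 0, 0.4)
  ord <- sample(8)
  expect_equal(validateJ(obs, pred)$r, validateJ(obs[ord], pred[ord])$r)
})

test_that("temperature coefficients are exact on noiseless lines", {
  temps <- seq(298, 310, by = 2)
  s <- data.frame(residue_index = 1, temperature_K = temps,
                  shift_ppm = 8.0 - 5.0e-3 * (temps - 298))
  fit <- fitTempCoefficient(s)
  expect_equal(fit$slope_ppb_per_K, -5.0, tolerance = 1e-10)
  expect_equal(fit$class, "solvent_exposed")
})

test_that("classification follows the -4.6 ppb/K boundary convention", {
  temps <- seq(298, 310, by = 2)
  mk <- function(slopePpb) data.frame(
    residue_index = 1, temperature_K = temps,
    shift_ppm = 8.3 + slopePpb * 1e-3 * (temps - 298))
  expect_equal(fitTempCoefficient(mk(-3.5))$class, "hbond_protected")
  expect_equal(fitTempCoefficient(mk(-7.0))$class, "solvent_exposed")
  expect_equal(fitTempCoefficient(mk(-4.6))$class, "solvent_exposed")  # boundary
  expect_equal(fitTempCoefficient(mk(1.2))$class, "exchange_or_aromatic")
})

test_that("noisy series recover the true gradient within two standard errors", {
  s <- simulateTempSeries(c(`1` = -6.0), temps = seq(298, 310, by = 2),
                          sigmaPpb = 2, seed = 13)
  fit <- fitTempCoefficient(s)
  expect_lt(abs(fit$slope_ppb_per_K - (-6.0)), 2 * fit$se_ppb_per_K)
  # closed-form normal-equations oracle for the same data
  x <- s$temperature_K; y <- s$shift_ppm * 1000
  bHat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$slope_ppb_per_K, bHat, tolerance = 1e-9)
})

test_that("degenerate temperature series are rejected", {
  expect_error(fitTempCoefficient(data.frame(
    residue_index = 1, temperature_K = c(298, 300), shift_ppm = c(8, 8.1))),
    "at least 3")
  expect_error(fitTempCoefficient(data.frame(
    residue_index = 1, temperature_K = rep(298, 4), shift_ppm = 8:11 / 1)),
    "single temperature")
})
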