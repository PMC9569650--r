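rc <- randomCoilModel()
toy <- toyShiftPredictor(rc)

test_that("pairwise RMSD is zero for identical or rigidly moved models", {
  e <- makeDihedralEnsemble(rbind(c(0, -63, -70), c(0, -63, -70)),
                            rbind(c(-42, -40, 150), c(-42, -40, 150)),
                            c("ALA", "LYS", "GLU"))
  d <- pairwiseRmsd(e)
  expect_equal(d, matrix(0, 2, 2))
  # a rigid rotation + translation superposes away entirely
  eRot <- rotateModel(e, 2)
  dRot <- pairwiseRmsd(eRot, atomSelection = c("N", "CA", "C", "O"))
  expect_equal(max(abs(dRot)), 0, tolerance = 1e-6)
})

test_that("pairwise RMSD agrees with a brute-force rotation-grid oracle", {
  set.seed(5)
  A <- matrix(rnorm(9, sd = 2), 3, 3)
  B <- A + matrix(rnorm(9, sd = 0.6), 3, 3)
  atoms <- data.frame(residue_index = 1:3, residue_name = "GLY",
                      atom_name = "CA")
  e <- ConformerEnsemble("toy3", atoms,
                         rbind(as.vector(t(A)), as.vector(t(B))))
  d <- pairwiseRmsd(e)
  expect_equal(d[1, 2], oracleFitRmsd(A, B), tolerance = 1e-4)
  expect_equal(d[1, 2], d[2, 1])
  expect_equal(diag(d), c(0, 0))
})

test_that("Kelley penalty separates two tight groups into two clusters", {
  set.seed(1)
  pts <- rbind(matrix(rnorm(24, 0, 0.1), ncol = 2),
               matrix(rnorm(24, 6, 0.1), ncol = 2))
  d <- as.matrix(dist(pts))
  cl <- kelleyCluster(d)
  expect_equal(cl@chosenK, 2L)
  expect_equal(length(unique(clusterLabels(cl)[1:12])), 1L)
  expect_equal(length(unique(clusterLabels(cl)[13:24])), 1L)
  # exhaustive recomputation of the penalty at every cut level
  tree <- hclust(as.dist(d), method = "average")
  M <- nrow(d)
  avg <- sapply(1:(M - 1), function(k) {
    lab <- cutree(tree, k = k)
    sp <- sapply(unique(lab), function(g) {
      i <- which(lab == g)
      if (length(i) < 2) NA_real_ else mean(as.dist(d[i, i]))
    })
    if (all(is.na(sp))) 0 else mean(sp, na.rm = TRUE)
  })
  norm <- (M - 2) * (avg - min(avg)) / diff(range(avg)) + 1
  expect_equal(clusterLevels(cl)$penalty, unname(norm + 1:(M - 1)),
               tolerance = 1e-12)
  expect_equal(which.min(norm + 1:(M - 1)), 2L)
  # medoids belong to their clusters
  expect_true(all(clusterLabels(cl)[clusterMedoids(cl)] ==
                  as.integer(names(clusterMedoids(cl)))))
})

test_that("degenerate and permuted clustering inputs behave predictably", {
  dZero <- matrix(0, 6, 6)
  expect_equal(kelleyCluster(dZero)@chosenK, 1L)
  expect_warning(tiny <- kelleyCluster(matrix(0, 2, 2)), "fewer than 3")
  expect_equal(tiny@chosenK, 1L)
  set.seed(2)
  pts <- rbind(matrix(rnorm(16, 0, 0.2), ncol = 2),
               matrix(rnorm(16, 5, 0.2), ncol = 2))
  d <- as.matrix(dist(pts))
  perm <- sample(16)
  clP <- kelleyCluster(d[perm, perm])
  cl <- kelleyCluster(d)
  # membership invariant up to label names
  expect_equal(clP@chosenK, cl@chosenK)
  expect_true(all(table(clusterLabels(cl)) %in% table(clusterLabels(clP))))
})

test_that("the toy predictor is offset-free in the coil basin and deterministic", {
  coil <- makeDihedralEnsemble(c(0, -70, -70, -70), c(150, 150, 150, 150),
                               c("ALA", "LYS", "GLU", "SER"))
  tab <- predictShifts(toy, coil, 1)
  s <- shifts(tab)
  ref <- randomCoilShift(rc, s$residue_name, s$atom_name)
  expect_equal(s$shift_ppm, ref, tolerance = 1e-12)
  expect_identical(shifts(predictShifts(toy, coil, 1)), s)
})

test_that("helix-basin offsets match the documented offset table by hand", {
  helix <- makeDihedralEnsemble(rep(-63, 5), rep(-42, 5),
                                c("ALA", "LYS", "GLU", "SER", "MET"))
  s <- shifts(predictShifts(toy, helix, 1))
  off <- basinOffsets()
  for (nuc in c("CA", "CB", "HA", "H", "N")) {
    got <- s$shift_ppm[s$residue_index == 3 & s$atom_name == nuc]
    expect_equal(got, randomCoilShift(rc, "GLU", nuc) +
                 off$helix[off$atom_name == nuc])
  }
  # helix lowers HA and raises CA relative to random coil
  expect_lt(s$shift_ppm[s$residue_index == 3 & s$atom_name == "HA"],
            randomCoilShift(rc, "GLU", "HA"))
  expect_gt(s$shift_ppm[s$residue_index == 3 & s$atom_name == "CA"],
            randomCoilShift(rc, "GLU", "CA"))
})

test_that("global CS-RMSD sums per-class root-mean-squares over shared cells", {
  a <- makeShiftTable("x", c(1, 2, 1), c("ALA", "LYS", "ALA"),
                      c("CA", "CA", "H"), c(52.5, 56.2, 8.24))
  expect_equal(globalCsRmsd(a, a)$global, 0)
  # single cell differing by 0.5 ppm
  b1 <- makeShiftTable("x", 1, "ALA", "CA", 52.5)
  b2 <- makeShiftTable("x", 1, "ALA", "CA", 53.0)
  expect_equal(globalCsRmsd(b1, b2)$global, 0.5)
  # two-class toy: hand-summed per-class RMS
  pred <- makeShiftTable("x", c(1, 2, 1), c("ALA", "LYS", "ALA"),
                         c("CA", "CA", "H"), c(52.9, 55.9, 8.14))
  got <- globalCsRmsd(a, pred)
  handCa <- sqrt(mean(c(0.4, -0.3)^2))
  handHN <- sqrt(mean(0.1^2))
  expect_equal(unname(got$perClass["Ca"]), handCa)
  expect_equal(got$global, handCa + handHN, tolerance = 1e-12)
  expect_true("Cb" %in% got$skippedClasses)
  noShare <- makeShiftTable("x", 9, "ALA", "CA", 50)
  expect_error(globalCsRmsd(a, noShare), "no shared")
})

test_that("global CS-RMSD and Q are invariant under residue reordering", {
  set.seed(8)
  n <- 6
  mk <- function(vals, ord = 1:n) makeShiftTable(
    "x", (1:n)[ord], rep("ALA", n)[ord], rep("CA", n)[ord], vals[ord])
  o <- rnorm(n, 52, 1); p <- o + rnorm(n, 0, 0.3)
  ord <- sample(n)
  expect_equal(globalCsRmsd(mk(o), mk(p))$global,
               globalCsRmsd(mk(o, ord), mk(p, ord))$global)
  so <- secondaryShifts(mk(o), rc); sp <- secondaryShifts(mk(p), rc)
  soP <- secondaryShifts(mk(o, ord), rc); spP <- secondaryShifts(mk(p, ord), rc)
  expect_equal(qFactor(so, sp)$pooled, qFactor(soP, spP)$pooled)
})

test_that("Q factor follows its defining ratio", {
  dObs <- c(1.2, -0.8, 0.4, 2.0)
  expect_equal(qFactor(dObs, dObs)$pooled, 0)
  expect_equal(qFactor(dObs, rep(0, 4))$pooled, 1)
  dPred <- c(1.0, -0.5, 0.6, 1.5)
  hand <- sqrt(mean((dObs - dPred)^2)) / sqrt(mean(dObs^2))
  expect_equal(qFactor(dObs, dPred)$pooled, hand, tolerance = 1e-12)
  expect_warning(q0 <- qFactor(rep(0, 4), dPred)$pooled, "undefined")
  expect_true(is.na(q0))
})

test_that("selection modes partition the ranking as requested", {
  set.seed(31)
  inst <- recoveryInstance(seed = 77, nConformers = 24, nTrue = 6)
  rank <- scoreConformers(inst$ensemble, inst$obs, toy)
  # ranking is sorted, deterministic, tie-broken by conformer id
  expect_true(!is.unsorted(rank$global_cs_rmsd))
  sel <- selectEnsemble(inst$ensemble, inst$obs, n = 6, mode = "lowest",
                        ranking = rank)
  expect_equal(selectedConformers(sel), rank$conformer[1:6])
  selH <- selectEnsemble(inst$ensemble, inst$obs, n = 6, mode = "highest",
                         ranking = rank)
  expect_equal(sort(selH@ranking$global_cs_rmsd[match(selectedConformers(selH),
                                                      selH@ranking$conformer)]),
               sort(tail(rank$global_cs_rmsd, 6)))
  # exhaustion: N = |reps| makes all three modes select the same set
  all1 <- selectEnsemble(inst$ensemble, inst$obs, n = 24, mode = "lowest", ranking = rank)
  all2 <- selectEnsemble(inst$ensemble, inst$obs, n = 24, mode = "highest", ranking = rank)
  all3 <- selectEnsemble(inst$ensemble, inst$obs, n = 24, mode = "random",
                         seed = 3, ranking = rank)
  expect_equal(sort(selectedConformers(all1)), sort(selectedConformers(all2)))
  expect_equal(sort(selectedConformers(all1)), sort(selectedConformers(all3)))
  # over-asking selects everything with a warning
  expect_warning(over <- selectEnsemble(inst$ensemble, inst$obs, n = 99,
                                        ranking = rank), "selecting all")
  expect_equal(length(selectedConformers(over)), 24L)
  # random mode is reproducible from its seed
  r1 <- selectEnsemble(inst$ensemble, inst$obs, n = 6, mode = "random",
                       seed = 11, ranking = rank)
  r2 <- selectEnsemble(inst$ensemble, inst$obs, n = 6, mode = "random",
                       seed = 11, ranking = rank)
  expect_identical(selectedConformers(r1), selectedConformers(r2))
})

test_that("the selected ensemble beats any single conformer on averaged data", {
  inst <- recoveryInstance(seed = 55, nConformers = 60, nTrue = 15)
  sel <- selectEnsemble(inst$ensemble, inst$obs, n = 15, mode = "lowest")
  best <- min(selectionRanking(sel)$global_cs_rmsd)
  expect_lte(ensembleScore(sel), best)
})
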