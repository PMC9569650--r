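# fixtures built in code; no files, no network

# ensemble with backbone built from explicit dihedrals (one row per model)
makeDihedralEnsemble <- function(phi, psi, sequence, id = "fixture",
                                 cyclicHead = FALSE) {
  phi <- rbind(phi); psi <- rbind(psi)
  nres <- length(sequence)
  stopifnot(ncol(phi) == nres, ncol(psi) == nres)
  xyz <- t(vapply(seq_len(nrow(phi)), function(m)
    as.vector(t(buildBackboneXyz(phi[m, ], psi[m, ]))), numeric(3 * 4 * nres)))
  atoms <- data.frame(residue_index = rep(seq_len(nres), each = 4),
                      residue_name = rep(sequence, each = 4),
                      atom_name = rep(c("N", "CA", "C", "O"), nres))
  ConformerEnsemble(id, atoms, xyz, cyclicHead = cyclicHead)
}

# minimal shift table from vectors
makeShiftTable <- function(id, residue_index, residue_name, atom_name, shift_ppm) {
  ShiftTable(id, data.frame(residue_index = residue_index,
                            residue_name = residue_name,
                            atom_name = atom_name, shift_ppm = shift_ppm))
}

# apply a rigid rotation + translation to one model of an ensemble
rotateModel <- function(ensemble, model, axisAngleDeg = 35, shift = c(3, -2, 7)) {
  th <- axisAngleDeg * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- ensembleXyz(ensemble)
  co <- matrix(xyz[model, ], ncol = 3, byrow = TRUE)
  co <- co %*% R + matrix(shift, nrow(co), 3, byrow = TRUE)
  xyz[model, ] <- as.vector(t(co))
  ConformerEnsemble(peptideId(ensemble), ensembleAtoms(ensemble), xyz,
                    cyclicHead = ensemble@cyclicHead)
}

# independent trigonometric evaluation of the coupling polynomial,
# written via the double-angle identity so it shares no code path with
# karplusJ
oracleKarplus <- function(phi, A, B, C, theta0 = -60) {
  d <- (phi + theta0) * pi / 180
  A * (1 + cos(2 * d)) / 2 + B * cos(d) + C
}

# brute-force optimal-superposition RMSD: coarse Euler-angle grid plus
# Nelder-Mead refinement; independent of the Kabsch/SVD route
oracleFitRmsd <- function(A, B, gridStep = 20) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  rotmat <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    Rz1 <- matrix(c(ca[1], -sa[1], 0, sa[1], ca[1], 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(ca[2], 0, sa[2], 0, 1, 0, -sa[2], 0, ca[2]), 3, 3)
    Rz2 <- matrix(c(ca[3], -sa[3], 0, sa[3], ca[3], 0, 0, 0, 1), 3, 3)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(ang) sqrt(mean(rowSums((A - B %*% rotmat(ang))^2)))
  grid <- seq(0, 2 * pi, by = gridStep * pi / 180)
  cand <- list()
  for (a1 in grid) for (a2 in grid[grid <= pi]) for (a3 in grid)
    cand[[length(cand) + 1L]] <- c(a1, a2, a3, obj(c(a1, a2, a3)))
  cand <- do.call(rbind, cand)
  starts <- cand[order(cand[, 4]), , drop = FALSE][1:8, 1:3, drop = FALSE]
  min(apply(starts, 1, function(s)
    stats::optim(s, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 20000))$value))
}
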