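#' Sequences of the studied RGD peptides
#'
#' Three-letter residue sequences of the truncated (14-residue) and
#' pseudopeptide (19-residue) variants of the bifunctional RGD peptide:
#' a cyclic c[Lys-Arg-Gly-Asp-DGlu] integrin-binding head followed by the
#' acyclic tail.  The D-glutamate is coded \code{DGLU} and homocitrulline
#' \code{HCIT}.
#'
#' @return character vector of 3-letter residue codes.
#' @export
rgdechi114Sequence <- function() {
  c("LYS", "ARG", "GLY", "ASP", "DGLU", "MET", "ASP", "ASP", "PRO",
    "GLY", "ARG", "ASN", "PRO", "HIS")
}

#' @rdname rgdechi114Sequence
#' @export
psiRgdechiSequence <- function() {
  c(rgdechi114Sequence(), "HCIT", "GLY", "PRO", "ALA", "THR")
}

#' Study conditions for the synthetic-data generator
#'
#' Bundles everything the generator needs: the peptide sequence, the number
#' of candidate conformers, the size of the hidden true sub-ensemble, the
#' dihedral-basin populations of true and decoy conformers, the measurement
#' noise on simulated shifts, the cyclic-head closure, and the seed.  The
#' defaults are the packaged study conditions: 400 candidates with a hidden
#' helix-biased sub-ensemble of 50, 0.05 ppm shift noise, and the 14-residue
#' cyclic-head peptide.
#'
#' @param sequence 3-letter residue codes.
#' @param nConformers number of conformers to generate.
#' @param nTrue size of the hidden true sub-ensemble.
#' @param truePopulations,decoyPopulations named helix/strand/coil
#'   populations (sum to 1) for true and decoy conformers.
#' @param shiftSigma Gaussian noise SD (ppm) for simulated observed shifts.
#' @param cyclicHead enforce the loose cyclic-head closure on residues 1-5.
#' @param closureMaxDist CA1-CA5 acceptance distance in Angstrom.
#' @param seed base seed (all stochastic output is a pure function of it).
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(sequence = rgdechi114Sequence(),
                          nConformers = 400L, nTrue = 50L,
                          truePopulations = c(helix = 0.80, strand = 0.05, coil = 0.15),
                          decoyPopulations = c(helix = 0.10, strand = 0.20, coil = 0.70),
                          shiftSigma = 0.05, cyclicHead = TRUE,
                          closureMaxDist = 10, seed = 101L) {
  new("SyntheticSpec", sequence = toupper(sequence),
      nConformers = as.integer(nConformers), nTrue = as.integer(nTrue),
      truePopulations = truePopulations[c("helix", "strand", "coil")],
      decoyPopulations = decoyPopulations[c("helix", "strand", "coil")],
      shiftSigma = shiftSigma, cyclicHead = isTRUE(cyclicHead),
      closureMaxDist = closureMaxDist, seed = as.numeric(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", length(object@sequence), "residues,",
      object@nConformers, "conformers (true sub-ensemble",
      object@nTrue, "), shift noise", object@shiftSigma, "ppm, seed",
      object@seed, "\n")
})

# wrapped-normal draw (degrees), mapped back to (-180, 180]
.rwrappedNorm <- function(n, mu, sd) {
  x <- (rnorm(n, mu, sd) + 180) %% 360 - 180
  ifelse(x == -180, 180, x)
}

#' Generate an idealized conformer ensemble with ground truth
#'
#' For each conformer and residue a basin (helix/strand/coil) is sampled
#' from the conformer's population vector (true sub-ensemble conformers use
#' \code{truePopulations}, the rest \code{decoyPopulations}); (phi, psi)
#' are drawn from the basin's wrapped normal (centers/widths from the
#' versioned [basinTable()] shared with the toy predictor); backbone
#' coordinates are built from the dihedrals with idealized geometry.  With
#' \code{cyclicHead}, the head dihedrals (residues 1-5) are redrawn until
#' the CA1-CA5 distance satisfies the loose closure surrogate.  The output
#' is a pure function of the spec (incl. its seed).
#'
#' @param spec a [SyntheticSpec-class].
#' @param maxRetries per-conformer cap on closure redraws.
#' @return list with \code{ensemble} (a [ConformerEnsemble-class]) and
#'   \code{groundTruth} (list: \code{trueIds}, \code{basins} M x nres
#'   character matrix, \code{spec}).
#' @export
generateEnsemble <- function(spec, maxRetries = 2000L) {
  stopifnot(is(spec, "SyntheticSpec"))
  set.seed(spec@seed)
  seqv <- spec@sequence
  nres <- length(seqv)
  M <- spec@nConformers
  basins <- basinTable()
  basinNames <- basins$basin
  trueIds <- sort(sample.int(M, spec@nTrue))
  isTrue <- seq_len(M) %in% trueIds
  basinMat <- matrix(NA_character_, M, nres)
  xyz <- matrix(NA_real_, M, 3L * 4L * nres)
  atomNames <- c("N", "CA", "C", "O")
  atoms <- data.frame(residue_index = rep(seq_len(nres), each = 4L),
                      residue_name = rep(seqv, each = 4L),
                      atom_name = rep(atomNames, nres))
  caRow <- function(r) (r - 1L) * 4L + 2L
  for (m in seq_len(M)) {
    pop <- if (isTrue[m]) spec@truePopulations else spec@decoyPopulations
    b <- sample(basinNames, nres, replace = TRUE,
                prob = pop[basinNames])
    drawAngles <- function(which) {
      bi <- match(b[which], basins$basin)
      list(phi = .rwrappedNorm(length(which), basins$phi_center_deg[bi],
                               basins$phi_sd_deg[bi]),
           psi = .rwrappedNorm(length(which), basins$psi_center_deg[bi],
                               basins$psi_sd_deg[bi]))
    }
    ang <- drawAngles(seq_len(nres))
    phi <- ang$phi; psi <- ang$psi
    co <- buildBackboneXyz(phi, psi)
    if (spec@cyclicHead) {
      # rejection sampling of the joint (basins, angles) of the head:
      # the macrocycle genuinely restricts which head conformations exist,
      # so accepted head-residue basin frequencies are conditional on closure
      tries <- 0L
      repeat {
        dCA <- sqrt(sum((co[caRow(1L), ] - co[caRow(5L), ])^2))
        if (dCA <= spec@closureMaxDist) break
        tries <- tries + 1L
        if (tries > maxRetries)
          stop("cyclic-head closure failed for conformer ", m,
               " after ", maxRetries, " redraws (seed ", spec@seed, ")")
        b[1:5] <- sample(basinNames, 5L, replace = TRUE, prob = pop[basinNames])
        redraw <- drawAngles(1:5)
        phi[1:5] <- redraw$phi; psi[1:5] <- redraw$psi
        co <- buildBackboneXyz(phi, psi)
      }
    }
    basinMat[m, ] <- b
    xyz[m, ] <- as.vector(t(co))
  }
  ens <- ConformerEnsemble(
    peptideId = paste0("synthetic-", nres, "mer"),
    atoms = atoms, xyz = xyz, cyclicHead = spec@cyclicHead)
  list(ensemble = ens,
       groundTruth = list(trueIds = trueIds, basins = basinMat, spec = spec))
}

#' Simulate observed chemical shifts from a hidden sub-ensemble
#'
#' The "observed" table is the uniform population average of the
#' toy-predicted shift tables over the true conformers, plus i.i.d.
#' Gaussian measurement noise per cell - exactly the quantity the
#' chemical-shift-driven selection protocol tries to invert.
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param trueIds conformer ids of the hidden true sub-ensemble (non-empty).
#' @param sigma Gaussian noise SD in ppm.
#' @param seed RNG seed for the noise draw.
#' @param predictor predictor used for the forward calculation.
#' @return a [ShiftTable-class].
#' @export
simulateObservedShifts <- function(ensemble, trueIds, sigma = 0.05, seed = 1L,
                                   predictor = toyShiftPredictor()) {
  stopifnot(is(ensemble, "ConformerEnsemble"))
  if (!length(trueIds)) stop("trueIds must be non-empty")
  if (!all(trueIds %in% seq_len(nModels(ensemble))))
    stop("trueIds outside the ensemble")
  tabs <- if (is(predictor, "ToyShiftPredictor")) {
    dh <- phiPsi(ensemble)  # computed once for all true conformers
    lapply(trueIds, function(m) .toyPredictOne(predictor, ensemble, m, dh))
  } else lapply(trueIds, function(m) predictShifts(predictor, ensemble, m))
  avg <- meanShiftTable(tabs, id = paste0(peptideId(ensemble), "-obs"))
  s <- shifts(avg)
  set.seed(seed)
  s$shift_ppm <- s$shift_ppm + rnorm(nrow(s), 0, sigma)
  ShiftTable(peptideId(avg), s)
}

#' Simulate amide-proton temperature series
#'
#' Linear HN shift-versus-temperature series per residue with Gaussian
#' noise, emulating a 1D series over the 298-310 K range.
#'
#' @param slopes named numeric, ppb/K per residue index.
#' @param temps temperatures in K (>= 3 values).
#' @param sigmaPpb Gaussian noise SD in ppb.
#' @param seed RNG seed.
#' @param baseShift HN shift at the first temperature (ppm).
#' @return data.frame with \code{residue_index}, \code{temperature_K},
#'   \code{shift_ppm}.
#' @export
simulateTempSeries <- function(slopes, temps = seq(298, 310, by = 2),
                               sigmaPpb = 0, seed = 1L, baseShift = 8.30) {
  if (length(temps) < 3L) stop("at least 3 temperatures are required")
  set.seed(seed)
  do.call(rbind, lapply(names(slopes), function(ri) {
    delta <- baseShift + slopes[[ri]] * 1e-3 * (temps - temps[1]) +
      rnorm(length(temps), 0, sigmaPpb * 1e-3)
    data.frame(residue_index = as.integer(ri), temperature_K = temps,
               shift_ppm = delta)
  }))
}

#' Simulate proline cis/trans signals
#'
#' Emits trans-like (Cb ~ 32.1, Cg ~ 27.2; delta ~ 5 ppm) and, when the cis
#' fraction is positive, cis-like (Cb ~ 34.5, Cg ~ 24.8; delta ~ 10 ppm)
#' shift pairs with peak intensities proportional to the populations.
#'
#' @param cisFraction cis population in [0, 1].
#' @param residueIndex proline residue number carried into the output.
#' @param sigma optional Gaussian shift noise (ppm).
#' @param seed RNG seed.
#' @return list with \code{intensities} (named cis/trans) and \code{shifts}
#'   (data.frame: form, cb_ppm, cg_ppm).
#' @export
simulateProline <- function(cisFraction, residueIndex = 9L, sigma = 0,
                            seed = 1L) {
  stopifnot(cisFraction >= 0, cisFraction <= 1)
  set.seed(seed)
  forms <- data.frame(form = c("trans", "cis"),
                      cb_ppm = c(32.1, 34.5), cg_ppm = c(27.2, 24.8))
  forms$cb_ppm <- forms$cb_ppm + rnorm(2, 0, sigma)
  forms$cg_ppm <- forms$cg_ppm + rnorm(2, 0, sigma)
  keep <- c(TRUE, cisFraction > 0)
  list(residue_index = as.integer(residueIndex),
       intensities = c(cis = cisFraction, trans = 1 - cisFraction),
       shifts = forms[keep, , drop = FALSE])
}

#' Build the packaged conformer-recovery instance
#'
#' Convenience wrapper generating the study-condition ensemble
#' ([syntheticSpec()] defaults) and its simulated observations: M candidate
#' conformers with a hidden helix-biased true sub-ensemble, observed shifts
#' equal to the true sub-ensemble's population-averaged prediction plus
#' 0.05 ppm noise.
#'
#' @param seed base seed; the ensemble uses it directly, the shift noise
#'   uses \code{seed + 1}.
#' @param ... overrides passed to [syntheticSpec()].
#' @return list with \code{ensemble}, \code{obs}, \code{groundTruth}.
#' @export
recoveryInstance <- function(seed = 101L, ...) {
  spec <- syntheticSpec(seed = seed, ...)
  gen <- generateEnsemble(spec)
  obs <- simulateObservedShifts(gen$ensemble, gen$groundTruth$trueIds,
                                sigma = spec@shiftSigma, seed = seed + 1L)
  list(ensemble = gen$ensemble, obs = obs, groundTruth = gen$groundTruth)
}
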