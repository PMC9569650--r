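#' Run configuration for the end-to-end pipeline
#'
#' Assembles (and optionally reads from a YAML file) the full set of
#' analysis decisions: input paths or objects, preset identifiers, the
#' thresholds of every calling rule, selection parameters and seeds.  Every
#' decision surfaced here is echoed into the output manifest so a run is
#' reproducible from its report bundle alone.
#'
#' @param shifts observed shifts: path to a shift CSV or a
#'   [ShiftTable-class].
#' @param ensemble candidate conformers: path to a multi-model PDB or a
#'   [ConformerEnsemble-class].
#' @param tempSeries optional temperature series (path or data.frame).
#' @param jCoupling optional measured couplings (path or data.frame).
#' @param r2 optional per-residue R2 rates (path or data.frame).
#' @param referenceShifts optional second shift table for a perturbation
#'   profile against a reference peptide variant.
#' @param selectionN,selectionMode,selectionSeed selection parameters.
#' @param ssWindow,ssThreshold secondary-structure calling parameters.
#' @param prolineTransMax,prolineCisMin proline classification bands (ppm).
#' @param tempcoBoundary temperature-coefficient class boundary (ppb/K).
#' @param filterTime,noiseFloor T2-filter parameters (s, fraction).
#' @param randomCoilId,karplusPreset,basinVersion preset identifiers.
#' @param clusterEnsemble cluster the candidates and score medoids only.
#' @return a \code{RunConfig} list (class \code{"RunConfig"}).
#' @export
runConfig <- function(shifts, ensemble, tempSeries = NULL, jCoupling = NULL,
                      r2 = NULL, referenceShifts = NULL,
                      selectionN = 50L, selectionMode = "lowest",
                      selectionSeed = 17L, ssWindow = 3L, ssThreshold = 2,
                      prolineTransMax = 6, prolineCisMin = 8,
                      tempcoBoundary = -4.6, filterTime = 0.250,
                      noiseFloor = 0.1, randomCoilId = "wishart1995",
                      karplusPreset = "bax1997", basinVersion = "v1",
                      clusterEnsemble = FALSE) {
  structure(list(
    shifts = shifts, ensemble = ensemble, tempSeries = tempSeries,
    jCoupling = jCoupling, r2 = r2, referenceShifts = referenceShifts,
    selectionN = as.integer(selectionN), selectionMode = selectionMode,
    selectionSeed = as.integer(selectionSeed), ssWindow = as.integer(ssWindow),
    ssThreshold = ssThreshold, prolineTransMax = prolineTransMax,
    prolineCisMin = prolineCisMin, tempcoBoundary = tempcoBoundary,
    filterTime = filterTime, noiseFloor = noiseFloor,
    randomCoilId = randomCoilId, karplusPreset = karplusPreset,
    basinVersion = basinVersion, clusterEnsemble = isTRUE(clusterEnsemble)),
    class = "RunConfig")
}

#' @rdname runConfig
#' @param path YAML file whose keys mirror the [runConfig()] arguments.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(runConfig, y)
}

.loadInput <- function(x, reader) {
  if (is.null(x) || !is.character(x)) return(x)
  reader(x)
}

#' Run the full conformational-analysis pipeline
#'
#' Orchestrates the workflow end to end: secondary shifts and structure
#' calls, proline configuration, optional temperature-coefficient and
#' perturbation analyses, optional clustering of the candidate ensemble,
#' chemical-shift-RMSD selection, Q-factor and (when measured couplings are
#' supplied) 3JHNHa validation, and dynamics metrics.  Per-stage CSVs, the
#' selected sub-ensemble PDB and a JSON manifest recording every preset,
#' threshold and seed are written into a fresh \code{outDir}; inputs are
#' never modified.  Missing optional inputs degrade the validation to
#' "partial" rather than failing; a stage failure halts with the stage
#' name.
#'
#' @param config a \code{RunConfig} from [runConfig()] / [readRunConfig()].
#' @param outDir output directory (created; must not pre-exist).
#' @return invisible list of the in-memory stage results.
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "RunConfig"))
  if (dir.exists(outDir)) stop("output directory already exists: ", outDir)
  dir.create(outDir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list()
  obs <- stage("read_shifts", .loadInput(config$shifts, readShiftTable))
  ens <- stage("read_ensemble", .loadInput(config$ensemble, readPdbEnsemble))
  rc <- randomCoilModel(config$randomCoilId)

  sec <- stage("secondary_shifts", secondaryShifts(obs, rc))
  res$secondary <- sec
  write.csv(secondaryDeltas(sec), file.path(outDir, "secondary_shifts.csv"),
            row.names = FALSE)
  ss <- stage("structure_calls",
              callSecondaryStructure(sec, config$ssWindow, config$ssThreshold))
  res$structureCalls <- ss
  write.csv(ss, file.path(outDir, "structure_calls.csv"), row.names = FALSE)

  pro <- stage("proline", prolineRecords(obs, transMax = config$prolineTransMax,
                                         cisMin = config$prolineCisMin))
  res$prolines <- pro
  write.csv(pro, file.path(outDir, "prolines.csv"), row.names = FALSE)

  if (!is.null(config$tempSeries)) {
    ts <- stage("tempco", fitTempCoefficient(
      .loadInput(config$tempSeries, readTempSeries), config$tempcoBoundary))
    res$tempco <- ts
    write.csv(ts, file.path(outDir, "tempco.csv"), row.names = FALSE)
  }
  if (!is.null(config$referenceShifts)) {
    csp <- stage("csp", combinedCSP(
      obs, .loadInput(config$referenceShifts, readShiftTable)))
    res$csp <- csp
    write.csv(cspProfile(csp), file.path(outDir, "csp.csv"), row.names = FALSE)
  }

  predictor <- toyShiftPredictor(rc, config$basinVersion)
  candidates <- ens
  if (config$clusterEnsemble) {
    cl <- stage("cluster", kelleyCluster(pairwiseRmsd(ens)))
    res$clusters <- cl
    meds <- clusterMedoids(cl)
    candidates <- ConformerEnsemble(peptideId(ens), ensembleAtoms(ens),
                                    ensembleXyz(ens)[meds, , drop = FALSE],
                                    cyclicHead = ens@cyclicHead)
  }
  sel <- stage("select", selectEnsemble(
    candidates, obs, n = config$selectionN, mode = config$selectionMode,
    seed = config$selectionSeed, predictor = predictor))
  res$selection <- sel
  write.csv(selectionRanking(sel), file.path(outDir, "ranking.csv"),
            row.names = FALSE)
  selEns <- ConformerEnsemble(peptideId(candidates), ensembleAtoms(candidates),
                              ensembleXyz(candidates)[selectedConformers(sel), ,
                                                      drop = FALSE],
                              cyclicHead = candidates@cyclicHead)
  writePdbEnsemble(selEns, file.path(outDir, "selected_ensemble.pdb"))

  # validation: Q factor always; 3J only when measurements are supplied
  ensTab <- meanShiftTable(.predictAll(predictor, candidates)[selectedConformers(sel)])
  q <- stage("qfactor", qFactor(sec, secondaryShifts(ensTab, rc)))
  validation <- list(q_pooled = q$pooled, q_per_class = as.list(q$perClass),
                     j_status = "partial (no measured couplings supplied)")
  kp <- karplusParams(config$karplusPreset)
  jPred <- stage("ensemble_j", ensembleJ(selEns, kp))
  write.csv(jPred, file.path(outDir, "jcoupling_predicted.csv"),
            row.names = FALSE)
  if (!is.null(config$jCoupling)) {
    jObs <- .loadInput(config$jCoupling, readJCoupling)
    mj <- merge(jObs, jPred, by = "residue_index")
    v <- stage("validate_j", validateJ(mj$j_obs_hz, mj$j_pred_hz))
    validation$j_status <- "complete"
    validation$j_r <- v$r
    validation$j_rmsd_hz <- v$rmsd_hz
  }
  res$validation <- validation

  dyn <- stage("rmsf", rmsfProfile(selEns))
  s2 <- stage("s2", predictS2(sec))
  dyn <- merge(dyn, s2[c("residue_index", "s2")], by = "residue_index",
               all.x = TRUE)
  if (!is.null(config$r2)) {
    t2 <- stage("t2filter", t2Filter(.loadInput(config$r2, readR2),
                                     config$filterTime, config$noiseFloor))
    dyn <- merge(dyn, t2[c("residue_index", "ratio", "detectable")],
                 by = "residue_index", all.x = TRUE)
  }
  res$dynamics <- dyn
  write.csv(dyn, file.path(outDir, "dynamics.csv"), row.names = FALSE)

  manifest <- list(
    package_version = as.character(packageVersion("peptideCS")),
    peptide_id = peptideId(obs),
    presets = list(random_coil = rc@id, karplus = kp@id,
                   shift_predictor = predictor@id, s2 = s2Preset()$id),
    thresholds = list(ss_window = config$ssWindow,
                      ss_threshold_ppm = config$ssThreshold,
                      proline_trans_max_ppm = config$prolineTransMax,
                      proline_cis_min_ppm = config$prolineCisMin,
                      tempco_boundary_ppb_per_K = config$tempcoBoundary,
                      t2_filter_time_s = config$filterTime,
                      t2_noise_floor = config$noiseFloor),
    selection = list(n = config$selectionN, mode = config$selectionMode,
                     seed = config$selectionSeed,
                     ensemble_global_cs_rmsd = ensembleScore(sel),
                     mean_conformer_cs_rmsd = sel@meanConformerScore),
    validation = validation)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
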