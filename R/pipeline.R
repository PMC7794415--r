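#' Run configuration for the end-to-end pipeline
#'
#' Exactly one of `generator` (a [CohortSimConfig-class]) or `inputs` (paths
#' to a cohort table, dosage matrix + variant sidecar, and optionally a
#' survival table) must be given. The training/validation split follows an
#' enrollment-order column when one is named (the first `splitFraction` of
#' participants in that order train the models, emulating a temporal split);
#' otherwise a seeded random split is used.
#'
#' @param generator optional [CohortSimConfig-class].
#' @param inputs optional named list: `cohort`, `dosage`, `variants`,
#'   optionally `survival`.
#' @param splitFraction fraction of participants used for training
#'   (default 0.54).
#' @param splitColumn optional enrollment-order column name.
#' @param stage1Alpha,scanAlpha,prsThreshold,windowBp,r2Max,nBins,middle
#'   analysis thresholds (defaults: 0.05, 1e-8, 1e-6, 250 kb, 0.1, 100 bins,
#'   middle band 48-53).
#' @param strata DRSA percentile strata for the trajectories.
#' @param factorInfo for file-based inputs: data.frame (`name`, `kind`,
#'   `group`, `source`) describing the cohort's factor columns (generator
#'   runs derive it from the config).
#' @param nPCs ancestry components (default 5).
#' @param seed master seed; every stage derives its stream from it.
#' @param outDir output directory for the artifact files (`NULL` = don't
#'   write).
#' @return A validated configuration list of class `skinRunConfig`.
#' @export
runConfig <- function(generator = NULL, inputs = NULL, splitFraction = 0.54,
                      splitColumn = NULL, stage1Alpha = 0.05,
                      scanAlpha = 1e-8, prsThreshold = 1e-6,
                      windowBp = 250000, r2Max = 0.1, nBins = 100L,
                      middle = 48:53,
                      strata = list(`1-20` = c(1, 20), `21-40` = c(21, 40),
                                    `41-60` = c(41, 60), `61-80` = c(61, 80),
                                    `81-90` = c(81, 90),
                                    `91-100` = c(91, 100)),
                      factorInfo = NULL, nPCs = 5L, seed = 1L, outDir = NULL) {
  if (is.null(generator) == is.null(inputs))
    stop("exactly one of `generator` or `inputs` must be supplied")
  if (!is.null(generator) && !is(generator, "CohortSimConfig"))
    stop("`generator` must be a CohortSimConfig")
  if (!is.null(inputs) &&
      !all(c("cohort", "dosage", "variants") %in% names(inputs)))
    stop("`inputs` needs elements cohort, dosage, variants")
  if (splitFraction <= 0 || splitFraction >= 1)
    stop("splitFraction must lie in (0, 1)")
  stopifnot(stage1Alpha > 0, stage1Alpha <= 1, scanAlpha > 0,
            prsThreshold > 0, prsThreshold <= 1, r2Max >= 0, r2Max <= 1,
            windowBp > 0, nBins >= 2)
  structure(list(generator = generator, inputs = inputs,
                 splitFraction = splitFraction, splitColumn = splitColumn,
                 stage1Alpha = stage1Alpha, scanAlpha = scanAlpha,
                 prsThreshold = prsThreshold, windowBp = windowBp,
                 r2Max = r2Max, nBins = as.integer(nBins), middle = middle,
                 strata = strata, factorInfo = factorInfo,
                 nPCs = as.integer(nPCs),
                 seed = as.integer(seed), outDir = outDir),
            class = "skinRunConfig")
}

.stageMsg <- function(stage, t0) {
  message(sprintf("[skinDRS] %-12s %6.1fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full risk-score pipeline
#'
#' Generate (or load) -> split -> per-cancer GWAS and clumped PRS (training
#' only) -> stage-1 survey-factor selection -> additional-phenotype scan ->
#' final per-cancer GLMs -> scores for both splits (standardized on the
#' training set) -> validation-set evaluation -> DRSA-stratified trajectories
#' and follow-up concordance. Deterministic given the seed; all intermediate
#' tables are written to `outDir` when set.
#'
#' @param config a `skinRunConfig` from [runConfig()].
#' @return A `skinRunReport` list: per-cancer selected factors, deviance
#'   explained, PRS variant count, AUCs, OR per SD, top-percentile
#'   enrichment, onset summaries, expected-vs-observed incidence, seed and
#'   config echo.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "skinRunConfig"))
  t0 <- as.numeric(Sys.time())
  cancers <- skinCancers()
  out <- if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    function(x, f, writer = .writeTSV) {
      writer(x, file.path(config$outDir, f))
    }
  } else function(x, f, writer = NULL) invisible(NULL)

  ## --- data -----------------------------------------------------------
  if (!is.null(config$generator)) {
    gen <- config$generator
    gen@seed <- config$seed
    sim <- generateCohort(gen)
    if (gen@followupYears > 0) sim <- generateFollowup(sim, gen)
    cohort <- sim$cohort
    genotypes <- sim$genotypes
    fInfo <- specTable(gen)
  } else {
    cohort <- readCohort(config$inputs$cohort)
    genotypes <- readGenotypes(config$inputs$dosage, config$inputs$variants)
    fInfo <- config$factorInfo
    if (is.null(fInfo))
      stop("file-based runs need `factorInfo` in the run configuration ",
           "(name/kind/group/source table for the cohort's factor columns)")
  }
  out(cohort, "cohort.tsv")
  .stageMsg("data", t0)

  ## --- split ----------------------------------------------------------
  n <- nrow(cohort)
  if (!is.null(config$splitColumn)) {
    ord <- order(cohort[[config$splitColumn]])
    trainIdx <- ord[seq_len(round(config$splitFraction * n))]
  } else {
    set.seed(config$seed + 101L)
    trainIdx <- sort(sample.int(n, round(config$splitFraction * n)))
  }
  isTrain <- seq_len(n) %in% trainIdx
  gTrain <- genotypes[, isTrain]
  gValid <- genotypes[, !isTrain]

  ## --- imputation (per split, no leakage) ------------------------------
  set.seed(config$seed + 211L)   # donor draws of the PMM imputation
  impT <- imputePhenotypes(cohort[isTrain, ], fInfo)
  impV <- imputePhenotypes(cohort[!isTrain, ], fInfo)
  trainC <- impT$cohort
  validC <- impV$cohort
  fInfo <- fInfo[!fInfo$name %in% c(impT$dropped, impV$dropped), ,
                 drop = FALSE]
  .stageMsg("impute", t0)

  ## --- ancestry + GWAS + PRS (training only) ---------------------------
  pcsT <- computePCs(gTrain, k = config$nPCs)
  pcsV <- projectPCs(gValid, pcsT)
  covT <- cbind(age = trainC$current_age,
                male = as.numeric(trainC$sex == "male"), pcsT)
  prsModels <- list(); prsT <- list(); prsV <- list()
  outcomesT <- lapply(setNames(cancers, cancers),
                      function(cc) trainC[[paste0("case_", cc)]])
  for (cc in cancers) {
    assoc <- runGWAS(gTrain, outcomesT[[cc]], covariates = covT)
    out(assoc, paste0("gwas_", cc, ".tsv"))
    prsModels[[cc]] <- clumpThreshold(
      assoc, gTrain, pThreshold = config$prsThreshold,
      windowBp = config$windowBp, r2Max = config$r2Max, cancer = cc)
    if (!is.null(config$outDir))
      writePRSModel(prsModels[[cc]],
                    file.path(config$outDir, paste0("prs_", cc, ".tsv")))
    prsT[[cc]] <- computePRS(gTrain, prsModels[[cc]])
    prsV[[cc]] <- computePRS(gValid, prsModels[[cc]])
  }
  .stageMsg("gwas/prs", t0)

  ## --- factor selection -------------------------------------------------
  survey <- fInfo[fInfo$source == "survey", , drop = FALSE]
  database <- fInfo[fInfo$source != "survey", , drop = FALSE]
  designAll <- buildFactorDesign(trainC, survey, pcs = pcsT)
  trace <- stage1Select(designAll, outcomesT, alpha = config$stage1Alpha)
  keptSurvey <- trace@kept
  scan <- NULL
  extraKeep <- character(0)
  if (nrow(database)) {
    base <- subsetDesign(designAll, keptSurvey)
    scan <- scanAdditional(base, outcomesT, trainC[database$name],
                           alpha = config$scanAlpha)
    extraKeep <- scan$phenotype[scan$candidate]
    out(scan, "scan_additional.tsv")
  }
  .stageMsg("selection", t0)

  ## --- final models -----------------------------------------------------
  finalInfo <- fInfo[fInfo$name %in% c(keptSurvey, extraKeep), ,
                     drop = FALSE]
  models <- list(); designsT <- list(); designsV <- list()
  for (cc in cancers) {
    usePRS <- sd(prsT[[cc]]) > 0
    if (!usePRS)
      message("[skinDRS] empty/constant PRS for ", cc,
              "; fitting without a PRS factor")
    dT <- buildFactorDesign(trainC, finalInfo, pcs = pcsT,
                            prs = if (usePRS) prsT[[cc]] else NULL)
    dT <- subsetDesign(dT, intersect(names(dT@recipe),
                                     c(keptSurvey, extraKeep,
                                       "current_age", "sex", "ancestry",
                                       "family_history", "PRS")))
    models[[cc]] <- fitRiskGLM(dT, outcomesT[[cc]], cancer = cc)
    designsT[[cc]] <- dT
    designsV[[cc]] <- applyDesign(dT, validC, pcs = pcsV,
                                  prs = if (usePRS) prsV[[cc]] else NULL)
    if (!is.null(config$outDir))
      writeRiskModel(models[[cc]],
                     file.path(config$outDir, paste0("model_", cc, ".tsv")))
  }
  .stageMsg("fit", t0)

  ## --- scores -----------------------------------------------------------
  scoresT <- computeScoreSet(models, designsT)
  scoresV <- computeScoreSet(models, designsV)
  zV <- standardizeScores(scoresV, reference = scoresT)
  if (!is.null(config$outDir)) {
    writeScoreSet(scoresV, file.path(config$outDir, "scores_validation.tsv"),
                  standardized = zV)
    writeScoreSet(scoresT, file.path(config$outDir, "scores_training.tsv"))
  }
  .stageMsg("scores", t0)

  ## --- evaluation + trajectories (validation only) ----------------------
  report <- list()
  for (cc in cancers) {
    y <- validC[[paste0("case_", cc)]]
    m <- scoreMatrix(scoresV, cc)
    mt <- scoreMatrix(scoresT, cc)
    met <- metricReport(m[, "DRS"], y, reference = mt[, "DRS"],
                        nBins = config$nBins, middle = config$middle)
    metA <- metricReport(m[, "DRSA"], y, reference = mt[, "DRSA"],
                         nBins = config$nBins, middle = config$middle)
    traj <- suppressWarnings(lifetimeRiskCurves(
      m[, "DRSA"], validC$current_age, y,
      validC[[paste0("age_dx_", cc)]], strata = config$strata, cancer = cc))
    I <- incidenceFromPrevalence(traj)
    S <- defaultSurvivalTable()
    onset <- expectedAgeOfDiagnosis(I, S)
    evo <- NULL
    if (any(grepl(paste0("^fu[0-9]+_dx_", cc), colnames(validC)))) {
      evo <- expectedVsObservedIncidence(traj, m[, "DRSA"],
                                         validC$current_age, validC, cc)
      out(evo, paste0("incidence_concordance_", cc, ".tsv"))
    }
    out(met$binSummary$bins, paste0("bins_DRS_", cc, ".tsv"))
    out(onset, paste0("onset_", cc, ".tsv"))
    report[[cc]] <- list(
      factors = unique(riskCoefficients(models[[cc]])$factor),
      devianceExplained = devianceExplained(models[[cc]]),
      prsVariants = nrow(prsVariants(prsModels[[cc]])),
      aucDRS = met$auc, aucDRSA = metA$auc,
      orPerSD_DRS = met$orPerSD$or,
      topPrevalence = met$topPrevalence, topFold = met$topFold,
      onset = onset, incidenceConcordance = evo)
  }
  .stageMsg("evaluate", t0)

  res <- structure(list(cancers = report, seed = config$seed,
                        nTrain = sum(isTrain), nValid = sum(!isTrain),
                        version = as.character(utils::packageVersion("skinDRS")),
                        config = config),
                   class = "skinRunReport")
  if (!is.null(config$outDir)) {
    rep <- lapply(report, function(r)
      r[c("devianceExplained", "prsVariants", "aucDRS", "aucDRSA",
          "orPerSD_DRS", "topPrevalence", "topFold")])
    jsonlite::write_json(list(seed = config$seed, cancers = rep),
                         file.path(config$outDir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.skinRunReport <- function(x, ...) {
  cat(sprintf("skinDRS run report (seed %d): %d training / %d validation\n",
              x$seed, x$nTrain, x$nValid))
  for (cc in names(x$cancers)) {
    r <- x$cancers[[cc]]
    cat(sprintf(
      "  %-8s dev.expl %.3f | PRS %2d variants | AUC DRS %.3f DRSA %.3f | OR/SD %.2f | top-1%% prev %.3f (%.1fx)\n",
      cc, r$devianceExplained, r$prsVariants, r$aucDRS, r$aucDRSA,
      r$orPerSD_DRS, r$topPrevalence,
      ifelse(is.na(r$topFold), NA, r$topFold)))
  }
  invisible(x)
}
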