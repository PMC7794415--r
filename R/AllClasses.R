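#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats anova aggregate as.formula binomial binom.test coef
#'   complete.cases cor glm glm.fit isoreg lm lm.fit median na.omit pchisq
#'   plogis pnorm poly predict qchisq qlogis qnorm quantile rbinom rnorm
#'   runif sd setNames var
#' @importFrom utils head read.delim write.table
NULL

## Cancer labels used throughout: basal cell carcinoma, squamous cell
## carcinoma, melanoma.

#' Skin cancer outcome labels
#'
#' The three outcomes every per-cancer structure in the package is keyed by.
#'
#' @return Character vector `c("BCC", "SCC", "melanoma")`.
#' @export
#' @examples
#' skinCancers()
skinCancers <- function() c("BCC", "SCC", "melanoma")

#' FactorSpec: one simulated risk factor
#'
#' Describes a single risk factor of the synthetic cohort generator: its
#' marginal distribution, its dependence on age, and its true per-cancer
#' effect on the yearly diagnosis hazard (log-odds per unit, or per level for
#' categorical factors).
#'
#' @slot name factor name (column name in the cohort table).
#' @slot kind one of `"binary"`, `"ordinal"`, `"continuous"`, `"categorical"`.
#' @slot group risk-score group label: one of Demographic, Family, Mole,
#'   Susceptibility, Exposure, Miscellaneous.
#' @slot params marginal distribution parameters. Binary: `prob`. Ordinal:
#'   `probs` (level probabilities, levels coded 1..K). Continuous: `mean`,
#'   `sd`, optionally `derived_from` and `rho` to induce correlation with an
#'   earlier continuous factor. Categorical: `probs` with `levels`.
#' @slot ageSlope dependence of the factor on standardized current age
#'   (shift of the latent mean / logit per SD of age; 0 = age-independent).
#' @slot beta true effect: numeric length-3 vector named by [skinCancers()]
#'   (per unit / per ordinal level / per SD for continuous), or for
#'   categorical factors a levels-by-3 matrix of per-level log-odds
#'   (reference level row 0).
#' @export
setClass("FactorSpec", representation(
  name = "character", kind = "character", group = "character",
  params = "list", ageSlope = "numeric", beta = "ANY"))

setValidity("FactorSpec", function(object) {
  msg <- NULL
  if (!object@kind %in% c("binary", "ordinal", "continuous", "categorical"))
    msg <- c(msg, "kind must be binary/ordinal/continuous/categorical")
  if (!object@group %in% c("Demographic", "Family", "Mole", "Susceptibility",
                           "Exposure", "Miscellaneous"))
    msg <- c(msg, "unknown group label")
  if (object@kind == "ordinal" && length(object@params$probs) < 2)
    msg <- c(msg, "ordinal factors need >= 2 ordered levels")
  if (object@kind == "categorical") {
    if (length(object@params$levels) < 2)
      msg <- c(msg, "categorical factors need >= 2 levels")
    if (!is.matrix(object@beta) ||
        nrow(object@beta) != length(object@params$levels))
      msg <- c(msg, "categorical beta must be a levels x 3 matrix")
  } else if (!is.matrix(object@beta) && length(object@beta) != 3) {
    msg <- c(msg, "beta must be length 3 (one per cancer)")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a FactorSpec
#'
#' @param name,kind,group,params,ageSlope,beta see [FactorSpec-class].
#' @return A [FactorSpec-class] object.
#' @export
#' @examples
#' factorSpec("dysplastic_moles", "binary", "Mole", list(prob = 0.05),
#'            beta = c(BCC = 0.9, SCC = 0.85, melanoma = log(6.7)))
factorSpec <- function(name, kind, group, params = list(), ageSlope = 0,
                       beta = c(BCC = 0, SCC = 0, melanoma = 0)) {
  if (!is.matrix(beta)) beta <- setNames(as.numeric(beta), skinCancers())
  new("FactorSpec", name = name, kind = kind, group = group, params = params,
      ageSlope = ageSlope, beta = beta)
}

setMethod("show", "FactorSpec", function(object) {
  cat(sprintf("FactorSpec '%s' (%s, group %s, ageSlope %.2f)\n",
              object@name, object@kind, object@group, object@ageSlope))
})

#' GenotypeDosage: imputed dosage matrix with variant metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying one assay
#' `"dosage"` (variants in rows, participants in columns, values in `[0,2]`)
#' and variant metadata in `rowData`: `chrom`, `pos` (1-based), `effect_allele`
#' and `maf`.
#'
#' @export
setClass("GenotypeDosage", contains = "SummarizedExperiment")

setValidity("GenotypeDosage", function(object) {
  msg <- NULL
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  need <- c("chrom", "pos", "effect_allele", "maf")
  if (!all(need %in% colnames(SummarizedExperiment::rowData(object))))
    msg <- c(msg, paste("rowData must contain", paste(need, collapse = ", ")))
  d <- SummarizedExperiment::assay(object, "dosage")
  if (length(d) && (min(d, na.rm = TRUE) < 0 || max(d, na.rm = TRUE) > 2))
    msg <- c(msg, "dosages must lie in [0,2]")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypeDosage object
#'
#' @param dosage numeric matrix, variants x participants, values in `[0,2]`.
#' @param variants data.frame with columns `id`, `chrom`, `pos`,
#'   `effect_allele`, `maf`; one row per row of `dosage`.
#' @return A [GenotypeDosage-class] object.
#' @export
GenotypeDosage <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), nrow(dosage) == nrow(variants))
  rownames(dosage) <- variants$id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage),
    rowData = S4Vectors::DataFrame(variants[setdiff(colnames(variants), "id")],
                                   row.names = variants$id))
  new("GenotypeDosage", se)
}

#' @describeIn GenotypeDosage dosage matrix accessor (variants x participants).
#' @param x a `GenotypeDosage`.
#' @export
dosages <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn GenotypeDosage variant metadata as a data.frame with an `id`
#'   column.
#' @export
variantInfo <- function(x) {
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  cbind(id = rownames(x), rd, stringsAsFactors = FALSE)
}

setMethod("show", "GenotypeDosage", function(object) {
  cat(sprintf("GenotypeDosage: %d variants x %d participants\n",
              nrow(object), ncol(object)))
  callNextMethod()
})

#' PRSModel: a clumped-and-thresholded polygenic risk score
#'
#' @slot variants data.frame: `id`, `chrom`, `pos`, `effect_allele`, `weight`
#'   (log-odds per dosage unit), `p`, `maf`.
#' @slot pThreshold p-value cut-off used for selection.
#' @slot windowBp clumping window in base pairs.
#' @slot r2Max maximum dosage r-squared tolerated within a window.
#' @slot cancer outcome label the model was trained for ("" if unspecified).
#' @export
setClass("PRSModel", representation(
  variants = "data.frame", pThreshold = "numeric", windowBp = "numeric",
  r2Max = "numeric", cancer = "character"))

setValidity("PRSModel", function(object) {
  v <- object@variants
  need <- c("id", "chrom", "pos", "effect_allele", "weight", "p", "maf")
  if (!all(need %in% colnames(v)))
    return(paste("variants table needs columns", paste(need, collapse = ", ")))
  if (nrow(v) && any(v$p > object@pThreshold))
    return("all selected variants must satisfy p <= pThreshold")
  TRUE
})

setMethod("show", "PRSModel", function(object) {
  cat(sprintf("PRSModel%s: %d variants (p <= %.3g, window %g bp, r2 <= %g)\n",
              if (nzchar(object@cancer)) paste0(" [", object@cancer, "]") else "",
              nrow(object@variants), object@pThreshold, object@windowBp,
              object@r2Max))
})

#' @describeIn PRSModel selected variant table accessor.
#' @param x a `PRSModel`.
#' @export
prsVariants <- function(x) x@variants

#' FactorDesign: model design matrix with factor bookkeeping
#'
#' Expansion of a cohort's risk factors into a numeric design matrix:
#' categorical factors are reference-coded (most frequent level as reference),
#' continuous factors are expanded on orthogonal polynomial bases fitted on
#' the training sample. The `recipe` stores everything needed to re-apply the
#' identical expansion to new participants ([applyDesign()]).
#'
#' @slot X numeric design matrix (no intercept column).
#' @slot map data.frame mapping each design `column` to its `factor`.
#' @slot groups data.frame mapping each `factor` to its risk-score `group`.
#' @slot recipe per-factor expansion recipe (internal).
#' @slot ids participant identifiers (rows of `X`).
#' @export
setClass("FactorDesign", representation(
  X = "matrix", map = "data.frame", groups = "data.frame", recipe = "list",
  ids = "character"))

setValidity("FactorDesign", function(object) {
  msg <- NULL
  if (ncol(object@X) != nrow(object@map) ||
      !identical(colnames(object@X), object@map$column))
    msg <- c(msg, "map must cover every design column exactly once")
  if (!all(object@map$factor %in% object@groups$factor))
    msg <- c(msg, "every factor must carry a group label")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "FactorDesign", function(object) {
  cat(sprintf("FactorDesign: %d participants x %d columns (%d factors)\n",
              nrow(object@X), ncol(object@X), nrow(object@groups)))
})

#' @describeIn FactorDesign design matrix accessor.
#' @param x a `FactorDesign`.
#' @export
designMatrix <- function(x) x@X

#' @describeIn FactorDesign column-to-factor map accessor.
#' @export
designMap <- function(x) x@map

#' @describeIn FactorDesign factor-to-group map accessor.
#' @export
designGroups <- function(x) x@groups

#' RiskModel: a fitted per-cancer logistic risk model
#'
#' Maximum-likelihood binomial GLM (logit link) of case status on the design
#' columns of a [FactorDesign-class], with per-column Wald statistics and the
#' deviance bookkeeping behind "variance explained".
#'
#' @slot cancer outcome label.
#' @slot coefficients data.frame: `column`, `factor`, `group`, `beta`, `se`,
#'   `z`, `p`.
#' @slot intercept fitted intercept (log-odds).
#' @slot deviance,nullDeviance residual and intercept-only deviance.
#' @slot design the training [FactorDesign-class] with its matrix dropped;
#'   carries the recipe used to score new participants.
#' @slot n number of training participants.
#' @export
setClass("RiskModel", representation(
  cancer = "character", coefficients = "data.frame", intercept = "numeric",
  deviance = "numeric", nullDeviance = "numeric", design = "FactorDesign",
  n = "integer"))

setValidity("RiskModel", function(object) {
  de <- 1 - object@deviance / object@nullDeviance
  if (is.finite(de) && (de < -1e-8 || de > 1 + 1e-8))
    return("deviance explained must lie in [0,1]")
  TRUE
})

#' Deviance explained by a fitted risk model
#'
#' `1 - deviance/null deviance` of the binomial GLM, the goodness-of-fit
#' measure reported as "variance explained" for these models.
#'
#' @param object a [RiskModel-class].
#' @return A single number in `[0,1]`.
#' @export
devianceExplained <- function(object) {
  1 - object@deviance / object@nullDeviance
}

#' @describeIn RiskModel coefficient table accessor.
#' @param x a `RiskModel`.
#' @export
riskCoefficients <- function(x) x@coefficients

setMethod("show", "RiskModel", function(object) {
  cat(sprintf(
    "RiskModel [%s]: %d columns / %d factors, n = %d, deviance explained = %.3f\n",
    object@cancer, nrow(object@coefficients),
    length(unique(object@coefficients$factor)), object@n,
    devianceExplained(object)))
})

#' ScoreSet: per-participant composite risk scores
#'
#' Per cancer, a participants-by-score matrix holding the polygenic score
#' (PRS), the six grouped scores (Demographic, Family, Mole, Susceptibility,
#' Exposure, Miscellaneous), the global disease risk score (DRS, all factors)
#' and the age-free DRSA (DRS minus the age polynomial block). All scores are
#' linear-predictor contributions without intercept.
#'
#' @slot ids participant identifiers.
#' @slot scores named list (per cancer) of numeric matrices.
#' @slot standardization named list (per cancer) of data.frames
#'   (`score`, `mean`, `sd`) giving the reference constants used by
#'   [standardizeScores()]; empty until standardization is applied.
#' @export
setClass("ScoreSet", representation(
  ids = "character", scores = "list", standardization = "list"))

setValidity("ScoreSet", function(object) {
  ok <- vapply(object@scores, function(m)
    is.matrix(m) && nrow(m) == length(object@ids), logical(1))
  if (!all(ok)) return("each score matrix needs one row per participant")
  TRUE
})

#' @describeIn ScoreSet score matrix for one cancer.
#' @param x a `ScoreSet`.
#' @param cancer outcome label.
#' @export
scoreMatrix <- function(x, cancer) {
  if (!cancer %in% names(x@scores)) stop("no scores for cancer ", cancer)
  x@scores[[cancer]]
}

#' @describeIn ScoreSet cancers with scores available.
#' @export
scoreCancers <- function(x) names(x@scores)

setMethod("show", "ScoreSet", function(object) {
  cat(sprintf("ScoreSet: %d participants; cancers: %s; scores: %s\n",
              length(object@ids), paste(names(object@scores), collapse = ", "),
              paste(colnames(object@scores[[1]]), collapse = ", ")))
})

#' @export
#' @describeIn ScoreSet long-format data.frame
#'   (participant, cancer, score, value).
#' @param row.names,optional,... passed for generic compatibility (unused).
as.data.frame.ScoreSet <- function(x, row.names = NULL, optional = FALSE, ...) {
  do.call(rbind, lapply(names(x@scores), function(cc) {
    m <- x@scores[[cc]]
    data.frame(participant = rep(x@ids, ncol(m)),
               cancer = cc,
               score = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  }))
}

#' SurvivalTable: yearly survival fractions by age
#'
#' @slot age integer ages (years).
#' @slot survival survival fraction at each age, non-increasing, in (0,1].
#' @export
setClass("SurvivalTable", representation(age = "integer", survival = "numeric"))

setValidity("SurvivalTable", function(object) {
  msg <- NULL
  if (length(object@age) != length(object@survival))
    msg <- c(msg, "age and survival must have the same length")
  if (any(object@survival <= 0) || any(object@survival > 1))
    msg <- c(msg, "survival fractions must lie in (0,1]")
  if (is.unsorted(object@age)) msg <- c(msg, "ages must be increasing")
  if (any(diff(object@survival) > 1e-12))
    msg <- c(msg, "survival must be non-increasing in age")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SurvivalTable
#'
#' @param age integer ages.
#' @param survival survival fractions, non-increasing, in (0,1].
#' @return A [SurvivalTable-class].
#' @export
survivalTable <- function(age, survival) {
  new("SurvivalTable", age = as.integer(age), survival = as.numeric(survival))
}

setMethod("show", "SurvivalTable", function(object) {
  cat(sprintf("SurvivalTable: ages %d-%d, S(%d) = %.3f\n",
              min(object@age), max(object@age), max(object@age),
              object@survival[length(object@survival)]))
})

#' TrajectorySet: lifetime risk curves stratified by risk score
#'
#' Per-age cumulative probabilities of diagnosis (`prevalence`, isotonic in
#' age) for each risk-score stratum of one cancer, with the raw retrospective
#' estimates kept alongside.
#'
#' @slot cancer outcome label.
#' @slot ages integer age grid.
#' @slot strata data.frame: `label`, `lo`, `hi` (percentile range), `n`.
#' @slot raw,prevalence matrices ages x strata (raw and isotonic-smoothed
#'   lifetime risk).
#' @export
setClass("TrajectorySet", representation(
  cancer = "character", ages = "integer", strata = "data.frame",
  raw = "matrix", prevalence = "matrix"))

setValidity("TrajectorySet", function(object) {
  msg <- NULL
  P <- object@prevalence
  if (nrow(P) != length(object@ages) || ncol(P) != nrow(object@strata))
    msg <- c(msg, "prevalence must be ages x strata")
  if (length(P) && (min(P, na.rm = TRUE) < -1e-12 || max(P, na.rm = TRUE) > 1 + 1e-12))
    msg <- c(msg, "lifetime risk must lie in [0,1]")
  if (length(P) && any(apply(P, 2, function(p) any(diff(na.omit(p)) < -1e-10))))
    msg <- c(msg, "smoothed lifetime risk must be non-decreasing in age")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn TrajectorySet smoothed lifetime-risk matrix accessor.
#' @param x a `TrajectorySet`.
#' @export
lifetimeRisk <- function(x) x@prevalence

#' @describeIn TrajectorySet stratum definition accessor.
#' @export
trajectoryStrata <- function(x) x@strata

setMethod("show", "TrajectorySet", function(object) {
  cat(sprintf("TrajectorySet [%s]: ages %d-%d, %d strata (n = %s)\n",
              object@cancer, min(object@ages), max(object@ages),
              nrow(object@strata),
              paste(object@strata$n, collapse = ", ")))
})
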