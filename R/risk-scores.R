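#' Family-history score
#'
#' Simple sum of four binary indicators of reported skin cancer in the
#' father, the mother, at least one sibling, and at least one child, with
#' the two highest categories collapsed: values 3 and 4 both map to 3, so
#' the score ranges over \{0, 1, 2, 3\}. Multiple affected siblings (or
#' children) still count +1. Missing indicators propagate as `NA` — they are
#' handled by the imputation step, never silently zeroed.
#'
#' @param father,mother,anySibling,anyChild binary 0/1 indicators (any skin
#'   cancer type counts).
#' @return Integer vector in \{0, 1, 2, 3\} (`NA` where any input is `NA`).
#' @export
#' @examples
#' familyHistoryScore(1, 1, 1, 1)  # 3: categories 3 and 4 are combined
#' familyHistoryScore(0, 0, 1, 0)  # 1: at least one sibling
familyHistoryScore <- function(father, mother, anySibling, anyChild) {
  args <- list(father, mother, anySibling, anyChild)
  for (a in args) {
    bad <- !is.na(a) & !a %in% c(0, 1)
    if (any(bad)) stop("family-history indicators must be binary 0/1")
  }
  raw <- as.integer(father) + as.integer(mother) + as.integer(anySibling) +
    as.integer(anyChild)
  pmin(raw, 3L)
}

#' Linear-predictor risk score over a factor subset
#'
#' `score_i = sum_j x_ij beta_j` over the design columns of the included
#' factors — no intercept, so scores are location-free and meaningful only
#' through ranks, bins and standardization.
#'
#' @param design a [FactorDesign-class] for the participants to score
#'   (typically from [applyDesign()]).
#' @param model a [RiskModel-class] providing the weights.
#' @param include factor names to include (must be a subset of the model's
#'   factors). Empty set gives all-zero scores.
#' @return Named numeric vector of scores.
#' @export
computeScore <- function(design, model, include) {
  co <- riskCoefficients(model)
  unknown <- setdiff(include, unique(co$factor))
  if (length(unknown))
    stop("factor(s) not in model: ", paste(unknown, collapse = ", "))
  X <- designMatrix(design)
  cols <- co$column[co$factor %in% include]
  if (!length(cols))
    return(setNames(numeric(nrow(X)), design@ids))
  missing <- setdiff(cols, colnames(X))
  if (length(missing))
    stop("design lacks column(s): ", paste(missing, collapse = ", "))
  w <- co$beta[match(cols, co$column)]
  setNames(as.vector(X[, cols, drop = FALSE] %*% w), design@ids)
}

#' Compute the full score set for one or more fitted models
#'
#' For each cancer: the global disease risk score DRS (all model factors),
#' the age-free DRSA (all factors except the current-age polynomial block —
#' sex and ancestry stay in), the PRS alone, and the six grouped scores
#' (Demographic, Family, Mole, Susceptibility, Exposure, Miscellaneous).
#' By construction `DRS - DRSA` equals the age-block contribution for every
#' participant, and when the groups partition the factors the grouped scores
#' plus PRS sum to the DRS.
#'
#' @param models named list of [RiskModel-class] objects (one per cancer).
#' @param designs named list of [FactorDesign-class] objects aligned with
#'   `models` (same participants in each).
#' @param ageFactor name of the age factor excluded by DRSA.
#' @return A [ScoreSet-class].
#' @export
computeScoreSet <- function(models, designs, ageFactor = "current_age") {
  stopifnot(identical(names(models), names(designs)))
  ids <- designs[[1]]@ids
  groupNames <- c("Demographic", "Family", "Mole", "Susceptibility",
                  "Exposure", "Miscellaneous")
  scores <- list()
  for (cc in names(models)) {
    model <- models[[cc]]
    design <- designs[[cc]]
    co <- riskCoefficients(model)
    allFactors <- unique(co$factor)
    drs <- computeScore(design, model, allFactors)
    drsa <- computeScore(design, model, setdiff(allFactors, ageFactor))
    m <- cbind(DRS = drs, DRSA = drsa)
    prsF <- unique(co$factor[co$group == "PRS"])
    m <- cbind(m, PRS = computeScore(design, model, prsF))
    for (g in groupNames) {
      gf <- unique(co$factor[co$group == g])
      m <- cbind(m, computeScore(design, model, gf))
      colnames(m)[ncol(m)] <- g
    }
    rownames(m) <- ids
    scores[[cc]] <- m
  }
  new("ScoreSet", ids = as.character(ids), scores = scores,
      standardization = list())
}

#' Standardize a score against a reference distribution
#'
#' `(score - mean(reference)) / sd(reference)`. The reference defaults to the
#' score itself; in the pipeline the training-set scores serve as reference
#' so validation z-values and odds ratios per SD are anchored to the
#' training distribution.
#'
#' @param score numeric vector.
#' @param reference numeric reference scores (default `score`).
#' @return The z-scored vector, with attributes `"mean"` and `"sd"` recording
#'   the reference constants.
#' @export
standardize <- function(score, reference = score) {
  m <- mean(reference); s <- sd(reference)
  if (!is.finite(s) || s <= 0) stop("reference has zero variance")
  z <- (score - m) / s
  attr(z, "mean") <- m
  attr(z, "sd") <- s
  z
}

#' Standardize every score of a ScoreSet
#'
#' @param x a [ScoreSet-class] to standardize.
#' @param reference a [ScoreSet-class] giving the reference distributions
#'   (default `x`, i.e. self-standardization).
#' @return `x` with scores replaced by z-values and the reference constants
#'   recorded in the `standardization` slot.
#' @export
standardizeScores <- function(x, reference = x) {
  std <- list()
  for (cc in names(x@scores)) {
    m <- x@scores[[cc]]
    ref <- reference@scores[[cc]]
    mu <- colMeans(ref)
    sdev <- apply(ref, 2, sd)
    if (any(sdev <= 0)) {
      ## structurally empty scores (e.g. a group with no selected factors)
      ## are left on their raw (constant) scale
      message("leaving zero-variance score(s) unstandardized [", cc, "]: ",
              paste(colnames(ref)[sdev <= 0], collapse = ", "))
      mu[sdev <= 0] <- 0
    }
    sdev2 <- ifelse(sdev > 0, sdev, 1)
    x@scores[[cc]] <- sweep(sweep(m, 2, mu), 2, sdev2, "/")
    std[[cc]] <- data.frame(score = colnames(ref), mean = unname(mu),
                            sd = ifelse(sdev > 0, unname(sdev), NA_real_))
  }
  x@standardization <- std
  x
}
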