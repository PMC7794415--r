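#' ROC curve and area under the curve
#'
#' AUC computed from the rank statistic, i.e. the probability a random case
#' outscores a random control, with ties counting one half — identical to
#' the normalized Mann-Whitney U. Curve points are returned at every
#' distinct threshold.
#'
#' @param score numeric risk score.
#' @param label binary 0/1 outcome; both classes must be present.
#' @return List: `auc`, and `curve` (data.frame `threshold`, `fpr`, `tpr`).
#' @export
#' @examples
#' rocAUC(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc  # 1
rocAUC <- function(score, label) {
  y <- as.numeric(label)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(score)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(score, decreasing = TRUE)
  ys <- y[ord]; ss <- score[ord]
  keep <- c(diff(ss) != 0, TRUE)
  tpr <- cumsum(ys)[keep] / n1
  fpr <- cumsum(1 - ys)[keep] / n0
  curve <- data.frame(threshold = c(Inf, ss[keep]), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  list(auc = auc, curve = curve)
}

#' Area under the precision-recall curve
#'
#' Average precision over the ranked score (step-wise integral of precision
#' in recall).
#'
#' @inheritParams rocAUC
#' @return A single number in `[0,1]`.
#' @export
prAUC <- function(score, label) {
  y <- as.numeric(label)
  n1 <- sum(y == 1)
  if (n1 == 0 || n1 == length(y)) stop("both classes must be present")
  ord <- order(score, decreasing = TRUE)
  ys <- y[ord]
  prec <- cumsum(ys) / seq_along(ys)
  sum(prec[ys == 1]) / n1
}

#' Odds ratio per standard deviation of a score
#'
#' Exponentiated coefficient of the z-scored score in a logistic regression
#' of the outcome on the score (plus optional covariates), with a Wald 95
#' per cent confidence interval.
#'
#' @param score numeric risk score (standardized internally against
#'   `reference`).
#' @param label binary 0/1 outcome.
#' @param covariates optional covariate matrix / data.frame.
#' @param reference reference scores for the standardization (default
#'   `score`).
#' @return List: `or`, `ci` (length 2), `beta`, `se`.
#' @export
orPerSD <- function(score, label, covariates = NULL, reference = score) {
  z <- standardize(score, reference)
  M <- cbind(1, z)
  if (!is.null(covariates)) M <- cbind(M, as.matrix(covariates))
  fit <- suppressWarnings(
    glm.fit(M, as.numeric(label), family = binomial(),
            control = list(maxit = 100)))
  V <- solve(crossprod(M * sqrt(fit$weights)))
  b <- fit$coefficients[2]; se <- sqrt(V[2, 2])
  list(or = exp(b), ci = exp(b + c(-1, 1) * qnorm(0.975) * se),
       beta = unname(b), se = unname(se))
}

#' Percentile bin assignment
#'
#' Rank-based assignment into `nBins` bins of as equal size as possible
#' (sizes differ by at most one); ties are broken by stable input order, so
#' the binning is reproducible and invariant under monotone transforms of
#' the score.
#'
#' @param score numeric score, length at least `nBins`.
#' @param nBins number of bins (default 100, i.e. percentiles).
#' @return Integer vector of bin indices in `1..nBins` (1 = lowest scores).
#' @export
percentileBins <- function(score, nBins = 100L) {
  n <- length(score)
  if (n < nBins)
    stop("need at least as many observations as bins; use fewer bins")
  ord <- order(score)         # stable: ties keep input order
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  as.integer(ceiling(pos * nBins / n))
}

## mask any case-derived statistic computed from fewer than `minN` cases
.maskedMeanCI <- function(x, minN = 5L) {
  x <- x[!is.na(x)]
  k <- length(x)
  if (k < minN) return(c(mean = NA_real_, lo = NA_real_, hi = NA_real_,
                         n = k))
  m <- mean(x); se <- sd(x) / sqrt(k)
  c(mean = m, lo = m - qnorm(0.975) * se, hi = m + qnorm(0.975) * se, n = k)
}

#' Summarize percentile bins: prevalence, enrichment, age of diagnosis
#'
#' Per-bin case prevalence and fold-enrichment relative to the middle band
#' of the distribution, plus the mean age at diagnosis among the bin's cases
#' with a normal-approximation 95 per cent confidence interval. Any
#' case-derived cell computed from fewer than 5 participants is masked
#' (`NA`). Optionally adds a bottom / middle / top strata table including
#' incident and cancer-free follow-up counts.
#'
#' @param bins integer bin assignment from [percentileBins()].
#' @param label binary 0/1 baseline case status.
#' @param ageAtDiagnosis per-participant age at diagnosis (`NA` for
#'   controls).
#' @param followupStatus optional per-participant follow-up classification
#'   from [classifyFollowup()].
#' @param middle bins forming the reference middle band (default 48-53,
#'   i.e. the 47.5-52.5 percentile band for 100 bins).
#' @param strata named list of bin ranges for the strata table (default
#'   bottom / middle / top 5 per cent).
#' @return List: `bins` (per-bin data.frame), `strata` (data.frame or
#'   `NULL`), `middlePrevalence`.
#' @export
summarizeBins <- function(bins, label, ageAtDiagnosis = NULL,
                          followupStatus = NULL, middle = 48:53,
                          strata = list(bottom = 1:5, middle = 48:53,
                                        top = 96:100)) {
  y <- as.numeric(label)
  nBins <- max(bins)
  midN <- sum(bins %in% middle)
  midCases <- sum(y[bins %in% middle])
  midPrev <- if (midN > 0) midCases / midN else NA_real_
  rows <- lapply(seq_len(nBins), function(b) {
    idx <- bins == b
    n <- sum(idx); cases <- sum(y[idx])
    prev <- cases / n
    fold <- if (!is.na(midPrev) && midCases >= 5 && midPrev > 0)
      prev / midPrev else NA_real_
    ci <- if (!is.null(ageAtDiagnosis))
      .maskedMeanCI(ageAtDiagnosis[idx & y == 1]) else
        c(mean = NA_real_, lo = NA_real_, hi = NA_real_, n = NA_real_)
    data.frame(bin = b, n = n, cases = cases, prevalence = prev,
               fold = fold, age_dx_mean = ci[["mean"]],
               age_dx_lo = ci[["lo"]], age_dx_hi = ci[["hi"]])
  })
  binTab <- do.call(rbind, rows)
  stratTab <- NULL
  if (!is.null(strata)) {
    stratTab <- do.call(rbind, lapply(names(strata), function(s) {
      idx <- bins %in% strata[[s]]
      n <- sum(idx); cases <- sum(y[idx])
      ci <- if (!is.null(ageAtDiagnosis))
        .maskedMeanCI(ageAtDiagnosis[idx & y == 1]) else
          c(mean = NA_real_, lo = NA_real_, hi = NA_real_, n = NA_real_)
      incident <- cancerFree <- unchanged <- NA_integer_
      incRate <- freeRate <- NA_real_
      if (!is.null(followupStatus)) {
        st <- followupStatus[idx]
        incident <- sum(st == "incident", na.rm = TRUE)
        unchanged <- sum(st == "unchanged_control", na.rm = TRUE)
        cancerFree <- sum(st == "cancer_free", na.rm = TRUE)
        persistent <- sum(st == "persistent_case", na.rm = TRUE)
        if (incident + unchanged >= 5)
          incRate <- incident / (incident + unchanged)
        if (cancerFree + persistent >= 5)
          freeRate <- cancerFree / (cancerFree + persistent)
      }
      data.frame(stratum = s, n = n,
                 cases = if (cases >= 5 || cases == 0) cases else NA_integer_,
                 prevalence = if (cases >= 5 || cases == 0) cases / n else
                   NA_real_,
                 age_dx_mean = ci[["mean"]],
                 incident = if (!is.na(incident) && incident < 5 &&
                                incident > 0) NA_integer_ else incident,
                 incident_rate = incRate,
                 cancer_free = if (!is.na(cancerFree) && cancerFree < 5 &&
                                   cancerFree > 0) NA_integer_ else
                                     cancerFree,
                 cancer_free_rate = freeRate)
    }))
  }
  list(bins = binTab, strata = stratTab, middlePrevalence = midPrev)
}

#' Discrimination metrics for one score
#'
#' Convenience wrapper producing the headline metric set: ROC AUC,
#' precision-recall AUC, odds ratio per SD, and top-percentile prevalence
#' and fold enrichment.
#'
#' @inheritParams orPerSD
#' @param nBins percentile resolution (default 100).
#' @param middle middle reference band (default 48:53).
#' @return List: `auc`, `prAUC`, `orPerSD` (list), `topPrevalence`,
#'   `topFold`, `binSummary`.
#' @export
metricReport <- function(score, label, covariates = NULL, reference = score,
                         nBins = 100L, middle = 48:53) {
  bins <- percentileBins(score, nBins)
  bs <- summarizeBins(bins, label, middle = middle)
  top <- bs$bins[bs$bins$bin == nBins, ]
  list(auc = rocAUC(score, label)$auc,
       prAUC = prAUC(score, label),
       orPerSD = orPerSD(score, label, covariates, reference),
       topPrevalence = top$prevalence, topFold = top$fold,
       binSummary = bs)
}

#' Score correlation, PCA and age-dependency diagnostics
#'
#' Pairwise Spearman correlations between the scores (constant scores are
#' excluded with a message), an unscaled PCA of the component scores that
#' enter the DRSA (PRS and the Family, Mole, Susceptibility, Exposure and
#' Miscellaneous groups), and mean-score-versus-age-decile profiles split by
#' low / middle / high DRSA risk group — the diagnostic used to judge how
#' age-dependent each score is.
#'
#' @param scoreSet a [ScoreSet-class].
#' @param cancer outcome label to diagnose.
#' @param ages per-participant current ages.
#' @return List: `spearman` (correlation matrix), `pca` (`prcomp` object),
#'   `ageProfile` (data.frame: risk group x age decile x mean DRSA).
#' @export
scoreDiagnostics <- function(scoreSet, cancer, ages) {
  m <- scoreMatrix(scoreSet, cancer)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    message("excluding constant score(s) from correlations: ",
            paste(colnames(m)[sds == 0], collapse = ", "))
  }
  keep <- sds > 0
  rho <- cor(m[, keep, drop = FALSE], method = "spearman")
  comp <- intersect(c("PRS", "Family", "Mole", "Susceptibility", "Exposure",
                      "Miscellaneous"), colnames(m)[keep])
  pca <- stats::prcomp(m[, comp, drop = FALSE], center = TRUE,
                       scale. = FALSE)
  drsa <- m[, "DRSA"]
  grp <- cut(rank(drsa, ties.method = "first") / length(drsa),
             c(0, 1 / 3, 2 / 3, 1), labels = c("low", "middle", "high"))
  dec <- cut(rank(ages, ties.method = "first") / length(ages),
             seq(0, 1, 0.1), labels = FALSE, include.lowest = TRUE)
  prof <- aggregate(drsa, list(group = grp, age_decile = dec), mean)
  names(prof)[3] <- "mean_DRSA"
  prof$mean_age <- aggregate(ages, list(grp, dec), mean)$x
  list(spearman = rho, pca = pca, ageProfile = prof)
}
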