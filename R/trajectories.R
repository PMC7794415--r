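#' Bundled synthetic survival schedule
#'
#' A synthetic stand-in for a national all-cause yearly survival table
#' (fraction of a birth cohort still alive at each age), built from a
#' Gompertz mortality law with parameters giving life expectancy near 79
#' years. Any user table can be supplied instead via [readSurvivalTable()].
#'
#' @param ageRange inclusive age range (default 30-90).
#' @param b,c Gompertz baseline mortality and shape per year.
#' @return A [SurvivalTable-class], normalized to S(30) close to 1 within
#'   the grid.
#' @export
defaultSurvivalTable <- function(ageRange = c(30L, 90L), b = 4e-5,
                                 c = 0.085) {
  ages <- ageRange[1]:ageRange[2]
  H <- (b / c) * (exp(c * ages) - exp(c * 30))   # cumulative hazard from 30
  survivalTable(ages, exp(-H))
}

#' DRSA-stratified lifetime risk curves
#'
#' Retrospective lifetime-risk estimator: within each risk-score stratum
#' `g`, the raw lifetime risk at age `a` is the fraction of participants
#' currently aged at least `a` whose diagnosis (if any) occurred at or
#' before `a`. Each stratum's curve is then smoothed by isotonic regression
#' in age (weighted by the per-age risk sets), which guarantees the
#' monotonicity a cumulative risk must have. Strata are percentile ranges of
#' the score (by default decile-granularity bands with the top decile
#' separate).
#'
#' @param score per-participant risk score (typically the DRSA).
#' @param currentAge per-participant current age.
#' @param caseStatus binary 0/1 baseline case status.
#' @param ageAtDiagnosis age at diagnosis (`NA` for controls).
#' @param strata named list of percentile ranges `c(lo, hi)` (1-100).
#' @param ageRange age grid bounds.
#' @param cancer outcome label stored in the result.
#' @param smooth apply isotonic smoothing (default `TRUE`).
#' @return A [TrajectorySet-class]. Strata with fewer than 100 participants
#'   are flagged with a warning.
#' @export
lifetimeRiskCurves <- function(score, currentAge, caseStatus,
                               ageAtDiagnosis,
                               strata = list(`1-20` = c(1, 20),
                                             `21-40` = c(21, 40),
                                             `41-60` = c(41, 60),
                                             `61-80` = c(61, 80),
                                             `81-90` = c(81, 90),
                                             `91-100` = c(91, 100)),
                               ageRange = c(30L, 90L), cancer = "",
                               smooth = TRUE) {
  bins <- percentileBins(score, 100L)
  ages <- ageRange[1]:ageRange[2]
  y <- as.numeric(caseStatus)
  raw <- P <- matrix(NA_real_, length(ages), length(strata),
                     dimnames = list(ages, names(strata)))
  ns <- integer(length(strata))
  for (g in seq_along(strata)) {
    rg <- strata[[g]]
    idx <- bins >= rg[1] & bins <= rg[2]
    ns[g] <- sum(idx)
    if (ns[g] < 100)
      warning(sprintf("stratum '%s' has %d participants; curve unstable",
                      names(strata)[g], ns[g]))
    ca <- currentAge[idx]; yy <- y[idx]; ad <- ageAtDiagnosis[idx]
    atRisk <- vapply(ages, function(a) sum(ca >= a), numeric(1))
    nCases <- vapply(ages, function(a)
      sum(yy == 1 & !is.na(ad) & ad <= a & ca >= a), numeric(1))
    p <- ifelse(atRisk > 0, nCases / atRisk, NA_real_)
    raw[, g] <- p
    if (smooth) {
      ok <- !is.na(p) & atRisk > 0
      if (sum(ok) >= 2) {
        iso <- .weightedIsotonic(p[ok], atRisk[ok])
        p[ok] <- iso
      }
    }
    P[, g] <- p
  }
  new("TrajectorySet", cancer = cancer, ages = as.integer(ages),
      strata = data.frame(label = names(strata),
                          lo = vapply(strata, `[`, numeric(1), 1),
                          hi = vapply(strata, `[`, numeric(1), 2),
                          n = ns, row.names = NULL),
      raw = raw, prevalence = P)
}

## weighted pool-adjacent-violators (isoreg is unweighted); weights = risk
## set sizes so sparse old ages do not dominate
.weightedIsotonic <- function(y, w) {
  n <- length(y)
  val <- y; wt <- w; idx <- as.list(seq_len(n))
  i <- 1
  while (i < length(val)) {
    if (val[i] > val[i + 1] + 1e-15) {
      nv <- (val[i] * wt[i] + val[i + 1] * wt[i + 1]) / (wt[i] + wt[i + 1])
      val[i] <- nv; wt[i] <- wt[i] + wt[i + 1]
      idx[[i]] <- c(idx[[i]], idx[[i + 1]])
      val <- val[-(i + 1)]; wt <- wt[-(i + 1)]; idx <- idx[-(i + 1)]
      if (i > 1) i <- i - 1
    } else i <- i + 1
  }
  out <- numeric(n)
  for (k in seq_along(val)) out[idx[[k]]] <- val[k]
  out
}

#' Incidence from lifetime risk
#'
#' The m-year incidence at age `a` is
#' `I_a = (P_a - P_{a-m}) / (1 - P_{a-m})`: the probability of a first
#' diagnosis in `(a-m, a]` given disease-free at `a-m`. Applied exactly per
#' age point. Where `P_{a-m} = 1` the incidence is undefined and reported
#' absent; negative values (non-monotone input, which isotonic smoothing
#' prevents) are clamped to 0 with a warning.
#'
#' @param P lifetime-risk values on an integer age grid: a numeric vector
#'   (names = ages), a matrix (rows = ages), or a [TrajectorySet-class].
#' @param m window in years (default 1).
#' @return Incidence with the same shape as the input; the first `m` grid
#'   points are `NA` (no `P_{a-m}` available).
#' @export
incidenceFromPrevalence <- function(P, m = 1L) {
  if (is(P, "TrajectorySet")) P <- lifetimeRisk(P)
  f <- function(p) {
    n <- length(p)
    I <- rep(NA_real_, n)
    if (n > m) {
      lag <- p[seq_len(n - m)]
      cur <- p[(m + 1):n]
      val <- (cur - lag) / (1 - lag)
      val[!is.na(lag) & lag >= 1] <- NA_real_
      neg <- !is.na(val) & val < 0
      if (any(neg)) {
        warning("negative incidence clamped to 0 at ", sum(neg), " age(s)")
        val[neg] <- 0
      }
      I[(m + 1):n] <- val
    }
    I
  }
  if (is.matrix(P)) apply(P, 2, f) else {
    out <- f(as.numeric(P))
    names(out) <- names(P)
    out
  }
}

#' Survival-weighted expected age of diagnosis
#'
#' With yearly incidence `I_a` and population survival `S_a` over the
#' integer grid `a = 30..90`:
#' `m = sum(S_a I_a a) / sum(S_a I_a)` and
#' `SD = sqrt(sum(S_a I_a (a-m)^2) / sum(S_a I_a))` —
#' the incidence curve weighted by the fraction of the population still
#' alive to be diagnosed at each age.
#'
#' @param I yearly incidence on an integer age grid: named numeric vector,
#'   or a matrix with rownames the ages (a column per stratum).
#' @param S a [SurvivalTable-class] covering the grid.
#' @param ageRange grid bounds used for the sums (default 30-90).
#' @return data.frame with `mean` and `sd` (one row per stratum).
#' @export
expectedAgeOfDiagnosis <- function(I, S, ageRange = c(30L, 90L)) {
  stopifnot(is(S, "SurvivalTable"))
  f <- function(i, ages) {
    keep <- ages >= ageRange[1] & ages <= ageRange[2] & !is.na(i)
    ages <- ages[keep]; i <- i[keep]
    s <- S@survival[match(ages, S@age)]
    if (anyNA(s)) stop("survival table does not cover the age grid")
    w <- s * i
    tot <- sum(w)
    if (tot <= 0) stop("all-zero survival-weighted incidence: no expected onset")
    mu <- sum(w * ages) / tot
    c(mean = mu, sd = sqrt(sum(w * (ages - mu)^2) / tot))
  }
  if (is.matrix(I)) {
    ages <- as.integer(rownames(I))
    ## strata without any observed incidence get NA summaries rather than
    ## aborting the whole table
    out <- t(apply(I, 2, function(i)
      tryCatch(f(i, ages), error = function(e)
        c(mean = NA_real_, sd = NA_real_))))
    data.frame(stratum = colnames(I), mean = out[, "mean"],
               sd = out[, "sd"], row.names = NULL)
  } else {
    ages <- as.integer(names(I))
    if (!length(ages) || anyNA(ages))
      stop("I must carry ages as names (or rownames)")
    v <- f(as.numeric(I), ages)
    data.frame(stratum = "all", mean = v[["mean"]], sd = v[["sd"]])
  }
}

#' Classify participants from follow-up waves
#'
#' Deterministic mapping from baseline status and follow-up responses, per
#' cancer: a baseline control reporting a diagnosis in any answered wave is
#' `incident`; a baseline control answering at least one wave without a
#' diagnosis is `unchanged_control`; a baseline case reporting no treatment
#' in any answered wave is `cancer_free`; a baseline case reporting
#' treatment is `persistent_case`; participants answering no wave are
#' `non_respondent` and are excluded from rates. A baseline case whose
#' responses claim a first diagnosis (contradictory) is flagged and counted
#' as `persistent_case`.
#'
#' @param cohort cohort data.frame with follow-up columns
#'   `fu<k>_dx_<cancer>` / `fu<k>_tx_<cancer>`.
#' @param cancer outcome label.
#' @param waves wave indices to use (default: all present).
#' @return Factor of statuses with an attribute `"contradictory"` (logical
#'   vector marking flagged baseline cases).
#' @export
classifyFollowup <- function(cohort, cancer, waves = NULL) {
  if (is.null(waves)) {
    pat <- sprintf("^fu([0-9]+)_dx_%s$", cancer)
    hits <- regmatches(colnames(cohort), regexec(pat, colnames(cohort)))
    waves <- sort(as.integer(vapply(hits[lengths(hits) > 0], `[`,
                                    character(1), 2)))
  }
  if (!length(waves)) stop("no follow-up columns found for ", cancer)
  base <- cohort[[paste0("case_", cancer)]]
  dx <- sapply(waves, function(k) cohort[[sprintf("fu%d_dx_%s", k, cancer)]])
  tx <- sapply(waves, function(k) cohort[[sprintf("fu%d_tx_%s", k, cancer)]])
  dx <- matrix(dx, nrow = nrow(cohort))
  tx <- matrix(tx, nrow = nrow(cohort))
  answered <- rowSums(!is.na(dx) | !is.na(tx)) > 0
  anyDx <- rowSums(dx == 1, na.rm = TRUE) > 0
  anyTx <- rowSums(tx == 1, na.rm = TRUE) > 0
  status <- rep("non_respondent", nrow(cohort))
  contradictory <- base == 1 & anyDx
  status[answered & base == 0 & anyDx] <- "incident"
  status[answered & base == 0 & !anyDx] <- "unchanged_control"
  status[answered & base == 1 & !anyTx] <- "cancer_free"
  status[answered & base == 1 & anyTx] <- "persistent_case"
  status[answered & contradictory] <- "persistent_case"
  out <- factor(status, levels = c("incident", "cancer_free",
                                   "unchanged_control", "persistent_case",
                                   "non_respondent"))
  attr(out, "contradictory") <- contradictory & answered
  out
}

#' Expected versus observed yearly incidence per stratum
#'
#' Person-wave pooling over up to `window` follow-up waves: every answered
#' wave of a baseline control still disease-free contributes one one-year
#' at-risk window. The observed incidence of a stratum is reported
#' first-diagnoses per person-wave (with an exact binomial confidence
#' interval); the expected incidence averages, over the same person-waves,
#' the trajectory-derived yearly incidence
#' `(P_{a+k} - P_{a+k-1}) / (1 - P_{a+k-1})` at the participant's age in
#' that wave. Pooling per person-wave keeps the observed rate unbiased under
#' missing-at-random wave non-response, because each answered wave is
#' compared against exactly the window it covers.
#'
#' @param trajectories a [TrajectorySet-class] built on the same score.
#' @param score,currentAge per-participant score and baseline age (aligned
#'   with `cohort`).
#' @param cohort cohort data.frame carrying the follow-up columns
#'   `fu<k>_dx_<cancer>`.
#' @param cancer outcome label.
#' @param window maximum number of yearly waves pooled (default 2, i.e. a
#'   two-year prospective observation).
#' @return data.frame per stratum: `stratum`, `person_waves`, `incident`,
#'   `observed`, `obs_lo`, `obs_hi`, `expected`.
#' @export
expectedVsObservedIncidence <- function(trajectories, score, currentAge,
                                        cohort, cancer, window = 2L) {
  P <- lifetimeRisk(trajectories)
  ages <- trajectories@ages
  aMax <- max(ages)
  st <- trajectories@strata
  bins <- percentileBins(score, 100L)
  base <- cohort[[paste0("case_", cancer)]]
  waves <- seq_len(window)
  waves <- waves[sprintf("fu%d_dx_%s", waves, cancer) %in% colnames(cohort)]
  if (!length(waves)) stop("no follow-up columns found for ", cancer)
  dx <- sapply(waves, function(k) cohort[[sprintf("fu%d_dx_%s", k, cancer)]])
  dx <- matrix(dx, nrow = nrow(cohort))
  out <- NULL
  for (g in seq_len(nrow(st))) {
    idx <- bins >= st$lo[g] & bins <= st$hi[g]
    pw <- 0L; events <- 0L; expSum <- 0
    prior <- rep(FALSE, nrow(cohort))   # incident in an earlier answered wave
    for (k in seq_along(waves)) {
      atRisk <- idx & base == 0 & !is.na(dx[, k]) & !prior
      if (any(atRisk)) {
        pw <- pw + sum(atRisk)
        events <- events + sum(dx[atRisk, k] == 1)
        a <- pmin(currentAge[atRisk] + waves[k], aMax)
        Pprev <- P[match(a - 1L, ages), g]
        Pa <- P[match(a, ages), g]
        I1 <- (Pa - Pprev) / (1 - Pprev)
        expSum <- expSum + sum(I1, na.rm = TRUE)
      }
      prior <- prior | (!is.na(dx[, k]) & dx[, k] == 1)
    }
    if (pw == 0) next
    ci <- binom.test(events, pw)$conf.int
    out <- rbind(out, data.frame(
      stratum = st$label[g], person_waves = pw, incident = events,
      observed = events / pw, obs_lo = ci[1], obs_hi = ci[2],
      expected = expSum / pw))
  }
  out
}
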