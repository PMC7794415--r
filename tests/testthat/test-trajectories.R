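test_that("incidence formula: exact identities and degenerate cases", {
  ## P_{a-1} = 0, P_a = 0.1 gives I_a = 0.1; flat prevalence gives 0
  p <- c(`30` = 0, `31` = 0.1, `32` = 0.1)
  I <- incidenceFromPrevalence(p)
  expect_true(is.na(I[1]))
  expect_equal(unname(I[2]), 0.1, tolerance = 1e-15)
  expect_equal(unname(I[3]), 0, tolerance = 1e-15)
  ## constant hazard h: I_a = h exactly at every age
  h <- 0.02; ages <- 30:90
  P <- 1 - (1 - h)^(ages - 30); names(P) <- ages
  I <- incidenceFromPrevalence(P)
  expect_equal(unname(I[-1]), rep(h, 60), tolerance = 1e-12)
  ## window m > 1: closed form (1 - (1-h)^m)
  I2 <- incidenceFromPrevalence(P, m = 2)
  expect_equal(unname(I2[-(1:2)]), rep(1 - (1 - h)^2, 59), tolerance = 1e-12)
  ## saturated prevalence is undefined, negatives clamp with warning
  ps <- c(`30` = 0.5, `31` = 1, `32` = 1)
  expect_true(is.na(incidenceFromPrevalence(ps)[3]))
  expect_warning(In <- incidenceFromPrevalence(c(`30` = 0.3, `31` = 0.1)),
                 "clamped")
  expect_equal(unname(In[2]), 0)
})

test_that("expected age of diagnosis matches closed-form moments", {
  ages <- 30:90
  S1 <- survivalTable(ages, rep(1, 61))
  ## point mass at 50
  I <- setNames(rep(0, 61), ages); I["50"] <- 0.01
  out <- expectedAgeOfDiagnosis(I, S1)
  expect_equal(out$mean, 50, tolerance = 1e-12)
  expect_equal(out$sd, 0, tolerance = 1e-12)
  ## discrete uniform over 30..90: mean 60, sd sqrt(sum((a-60)^2)/61)
  Iu <- setNames(rep(0.005, 61), ages)
  out <- expectedAgeOfDiagnosis(Iu, S1)
  expect_equal(out$mean, 60, tolerance = 1e-12)
  expect_equal(out$sd, sqrt(sum((ages - 60)^2) / 61), tolerance = 1e-12)
  ## all-zero weights error
  expect_error(expectedAgeOfDiagnosis(setNames(rep(0, 61), ages), S1),
               "no expected onset")
  ## survival weighting shifts the mean downward
  Sdec <- survivalTable(ages, exp(-0.05 * (ages - 30)))
  outW <- expectedAgeOfDiagnosis(Iu, Sdec)
  expect_lt(outW$mean, 60)
})

test_that("expected age of diagnosis is shift-equivariant", {
  ages <- 30:90
  set.seed(81)
  I <- setNames(runif(61, 0, 0.02), ages)
  S <- survivalTable(ages, rep(1, 61))
  base <- expectedAgeOfDiagnosis(I, S)
  shifted <- setNames(as.numeric(I), ages + 5)
  Ss <- survivalTable(ages + 5, rep(1, 61))
  out <- expectedAgeOfDiagnosis(shifted, Ss, ageRange = c(35L, 95L))
  expect_equal(out$mean, base$mean + 5, tolerance = 1e-10)
  expect_equal(out$sd, base$sd, tolerance = 1e-10)
})

test_that("prevalence -> incidence -> prevalence round-trips exactly", {
  set.seed(82)
  for (rep in 1:5) {
    P <- randomMonotoneCurve()
    I <- incidenceFromPrevalence(P)
    Pback <- 1 - (1 - P[1]) * cumprod(c(1, 1 - I[-1]))
    expect_equal(unname(Pback), unname(P), tolerance = 1e-12)
  }
})

test_that("weighted isotonic regression reduces to isoreg with equal weights", {
  set.seed(83)
  for (rep in 1:10) {
    y <- rnorm(40)
    fit <- skinDRS:::.weightedIsotonic(y, rep(1, 40))
    expect_equal(fit, isoreg(y)$yf, tolerance = 1e-10)
  }
  ## weighting pulls the pooled value toward the heavy observation
  w <- skinDRS:::.weightedIsotonic(c(0.5, 0.1), c(9, 1))
  expect_equal(w, rep(0.46, 2), tolerance = 1e-12)
})

test_that("lifetime risk curves recover a constant-hazard cohort", {
  h <- 0.015
  cfg <- nullConfig(30000, h = c(h, 0.001, 0.001), seed = 84)
  sim <- generateCohort(cfg)
  co <- sim$cohort
  score <- rnorm(nrow(co))   # uninformative score, single wide stratum
  traj <- lifetimeRiskCurves(score, co$current_age, co$case_BCC,
                             co$age_dx_BCC,
                             strata = list(all = c(1, 100)), cancer = "BCC")
  P <- lifetimeRisk(traj)[, "all"]
  truth <- 1 - (1 - h)^(traj@ages - 30)
  ## Monte-Carlo agreement over the well-populated ages (risk sets thin out
  ## quickly above ~80 in an age distribution centred at 58)
  sub <- traj@ages <= 80
  expect_lt(max(abs(P[sub] - truth[sub])), 0.03)
  expect_true(all(diff(P[!is.na(P)]) > -1e-10))
  ## zero cases: flat zero curve
  traj0 <- lifetimeRiskCurves(score, co$current_age, rep(0, nrow(co)),
                              rep(NA, nrow(co)),
                              strata = list(all = c(1, 100)))
  expect_true(all(lifetimeRisk(traj0) == 0, na.rm = TRUE))
  ## small strata are flagged
  expect_warning(
    lifetimeRiskCurves(score[1:150], co$current_age[1:150],
                       co$case_BCC[1:150], co$age_dx_BCC[1:150],
                       strata = list(tiny = c(1, 10), rest = c(11, 100))),
    "unstable")
})

test_that("higher-hazard strata dominate lower ones at every age", {
  ## two groups with ordered hazards, stratified by a score that tracks them
  specs <- list(factorSpec("grp", "binary", "Mole", list(prob = 0.5),
                           beta = c(1.2, 0, 0)))
  cfg <- cohortSimConfig(nParticipants = 30000, nVariants = 4,
                         variantEffects = matrix(0, 4, 3,
                                                 dimnames = list(NULL, skinCancers())),
                         factorSpecs = specs, missingRate = 0,
                         sexEffect = c(BCC = 0, SCC = 0, melanoma = 0),
                         seed = 85)
  sim <- generateCohort(cfg)
  co <- sim$cohort
  traj <- lifetimeRiskCurves(sim$truth$lp[, "BCC"], co$current_age,
                             co$case_BCC, co$age_dx_BCC,
                             strata = list(lo = c(1, 45), hi = c(56, 100)))
  P <- lifetimeRisk(traj)
  sub <- traj@ages >= 40 & traj@ages <= 85
  expect_true(all(P[sub, "hi"] >= P[sub, "lo"]))
})

test_that("follow-up classification implements the definitions", {
  co <- data.frame(
    id = as.character(1:6), sex = "female", current_age = 60L,
    case_BCC = c(0L, 0L, 1L, 1L, 0L, 1L),
    fu1_dx_BCC = c(1L, 0L, 0L, 0L, NA, 1L),
    fu1_tx_BCC = c(NA, NA, 0L, 1L, NA, 0L))
  st <- classifyFollowup(co, "BCC")
  expect_equal(as.character(st),
               c("incident", "unchanged_control", "cancer_free",
                 "persistent_case", "non_respondent", "persistent_case"))
  ## the baseline case claiming a first diagnosis is flagged contradictory
  expect_true(attr(st, "contradictory")[6])
  expect_false(any(attr(st, "contradictory")[1:5]))
  expect_error(classifyFollowup(co, "SCC"), "no follow-up")
})

test_that("expected vs observed incidence agree on a null stratum", {
  cfg <- nullConfig(4000, h = c(0, 0, 0), seed = 86, followupYears = 2L,
                    responseRate = 1)
  sim <- generateFollowup(generateCohort(cfg))
  co <- sim$cohort
  score <- rnorm(nrow(co))
  traj <- lifetimeRiskCurves(score, co$current_age, co$case_BCC,
                             co$age_dx_BCC, strata = list(all = c(1, 100)))
  tab <- expectedVsObservedIncidence(traj, score, co$current_age, co, "BCC")
  expect_equal(tab$observed, 0)
  expect_equal(tab$expected, 0, tolerance = 1e-12)
  ## person-wave denominator: two answered waves per baseline control
  expect_equal(tab$person_waves, 2L * sum(co$case_BCC == 0))
})

test_that("survival tables validate and round-trip through text", {
  expect_error(survivalTable(30:32, c(1, 1.1, 0.9)), "survival")
  expect_error(survivalTable(30:32, c(0.9, 0.95, 0.9)), "non-increasing")
  S <- defaultSurvivalTable()
  expect_equal(S@age, 30:90)
  expect_true(all(diff(S@survival) <= 0))
  tmp <- tempfile(fileext = ".tsv")
  writeSurvivalTable(S, tmp)
  S2 <- readSurvivalTable(tmp)
  expect_equal(S2@survival, S@survival, tolerance = 1e-12)
})
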