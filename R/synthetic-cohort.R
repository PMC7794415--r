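#' CohortSimConfig: parameters of the synthetic cohort generator
#'
#' Bundles everything the generator needs: cohort size, variant panel,
#' risk-factor catalog with true effects, the per-year baseline diagnosis
#' hazards for the three cancers, follow-up behaviour, missingness and seed.
#'
#' @slot nParticipants,nVariants cohort and variant panel sizes.
#' @slot maf per-variant minor allele frequencies in (0, 0.5].
#' @slot variantEffects nVariants x 3 matrix of true per-dosage log-odds
#'   (columns named by [skinCancers()]).
#' @slot factorSpecs list of [FactorSpec-class] objects.
#' @slot ageRange inclusive current-age range in years (default 30-90).
#' @slot baselineHazard ages x 3 matrix of per-year baseline diagnosis
#'   probabilities (rownames = ages over `ageRange`).
#' @slot followupYears number of yearly follow-up survey waves.
#' @slot responseRate per-wave probability a participant answers.
#' @slot recurrenceRate per-year probability a baseline case reports
#'   treatment in a follow-up wave.
#' @slot missingRate completely-at-random missingness applied to factor
#'   columns only.
#' @slot femaleFraction fraction of female participants.
#' @slot sexEffect per-cancer log hazard ratio for males vs females.
#' @slot fhBase,fhSlope baseline probability that a given relative is
#'   affected, and its increase per SD of the participant's own summed
#'   linear predictor (shared-risk proxy for family history).
#' @slot ldPairs data.frame (`i`, `j`, `r`) of variant index pairs forced to
#'   be correlated (dosage of `j` copies `i` with probability `r`); empty by
#'   default (variants independent).
#' @slot mechanism disease mechanism. `"logit-cumulative"` (default): the
#'   cumulative incidence by age `a` is `plogis(qlogis(P0(a)) + lp)` with
#'   `P0` the baseline cumulative incidence implied by `baselineHazard`, and
#'   the yearly hazard is derived from it — exactly consistent with the
#'   cross-sectional logistic model class fitted downstream.
#'   `"hazard"`: yearly hazard `baselineHazard(a) * exp(lp)` clipped to
#'   `[0,1]` (proportional hazards). The two agree closely at low
#'   prevalence.
#' @slot seed integer RNG seed; identical config + seed gives byte-identical
#'   cohorts.
#' @export
setClass("CohortSimConfig", representation(
  nParticipants = "integer", nVariants = "integer", maf = "numeric",
  variantEffects = "matrix", factorSpecs = "list", ageRange = "integer",
  baselineHazard = "matrix", followupYears = "integer",
  responseRate = "numeric", recurrenceRate = "numeric",
  missingRate = "numeric", femaleFraction = "numeric", sexEffect = "numeric",
  fhBase = "numeric", fhSlope = "numeric", ldPairs = "data.frame",
  mechanism = "character", seed = "integer"))

setValidity("CohortSimConfig", function(object) {
  msg <- NULL
  if (object@nParticipants < 1) msg <- c(msg, "nParticipants must be >= 1")
  if (length(object@maf) != object@nVariants)
    msg <- c(msg, "maf must have length nVariants")
  if (any(object@maf <= 0) || any(object@maf > 0.5))
    msg <- c(msg, "maf values must lie in (0, 0.5]")
  if (!identical(dim(object@variantEffects),
                 c(object@nVariants, 3L)))
    msg <- c(msg, "variantEffects must be nVariants x 3")
  if (length(object@ageRange) != 2 || diff(object@ageRange) <= 0)
    msg <- c(msg, "ageRange must be [min, max] with min < max")
  ages <- object@ageRange[1]:object@ageRange[2]
  if (nrow(object@baselineHazard) != length(ages))
    msg <- c(msg, "baselineHazard needs one row per age in ageRange")
  if (any(object@baselineHazard < 0) || any(object@baselineHazard > 1))
    msg <- c(msg, "hazards must lie in [0,1]")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0,1)")
  if (object@followupYears < 0) msg <- c(msg, "followupYears must be >= 0")
  if (!object@mechanism %in% c("logit-cumulative", "hazard"))
    msg <- c(msg, "mechanism must be 'logit-cumulative' or 'hazard'")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CohortSimConfig", function(object) {
  cat(sprintf(paste0(
    "CohortSimConfig: n = %d, %d variants, %d factors, ages %d-%d, ",
    "%d follow-up wave(s), missing rate %.2f, seed %d\n"),
    object@nParticipants, object@nVariants, length(object@factorSpecs),
    object@ageRange[1], object@ageRange[2], object@followupYears,
    object@missingRate, object@seed))
})

#' Default per-year baseline diagnosis hazards
#'
#' Exponentially increasing per-year hazards calibrated so that a cohort with
#' the default factor catalog reaches cross-sectional prevalences of roughly
#' 14\%, 7\% and 4\% for BCC, SCC and melanoma — the case fractions typical
#' of a self-reported skin-cancer survey cohort aged 30-90.
#'
#' @param ageRange inclusive age range.
#' @param h0 per-cancer hazard at the lower age bound.
#' @param growth log-linear increase of the hazard per year of age.
#' @return An ages x 3 matrix with rownames the ages.
#' @export
defaultBaselineHazard <- function(ageRange = c(30L, 90L),
                                  h0 = c(BCC = 0.00225, SCC = 0.00104,
                                         melanoma = 0.00052),
                                  growth = 0.04) {
  ages <- ageRange[1]:ageRange[2]
  H <- outer(exp(growth * (ages - ageRange[1])), h0)
  dimnames(H) <- list(ages, skinCancers())
  pmin(H, 1)
}

#' Default risk-factor catalog
#'
#' Ships 27 mixed-type risk factors named after the classical skin-cancer
#' risk factors (dysplastic moles, mole counts, pigmentation, sun exposure,
#' BMI/weight, ...), grouped into the four non-demographic score groups with
#' the sizes the grouped scores expect (Mole 4, Susceptibility 8, Exposure 8,
#' Miscellaneous 7). Effect directions follow the skin-cancer literature
#' (e.g. dysplastic moles raise melanoma hazard by a factor 6.7; actinic
#' keratosis before age 40 raises BCC/SCC by more than 3x; males about 1.6x);
#' magnitudes are generator truth, not estimates from any particular cohort.
#' Factors carry a `source` of `"survey"` or `"database"`: the latter emulate
#' phenotypes found outside the baseline survey and enter the analysis only
#' through the additional-phenotype scan.
#'
#' @param ageSlopes if `FALSE`, every factor is made age-independent
#'   (all `ageSlope = 0`) — used by age-independence diagnostics.
#' @return A list of [FactorSpec-class] objects.
#' @export
defaultFactorCatalog <- function(ageSlopes = TRUE) {
  s <- function(x) if (ageSlopes) x else 0
  ord <- function(k) rep(1 / k, k)
  specs <- list(
    ## Mole group (4)
    factorSpec("dysplastic_moles", "binary", "Mole", list(prob = 0.05),
               beta = c(0.90, 0.85, log(6.7))),
    factorSpec("mole_count", "ordinal", "Mole",
               list(probs = c(0.35, 0.35, 0.20, 0.10)), ageSlope = s(-0.15),
               beta = c(0.12, 0.10, 0.30)),
    factorSpec("mole_size", "ordinal", "Mole", list(probs = c(0.6, 0.3, 0.1)),
               beta = c(0.08, 0.08, 0.22)),
    factorSpec("actinic_keratosis_before_40", "binary", "Mole",
               list(prob = 0.04), ageSlope = s(0.25),
               beta = c(log(3.2), log(3.1), 0.35)),
    ## Susceptibility group (8)
    factorSpec("skin_color", "ordinal", "Susceptibility",
               list(probs = c(0.25, 0.45, 0.30)),
               beta = c(0.22, 0.22, 0.18)),
    factorSpec("hair_color", "categorical", "Susceptibility",
               list(levels = c("dark", "brown", "blond", "red"),
                    probs = c(0.35, 0.40, 0.18, 0.07)),
               beta = rbind(dark = c(0, 0, 0), brown = c(0.08, 0.08, 0.08),
                            blond = c(0.25, 0.25, 0.22),
                            red = c(0.55, 0.55, 0.50))),
    factorSpec("eye_color", "ordinal", "Susceptibility",
               list(probs = c(0.45, 0.30, 0.25)),
               beta = c(0.10, 0.10, 0.10)),
    factorSpec("freckles", "ordinal", "Susceptibility",
               list(probs = c(0.55, 0.30, 0.15)),
               beta = c(0.16, 0.16, 0.16)),
    factorSpec("tanning_ability", "ordinal", "Susceptibility",
               list(probs = ord(4)), beta = c(0.15, 0.15, 0.12)),
    factorSpec("sunburn_susceptibility", "ordinal", "Susceptibility",
               list(probs = ord(4)), beta = c(0.18, 0.18, 0.15)),
    factorSpec("skin_sensitivity", "ordinal", "Susceptibility",
               list(probs = c(0.5, 0.3, 0.2)), beta = c(0.10, 0.10, 0.10)),
    factorSpec("childhood_freckling", "ordinal", "Susceptibility",
               list(probs = c(0.6, 0.25, 0.15)), beta = c(0.07, 0.07, 0.09)),
    ## Exposure group (8)
    factorSpec("sunbathing_before_30", "ordinal", "Exposure",
               list(probs = ord(4)), ageSlope = s(0.10),
               beta = c(0.15, 0.20, 0.12)),
    factorSpec("weekly_sun_exposure", "continuous", "Exposure",
               list(mean = 120, sd = 60), ageSlope = s(0.10),
               beta = c(0.08, 0.08, 0.06)),
    factorSpec("tanning_bed_use", "ordinal", "Exposure",
               list(probs = c(0.584, 0.3, 0.116)),
               beta = c(0.10, 0.13, 0.10)),
    factorSpec("severe_sunburns", "ordinal", "Exposure",
               list(probs = ord(4)), beta = c(0.12, 0.12, 0.12)),
    factorSpec("outdoor_occupation", "binary", "Exposure",
               list(prob = 0.25), beta = c(0.12, 0.15, 0.06)),
    factorSpec("sunscreen_use", "ordinal", "Exposure",
               list(probs = ord(4)), beta = c(-0.08, -0.08, -0.05)),
    factorSpec("childhood_sunny_climate", "binary", "Exposure",
               list(prob = 0.30), beta = c(0.09, 0.10, 0.07)),
    factorSpec("uv_index_residence", "continuous", "Exposure",
               list(mean = 5, sd = 2), beta = c(0.07, 0.08, 0.05)),
    ## Miscellaneous group (7)
    factorSpec("bmi", "continuous", "Miscellaneous",
               list(mean = 27, sd = 5), ageSlope = s(0.08),
               beta = c(-0.12, -0.10, -0.08)),
    factorSpec("weight", "continuous", "Miscellaneous",
               list(mean = 78, sd = 15, derived_from = "bmi", rho = 0.93),
               beta = c(-0.05, -0.05, -0.04)),
    factorSpec("clean_desk", "binary", "Miscellaneous", list(prob = 0.5),
               beta = c(0.08, 0.07, 0.06)),
    factorSpec("education", "ordinal", "Miscellaneous",
               list(probs = ord(4)), beta = c(0.06, 0.04, 0.08)),
    factorSpec("smoking", "ordinal", "Miscellaneous",
               list(probs = c(0.55, 0.25, 0.20)), beta = c(-0.06, 0.05, -0.08)),
    factorSpec("alcohol", "ordinal", "Miscellaneous",
               list(probs = c(0.4, 0.4, 0.2)), beta = c(0.06, 0.05, 0.05)),
    factorSpec("physical_activity", "ordinal", "Miscellaneous",
               list(probs = ord(4)), beta = c(0.04, 0.03, 0.05))
  )
  database <- c("bmi", "weight", "clean_desk", "education", "smoking",
                "alcohol", "physical_activity", "uv_index_residence",
                "outdoor_occupation", "childhood_sunny_climate",
                "childhood_freckling")
  lapply(specs, function(sp) {
    sp@params$source <- if (sp@name %in% database) "database" else "survey"
    sp
  })
}

#' Construct a CohortSimConfig
#'
#' All arguments default to the package's reference study conditions: a
#' survey cohort aged 30-90 centred in the 50-70 band, the
#' [defaultFactorCatalog()], baseline hazards giving BCC/SCC/melanoma
#' prevalences around 14/7/4 per cent, per-column missingness of 5 per cent
#' (within the 2-15 per cent band typical of survey questions), two yearly
#' follow-up waves with a 56 per cent response rate, and ten causal variants
#' per cancer at allelic odds ratios near 1.2.
#'
#' @param nParticipants,nVariants,maf,variantEffects,factorSpecs,ageRange,
#'   baselineHazard,followupYears,responseRate,recurrenceRate,missingRate,
#'   femaleFraction,sexEffect,fhBase,fhSlope,ldPairs,seed see
#'   [CohortSimConfig-class].
#' @return A validated [CohortSimConfig-class].
#' @export
#' @examples
#' cfg <- cohortSimConfig(nParticipants = 500, nVariants = 20, seed = 1)
#' cfg
cohortSimConfig <- function(nParticipants = 5000L, nVariants = 200L,
                            maf = NULL, variantEffects = NULL,
                            factorSpecs = defaultFactorCatalog(),
                            ageRange = c(30L, 90L), baselineHazard = NULL,
                            followupYears = 2L, responseRate = 0.56,
                            recurrenceRate = 0.30, missingRate = 0.05,
                            femaleFraction = 0.60,
                            sexEffect = c(BCC = log(1.6), SCC = log(1.6),
                                          melanoma = log(1.6)),
                            fhBase = 0.12, fhSlope = 0.45,
                            ldPairs = data.frame(i = integer(), j = integer(),
                                                 r = numeric()),
                            mechanism = c("logit-cumulative", "hazard"),
                            seed = 1L) {
  mechanism <- match.arg(mechanism)
  nVariants <- as.integer(nVariants)
  if (is.null(maf))
    maf <- rep(seq(0.05, 0.5, length.out = 20), length.out = nVariants)
  if (is.null(variantEffects)) {
    variantEffects <- matrix(0, nVariants, 3,
                             dimnames = list(NULL, skinCancers()))
    for (k in 1:3) {
      idx <- seq.int(1 + (k - 1) * 5, length.out = 10)
      idx <- idx[idx <= nVariants]
      variantEffects[idx, k] <- 0.2
    }
  }
  if (is.null(baselineHazard))
    baselineHazard <- defaultBaselineHazard(ageRange)
  new("CohortSimConfig", nParticipants = as.integer(nParticipants),
      nVariants = nVariants, maf = maf, variantEffects = variantEffects,
      factorSpecs = factorSpecs, ageRange = as.integer(ageRange),
      baselineHazard = baselineHazard, followupYears = as.integer(followupYears),
      responseRate = responseRate, recurrenceRate = recurrenceRate,
      missingRate = missingRate, femaleFraction = femaleFraction,
      sexEffect = setNames(as.numeric(sexEffect), skinCancers()),
      fhBase = fhBase, fhSlope = fhSlope, ldPairs = ldPairs,
      mechanism = mechanism, seed = as.integer(seed))
}

#' Generate Hardy-Weinberg genotype dosages
#'
#' Draws per-variant dosages as Binomial(2, maf) (columns independent unless
#' `ldPairs` forces correlated pairs) and lays the variants out on a synthetic
#' genetic map: variants are assigned round-robin to chromosomes 1-22 with
#' 200 kb spacing within a chromosome.
#'
#' @param n number of participants.
#' @param maf vector of minor allele frequencies in (0, 0.5].
#' @param seed RNG seed.
#' @param ldPairs optional data.frame (`i`, `j`, `r`): dosage of variant `j`
#'   is replaced by that of `i` with probability `r`, inducing dosage
#'   correlation close to `r` (pairs are placed adjacently on the map). Used
#'   to exercise clumping.
#' @param spacingBp base-pair spacing of consecutive variants on a chromosome.
#' @return A [GenotypeDosage-class] (variants x participants).
#' @export
#' @examples
#' g <- generateGenotypes(100, maf = rep(0.3, 10), seed = 7)
#' dim(dosages(g))
generateGenotypes <- function(n, maf, seed = 1L, ldPairs = NULL,
                              spacingBp = 200000) {
  if (n < 1) stop("n must be >= 1")
  if (any(maf <= 0) || any(maf > 0.5))
    stop("maf values must lie in (0, 0.5]")
  set.seed(as.integer(seed))
  m <- length(maf)
  D <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), nrow = m, ncol = n,
              byrow = TRUE)
  nChrom <- min(22L, m)
  chrom <- rep_len(seq_len(nChrom), m)
  pos <- integer(m)
  for (cc in seq_len(nChrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- seq_along(idx) * spacingBp
  }
  if (!is.null(ldPairs) && nrow(ldPairs)) {
    for (r in seq_len(nrow(ldPairs))) {
      i <- ldPairs$i[r]; j <- ldPairs$j[r]
      copy <- runif(n) < ldPairs$r[r]
      D[j, copy] <- D[i, copy]
      chrom[j] <- chrom[i]
      pos[j] <- pos[i] + 1000L
    }
  }
  variants <- data.frame(
    id = sprintf("v%04d", seq_len(m)), chrom = chrom, pos = pos,
    effect_allele = rep_len(c("A", "C", "G", "T"), m), maf = maf,
    stringsAsFactors = FALSE)
  g <- GenotypeDosage(D, variants)
  colnames(g) <- sprintf("p%06d", seq_len(n))
  g
}


## Per-cancer conditional yearly hazard h(a | lp) under the configured
## mechanism. For "logit-cumulative": P(a | lp) = plogis(qlogis(P0(a)) + lp)
## with P0 the baseline cumulative incidence, and
## h(a | lp) = (P(a) - P(a-1)) / (1 - P(a-1)). Supports vector age `a`
## aligned with `idx`.
.yearlyHazardFun <- function(config, k, lpk) {
  ages <- config@ageRange[1]:config@ageRange[2]
  h0 <- config@baselineHazard[, k]
  if (config@mechanism == "hazard") {
    elp <- exp(lpk)
    function(a, idx) h0[match(a, ages)] * elp[idx]
  } else {
    P0 <- 1 - cumprod(1 - c(0, h0[-1])) # P0(aMin) = 0
    q0 <- ifelse(P0 <= 0, -Inf, qlogis(P0))
    function(a, idx) {
      ia <- match(a, ages)
      Pa <- plogis(q0[ia] + lpk[idx])
      Pprev <- plogis(q0[ia - 1L] + lpk[idx])
      ifelse(Pprev >= 1, 1, (Pa - Pprev) / (1 - Pprev))
    }
  }
}

## Draw one factor column and its centred per-cancer hazard contribution.
## Ordinal factors use a latent-logistic cut at thresholds matching the
## marginal level probabilities, shifted by ageSlope * z(age).
.drawFactor <- function(sp, zage, store) {
  n <- length(zage)
  p <- sp@params
  if (sp@kind == "binary") {
    prob <- plogis(qlogis(p$prob) + sp@ageSlope * zage)
    x <- rbinom(n, 1L, prob)
    contrib <- outer(x - p$prob, rep(1, 3)) * rep(sp@beta, each = n)
  } else if (sp@kind == "ordinal") {
    k <- length(p$probs)
    cuts <- qlogis(cumsum(p$probs)[-k])
    lat <- sp@ageSlope * zage + rlogis_(n)
    x <- findInterval(lat, cuts) + 1L
    mu <- sum(seq_len(k) * p$probs)
    contrib <- outer(x - mu, rep(1, 3)) * rep(sp@beta, each = n)
  } else if (sp@kind == "continuous") {
    if (!is.null(p$derived_from)) {
      src <- store[[p$derived_from]]
      zsrc <- (src - mean(src)) / sd(src)
      z <- p$rho * zsrc + sqrt(1 - p$rho^2) * rnorm(n)
    } else {
      z <- sp@ageSlope * zage + rnorm(n) * sqrt(max(0, 1 - sp@ageSlope^2))
    }
    x <- p$mean + p$sd * z
    zc <- (x - p$mean) / p$sd
    contrib <- outer(zc, rep(1, 3)) * rep(sp@beta, each = n)
  } else { # categorical
    x <- sample(p$levels, n, replace = TRUE, prob = p$probs)
    B <- sp@beta # levels x 3
    idx <- match(x, p$levels)
    centre <- colSums(B * p$probs)
    contrib <- B[idx, , drop = FALSE] -
      matrix(centre, n, 3, byrow = TRUE)
  }
  list(x = x, contrib = contrib)
}

rlogis_ <- function(n) stats::rlogis(n)

#' Generate a synthetic case-control survey cohort
#'
#' Draws participant ages (discretized truncated normal centred at 58, so
#' about half the cohort is 50-70), sex, the factor catalog with its age
#' dependencies, and genotypes; then runs, for each cancer, a yearly
#' diagnosis process from the lower age bound to each participant's current
#' age with hazard `h(a) = baselineHazard(a) * exp(lp)` (clipped to `[0,1]`),
#' where `lp` is the centred sum of factor, sex and genotype contributions.
#' The first success sets case status and the age at diagnosis, giving every
#' downstream stage (cross-sectional models, trajectories, follow-up) a
#' common ground truth. Family-history indicators are drawn with probability
#' increasing in the participant's own summed linear predictor, and
#' missingness is applied completely at random to factor columns only.
#'
#' @param config a [CohortSimConfig-class].
#' @return A list with elements `cohort` (data.frame), `genotypes`
#'   ([GenotypeDosage-class]) and `truth` (list: `lp` matrix, the config, the
#'   fraction of clipped person-years).
#' @export
#' @examples
#' sim <- generateCohort(cohortSimConfig(nParticipants = 300, nVariants = 10,
#'                                       seed = 42))
#' table(sim$cohort$case_BCC)
generateCohort <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nParticipants
  cancers <- skinCancers()
  aMin <- config@ageRange[1]; aMax <- config@ageRange[2]

  ## ages: truncated normal via inverse-cdf so no clumping at the bounds
  u <- runif(n, pnorm(aMin - 0.5, 58, 13), pnorm(aMax + 0.5, 58, 13))
  age <- pmin(pmax(round(qnorm(u, 58, 13)), aMin), aMax)
  zage <- (age - 60) / 15
  sex <- ifelse(runif(n) < config@femaleFraction, "female", "male")

  lp <- matrix(0, n, 3, dimnames = list(NULL, cancers))
  lp <- lp + outer((sex == "male") - (1 - config@femaleFraction),
                   config@sexEffect)

  store <- list()
  for (sp in config@factorSpecs) {
    drawn <- .drawFactor(sp, zage, store)
    store[[sp@name]] <- drawn$x
    lp <- lp + drawn$contrib
  }

  genotypes <- generateGenotypes(n, config@maf, seed = config@seed + 7L,
                                 ldPairs = config@ldPairs)
  if (any(config@variantEffects != 0)) {
    Dc <- t(dosages(genotypes)) -
      matrix(2 * config@maf, n, config@nVariants, byrow = TRUE)
    lp <- lp + Dc %*% config@variantEffects
  }

  ## yearly diagnosis process: hazard applied at ages (aMin+1)..current_age,
  ## so with zero effects P(case | age a) = 1 - prod(1 - h0) over a - aMin
  ## years. Under "logit-cumulative" the per-year hazard is derived from the
  ## participant cumulative incidence plogis(qlogis(P0(a)) + lp); under
  ## "hazard" it is baseline * exp(lp) clipped to [0,1].
  case <- matrix(0L, n, 3, dimnames = list(NULL, cancers))
  ageDx <- matrix(NA_integer_, n, 3, dimnames = list(NULL, cancers))
  clipped <- 0; personYears <- 0
  ages <- aMin:aMax
  for (k in 1:3) {
    elp <- exp(lp[, k])
    hFun <- .yearlyHazardFun(config, k, lp[, k])
    for (a in (aMin + 1L):aMax) {
      idx <- which(age >= a & case[, k] == 0L)
      if (!length(idx)) next
      h <- hFun(a, idx)
      clipped <- clipped + sum(h > 1)
      personYears <- personYears + length(idx)
      hit <- runif(length(idx)) < pmin(h, 1)
      case[idx[hit], k] <- 1L
      ageDx[idx[hit], k] <- a
    }
  }
  if (personYears > 0 && clipped / personYears > 0.01)
    warning(sprintf(
      "hazard clipped on %.2f%% of person-years; effect sizes too large for the baseline hazard",
      100 * clipped / personYears))

  ## family history from the proband's own linear predictor (shared risk)
  zlp <- rowSums(lp); zlp <- (zlp - mean(zlp)) / max(sd(zlp), 1e-12)
  pfh <- plogis(qlogis(config@fhBase) + config@fhSlope * zlp)
  fh <- sapply(1:4, function(i) rbinom(n, 1L, pfh))
  colnames(fh) <- c("fh_father", "fh_mother", "fh_sibling", "fh_child")

  ## optional disease descriptors for cases
  stage <- matrix(NA_integer_, n, 3, dimnames = list(NULL, cancers))
  recent <- matrix(NA_integer_, n, 3, dimnames = list(NULL, cancers))
  for (k in 1:3) {
    ic <- which(case[, k] == 1L)
    if (length(ic)) {
      stage[ic, k] <- sample(1:4, length(ic), replace = TRUE,
                             prob = c(0.80, 0.15, 0.04, 0.01))
      recent[ic, k] <- 1L + rbinom(length(ic), 2L, 0.15)
    }
  }

  cohort <- data.frame(id = sprintf("p%06d", seq_len(n)), sex = sex,
                       current_age = age, stringsAsFactors = FALSE)
  for (nm in names(store)) cohort[[nm]] <- store[[nm]]
  cohort <- cbind(cohort, as.data.frame(fh))
  for (k in 1:3) {
    cc <- cancers[k]
    cohort[[paste0("case_", cc)]] <- case[, k]
    cohort[[paste0("age_dx_", cc)]] <- ageDx[, k]
    cohort[[paste0("stage_", cc)]] <- stage[, k]
    cohort[[paste0("recent_dx_", cc)]] <- recent[, k]
  }

  ## MCAR missingness on factor columns only
  if (config@missingRate > 0) {
    for (nm in names(store)) {
      miss <- runif(n) < config@missingRate
      cohort[[nm]][miss] <- NA
    }
  }

  list(cohort = cohort, genotypes = genotypes,
       truth = list(lp = lp, config = config,
                    clippedFraction = if (personYears > 0)
                      clipped / personYears else 0))
}

#' Generate yearly follow-up survey waves
#'
#' For each wave `k = 1..followupYears`, a `responseRate` fraction of
#' participants answers. Baseline controls report a diagnosis in the last
#' year (`fu<k>_dx_<cancer>`) with their own yearly hazard evaluated at
#' `current_age + k`; baseline cases (and participants already incident in an
#' earlier wave) report treatment in the last year (`fu<k>_tx_<cancer>`) with
#' probability `recurrenceRate`. Non-respondents carry `NA` in all wave
#' columns.
#'
#' @param sim result of [generateCohort()].
#' @param config the same [CohortSimConfig-class] (its `followupYears`,
#'   `responseRate`, `recurrenceRate` and hazards are used).
#' @return `sim` with follow-up columns appended to `sim$cohort`.
#' @export
generateFollowup <- function(sim, config = sim$truth$config) {
  if (config@followupYears < 1) stop("followupYears must be >= 1")
  set.seed(config@seed + 31L)
  cohort <- sim$cohort
  lp <- sim$truth$lp
  n <- nrow(cohort)
  cancers <- skinCancers()
  ages <- config@ageRange[1]:config@ageRange[2]
  isCase <- sapply(cancers, function(cc) cohort[[paste0("case_", cc)]] == 1L)
  for (k in seq_len(config@followupYears)) {
    responded <- runif(n) < config@responseRate
    for (j in 1:3) {
      cc <- cancers[j]
      a <- pmin(cohort$current_age + k, config@ageRange[2])
      hFun <- .yearlyHazardFun(config, j, lp[, j])
      h <- pmin(hFun(a, seq_len(n)), 1)
      newDx <- as.integer(!isCase[, j] & runif(n) < h)
      tx <- as.integer(isCase[, j] & runif(n) < config@recurrenceRate)
      dxCol <- ifelse(isCase[, j], 0L, newDx)
      txCol <- ifelse(isCase[, j], tx, NA_integer_)
      dxCol[!responded] <- NA_integer_
      txCol[!responded] <- NA_integer_
      cohort[[sprintf("fu%d_dx_%s", k, cc)]] <- dxCol
      cohort[[sprintf("fu%d_tx_%s", k, cc)]] <- txCol
      isCase[, j] <- isCase[, j] | (responded & !is.na(newDx) & newDx == 1L)
    }
  }
  sim$cohort <- cohort
  sim
}

#' Names of the factor columns of a simulated cohort
#'
#' @param config a [CohortSimConfig-class].
#' @param source restrict to `"survey"` or `"database"` factors
#'   (`NULL` = all).
#' @return Character vector of factor names.
#' @export
factorNames <- function(config, source = NULL) {
  specs <- config@factorSpecs
  if (!is.null(source))
    specs <- Filter(function(sp) identical(sp@params$source, source), specs)
  vapply(specs, function(sp) sp@name, character(1))
}
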