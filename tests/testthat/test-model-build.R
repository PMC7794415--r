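test_that("imputation respects observed cells and MCAR unbiasedness", {
  cfg <- tinyConfig(n = 4000, seed = 41, missingRate = 0)
  co <- generateCohort(cfg)$cohort
  co$cont <- rnorm(4000, 50, 10) + co$risk_ordinal
  fi <- rbind(specTable(cfg),
              data.frame(name = "cont", kind = "continuous", group = "Miscellaneous",
                         source = "survey"))
  ## no missing values: identity
  out <- imputePhenotypes(co, fi)
  expect_identical(out$cohort, co)

  ## 10% MCAR on the continuous factor
  set.seed(1)
  miss <- runif(4000) < 0.1
  co2 <- co; co2$cont[miss] <- NA
  out2 <- imputePhenotypes(co2, fi)
  expect_false(anyNA(out2$cohort$cont))
  ## observed cells untouched
  expect_identical(out2$cohort$cont[!miss], co$cont[!miss])
  ## imputed values are unbiased for the observed distribution: the mean of
  ## the filled column deviates only by the noise of the n_miss donor draws
  seMiss <- sd(co2$cont, na.rm = TRUE) * sqrt(sum(miss)) / 4000
  expect_lt(abs(mean(out2$cohort$cont) - mean(co2$cont, na.rm = TRUE)),
            3 * seMiss)
  expect_true(identical(out2$flags$cont, miss))
})

test_that("columns at or above 50% missingness are excluded with a warning", {
  cfg <- tinyConfig(n = 200, seed = 42, missingRate = 0)
  co <- generateCohort(cfg)$cohort
  co$mostly_gone <- NA_real_
  fi <- rbind(specTable(cfg),
              data.frame(name = "mostly_gone", kind = "continuous",
                         group = "Miscellaneous", source = "survey"))
  expect_warning(out <- imputePhenotypes(co, fi), "mostly_gone")
  expect_false("mostly_gone" %in% colnames(out$cohort))
  expect_equal(out$dropped, "mostly_gone")
})

test_that("single-binary-factor GLM equals the 2x2 table log odds ratio", {
  set.seed(43)
  x <- rbinom(2000, 1, 0.3)
  y <- rbinom(2000, 1, plogis(-1 + 0.8 * x))
  co <- data.frame(id = as.character(1:2000), sex = "female",
                   current_age = 50L, x = x)
  fi <- data.frame(name = "x", kind = "binary", group = "Mole",
                   source = "survey")
  d <- buildFactorDesign(co, fi, includeDemo = FALSE, includeFH = FALSE)
  m <- fitRiskGLM(d, y)
  tab <- table(x, y)
  lor <- log(tab[2, 2] * tab[1, 1] / (tab[2, 1] * tab[1, 2]))
  expect_equal(riskCoefficients(m)$beta, unname(lor), tolerance = 1e-8)
})

test_that("GLM fit equals an independent Newton optimizer to 1e-6", {
  for (s in 1:8) {
    set.seed(s)
    n <- 400; p <- sample(2:9, 1)
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("c", seq_len(p))
    y <- rbinom(n, 1, plogis(X %*% rnorm(p, 0, 0.5)))
    if (length(unique(y)) < 2) next
    co <- data.frame(id = as.character(1:n), sex = "female",
                     current_age = 50L, X)
    fi <- data.frame(name = colnames(X), kind = "continuous",
                     group = "Miscellaneous", source = "survey")
    d <- buildFactorDesign(co, fi, includeDemo = FALSE, includeFH = FALSE,
                           degrees = setNames(rep(1L, p), colnames(X)))
    m <- fitRiskGLM(d, y)
    oracle <- irlsLogistic(cbind(1, designMatrix(d)), y)
    expect_lt(max(abs(c(m@intercept, riskCoefficients(m)$beta) - oracle)),
              1e-6)
  }
})

test_that("a null model explains nothing and flags rank deficiency", {
  set.seed(44)
  n <- 3000
  co <- data.frame(id = as.character(1:n), sex = "female", current_age = 50L,
                   a = rnorm(n), b = rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, 0.2)
  fi <- data.frame(name = c("a", "b"), kind = c("continuous", "binary"),
                   group = "Mole", source = "survey")
  d <- buildFactorDesign(co, fi, includeDemo = FALSE, includeFH = FALSE)
  m <- fitRiskGLM(d, y)
  expect_lt(devianceExplained(m), 0.005)
  expect_true(all(abs(riskCoefficients(m)$beta) <
                    3 * riskCoefficients(m)$se + 1e-9 |
                    riskCoefficients(m)$p > 0.0027))
  co$b2 <- co$b
  fi2 <- rbind(fi, data.frame(name = "b2", kind = "binary", group = "Mole",
                              source = "survey"))
  d2 <- buildFactorDesign(co, fi2, includeDemo = FALSE, includeFH = FALSE)
  expect_error(fitRiskGLM(d2, y), "aliased.*b2|b2.*aliased")
})

test_that("orthogonal polynomial age bases are orthonormal and reapplicable", {
  cfg <- tinyConfig(n = 1000, seed = 45)
  co <- generateCohort(cfg)$cohort
  d <- buildFactorDesign(co, specTable(cfg), agePoly = 3L)
  agecols <- designMap(d)$column[designMap(d)$factor == "current_age"]
  P <- designMatrix(d)[, agecols]
  expect_equal(crossprod(P), diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  ## recipe reapplied to the same cohort reproduces the matrix exactly
  d2 <- applyDesign(d, co)
  expect_equal(designMatrix(d2), designMatrix(d), tolerance = 1e-12)
})

test_that("polynomial degree selection finds planted curvature", {
  set.seed(46)
  n <- 6000
  x <- rnorm(n)
  yc <- rbinom(n, 1, plogis(-1.5 + 0.6 * x^3 - 0.4 * x))
  expect_gte(selectPolyDegree(x, yc), 3L)
  yl <- rbinom(n, 1, plogis(-1 + 0.5 * x))
  expect_equal(selectPolyDegree(x, yl), 2L)
})

test_that("stage-1 selection applies the union rule and alpha = 1 keeps all", {
  specs <- list(
    factorSpec("one_cancer", "binary", "Mole", list(prob = 0.3),
               beta = c(log(2), 0, 0)),       # effect in BCC only
    factorSpec("noise", "binary", "Exposure", list(prob = 0.3),
               beta = c(0, 0, 0)))
  cfg <- cohortSimConfig(nParticipants = 20000, nVariants = 4,
                         variantEffects = matrix(0, 4, 3,
                                                 dimnames = list(NULL, skinCancers())),
                         factorSpecs = specs, missingRate = 0, seed = 47)
  sim <- generateCohort(cfg)
  co <- sim$cohort
  d <- buildFactorDesign(co, specTable(cfg))
  outcomes <- lapply(setNames(skinCancers(), skinCancers()),
                     function(cc) co[[paste0("case_", cc)]])
  tr <- stage1Select(d, outcomes)
  expect_true("one_cancer" %in% tr@kept)        # kept for all by the union
  expect_false(tr@perCancer$SCC$kept[tr@perCancer$SCC$factor == "one_cancer"])
  trAll <- stage1Select(d, outcomes, alpha = 1)
  expect_setequal(trAll@kept, names(d@recipe))
})

test_that("additional-phenotype scan: alias skip, null nulls, planted hit", {
  cfg <- tinyConfig(n = 12000, seed = 48, betas = c(log(2), 0.3, 1.0))
  sim <- generateCohort(cfg)
  co <- sim$cohort
  d <- buildFactorDesign(co, specTable(cfg))
  outcomes <- lapply(setNames(skinCancers(), skinCancers()),
                     function(cc) co[[paste0("case_", cc)]])
  set.seed(1)
  extra <- data.frame(
    duplicate = co$risk_binary,               # aliased with a base factor
    null1 = rnorm(12000), null2 = rbinom(12000, 1, 0.5),
    planted = co$risk_binary)                 # same, but name differs
  extra$planted <- co$risk_strong             # strong causal factor
  base <- subsetDesign(d, setdiff(names(d@recipe), "risk_strong"))
  scan <- scanAdditional(base, outcomes, extra, alpha = 1e-8)
  expect_equal(scan$note[scan$phenotype == "duplicate"], "aliased")
  expect_false(any(scan$candidate[scan$phenotype %in% c("null1", "null2")]))
  expect_true(scan$candidate[scan$phenotype == "planted"])
})

test_that("variable clustering groups duplicates and picks the right representative", {
  set.seed(49)
  n <- 500
  base <- rnorm(n)
  dat <- data.frame(
    a1 = base, a2 = base, a3 = base + rnorm(n, 0, 0.01),
    n1 = rnorm(n), n2 = factor(sample(letters[1:3], n, TRUE)))
  cl <- clusterVariables(dat, nClusters = 3,
                         pvalues = c(a1 = 1e-9, a2 = 1e-3, a3 = 1e-3,
                                     n1 = 0.5, n2 = 0.5),
                         missingness = c(a1 = 0, a2 = 0, a3 = 0.2,
                                         n1 = 0, n2 = 0))
  asg <- cl$assignment
  expect_equal(asg[["a1"]], asg[["a2"]])
  expect_equal(asg[["a1"]], asg[["a3"]])
  expect_false(asg[["n1"]] == asg[["a1"]])
  expect_false(asg[["n2"]] == asg[["a1"]])
  ## representative of the duplicated block is its lowest-p member
  expect_true("a1" %in% cl$representatives)
  ## first merge of exact duplicates loses essentially nothing
  expect_lt(cl$homogeneityLoss[1], 1e-6)
  ## singleton clustering is trivial
  one <- clusterVariables(dat["a1"], nClusters = 1)
  expect_equal(unname(one$assignment), 1L)
})

test_that("deviance decomposition telescopes and ranks the dominant factor first", {
  cfg <- tinyConfig(n = 10000, seed = 50, betas = c(0.3, 0.2, 1.6))
  sim <- generateCohort(cfg)
  co <- sim$cohort
  d <- buildFactorDesign(co, specTable(cfg), includeDemo = TRUE,
                         includeFH = FALSE)
  y <- co$case_BCC
  dec <- devianceDecomposition(d, y)
  m <- fitRiskGLM(d, y)
  expect_equal(sum(dec$marginal), devianceExplained(m), tolerance = 1e-10)
  ## age dominates in this configuration (it drives the baseline hazard)
  expect_equal(dec$factor[1], "current_age")
  ## a null factor contributes essentially nothing
  co$null <- rnorm(nrow(co))
  fi <- rbind(specTable(cfg), data.frame(name = "null", kind = "continuous",
                                         group = "Miscellaneous",
                                         source = "survey"))
  d2 <- buildFactorDesign(co, fi, includeDemo = FALSE, includeFH = FALSE)
  dec2 <- devianceDecomposition(d2, y)
  expect_lt(dec2$marginal[dec2$factor == "null"], 0.002)
})

test_that("VIF identities: orthogonal columns, closed form, exact collinearity", {
  n <- 128
  X <- cbind(a = rep(c(-1, 1), n / 2), b = rep(c(-1, -1, 1, 1), n / 4))
  expect_equal(unname(vif(X)), c(1, 1), tolerance = 1e-10)
  set.seed(51)
  x1 <- rnorm(500); x2 <- 0.95 * x1 + sqrt(1 - 0.95^2) * rnorm(500)
  v <- vif(cbind(x1 = x1, x2 = x2))
  r2 <- cor(x1, x2)^2
  expect_equal(unname(v), rep(1 / (1 - r2), 2), tolerance = 1e-8)
  expect_gt(v[["x1"]], 5)   # near the classical BMI/weight range
  vd <- vif(cbind(u = x1, v = x1, w = rnorm(500)))
  expect_true(is.infinite(vd[["u"]]) && is.infinite(vd[["v"]]))
  expect_equal(attr(vd, "aliased")$partner[1], "v")
})

test_that("interaction tests: self-pair error, null calibration point, planted effect", {
  set.seed(52)
  n <- 4000
  co <- data.frame(id = as.character(1:n), sex = "female", current_age = 50L,
                   f1 = rbinom(n, 1, 0.4), f2 = rbinom(n, 1, 0.5))
  fi <- data.frame(name = c("f1", "f2"), kind = "binary", group = "Mole",
                   source = "survey")
  d <- buildFactorDesign(co, fi, includeDemo = FALSE, includeFH = FALSE)
  yNull <- rbinom(n, 1, plogis(-1 + 0.4 * co$f1 + 0.3 * co$f2))
  expect_error(testInteractions(d, yNull, data.frame(a = "f1", b = "f1")),
               "itself")
  yInt <- rbinom(n, 1, plogis(-1.5 + 0.3 * co$f1 + 0.2 * co$f2 +
                                1.2 * co$f1 * co$f2))
  res <- testInteractions(d, yInt, data.frame(a = "f1", b = "f2"))
  expect_equal(res$df, 1L)
  expect_gt(res$devianceGain, 0)
  expect_lt(res$p, 0.01)
})
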