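test_that("PC1 separates a planted two-population structure", {
  set.seed(21)
  n <- 400; m <- 80
  grp <- rep(0:1, each = n / 2)
  maf <- cbind(runif(m, 0.1, 0.4), runif(m, 0.1, 0.4))
  maf[1:50, 2] <- pmin(maf[1:50, 1] + 0.3, 0.6)   # frequency shift
  D <- sapply(seq_len(n), function(i) rbinom(m, 2, maf[, grp[i] + 1]))
  g <- GenotypeDosage(D, data.frame(id = sprintf("v%02d", 1:m),
                                    chrom = 1L, pos = seq_len(m) * 1000L,
                                    effect_allele = "A", maf = rowMeans(D) / 2))
  pcs <- computePCs(g, k = 2)
  r <- cor(pcs[, 1], grp)
  expect_gt(abs(r), 0.9)
})

test_that("computePCs edge behaviour: k = 0, constant columns, equivariance", {
  g <- generateGenotypes(100, maf = rep(0.3, 12), seed = 3)
  expect_equal(ncol(computePCs(g, k = 0)), 0)

  D <- dosages(g); D[1, ] <- 2   # constant variant
  g2 <- GenotypeDosage(D, variantInfo(g))
  expect_warning(computePCs(g2, k = 2), "constant")

  pcs <- computePCs(g, k = 3)
  perm <- sample(ncol(g))
  pcsP <- computePCs(g[, perm], k = 3)
  expect_equal(unname(pcsP[, 1:3]), unname(pcs[perm, 1:3]),
               tolerance = 1e-8)
})

test_that("projected PCs reproduce training coordinates on the same panel", {
  g <- generateGenotypes(150, maf = rep(c(0.2, 0.4), 10), seed = 13)
  pcs <- computePCs(g, k = 4)
  proj <- projectPCs(g, pcs)
  expect_equal(unname(proj), unname(pcs[, 1:4]), tolerance = 1e-8)
})

test_that("GWAS scan recovers a planted dosage effect and matches IRLS", {
  beta <- 0.3
  nv <- 12
  ve <- matrix(0, nv, 3, dimnames = list(NULL, skinCancers()))
  ve[3, ] <- beta
  cfg <- cohortSimConfig(nParticipants = 12000, nVariants = nv,
                         maf = rep(0.3, nv), variantEffects = ve,
                         factorSpecs = list(), missingRate = 0,
                         baselineHazard = defaultBaselineHazard(
                           h0 = c(BCC = 0.004, SCC = 0.001, melanoma = 0.001)),
                         seed = 31)
  sim <- generateCohort(cfg)
  y <- sim$cohort$case_BCC
  cov <- cbind(age = sim$cohort$current_age,
               male = as.numeric(sim$cohort$sex == "male"))
  assoc <- runGWAS(sim$genotypes, y, covariates = cov)
  hit <- assoc[3, ]
  expect_lt(abs(hit$beta - beta), 3 * hit$se)
  expect_lt(hit$p, 1e-4)

  ## single-variant fit equals the independent Newton oracle to 1e-6
  x <- dosages(sim$genotypes)[3, ]
  M <- cbind(1, cov, x)
  expect_lt(abs(irlsLogistic(M, y)[4] - hit$beta), 1e-6)
})

test_that("GWAS flags degenerate variants instead of selecting them", {
  g <- generateGenotypes(300, maf = c(0.3, 0.3, 0.02), seed = 7)
  D <- dosages(g)
  y <- rbinom(300, 1, 0.3)
  cov <- matrix(D[1, ], ncol = 1)  # covariate identical to variant 1
  assoc <- runGWAS(g, y, covariates = cov, mafFloor = 0.05)
  expect_equal(assoc$note[1], "non-identifiable")
  expect_true(is.na(assoc$p[1]))
  expect_equal(assoc$note[3], "maf_below_floor")
  expect_error(runGWAS(g, rep(1, 300)), "both classes")
})

test_that("genomic-control lambda behaves at and off the null", {
  expect_equal(genomicControlLambda(rep(0.5, 200)), 1.0, tolerance = 1e-12)
  set.seed(11)
  p <- runif(100000)
  expect_gt(genomicControlLambda(p), 0.98)
  expect_lt(genomicControlLambda(p), 1.02)
  ## doubling every chi-square statistic doubles lambda
  chi <- qchisq(p[1:1000], 1, lower.tail = FALSE)
  lam1 <- genomicControlLambda(pchisq(chi, 1, lower.tail = FALSE))
  lam2 <- genomicControlLambda(pchisq(2 * chi, 1, lower.tail = FALSE))
  expect_equal(lam2, 2 * lam1, tolerance = 1e-10)
  expect_error(genomicControlLambda(runif(50)), "100")
})

test_that("clumping keeps the smaller-p member of a duplicate pair", {
  lp <- data.frame(i = 2L, j = 5L, r = 1.0)   # exact duplicate columns
  g <- generateGenotypes(500, maf = rep(0.3, 8), seed = 15, ldPairs = lp)
  assoc <- data.frame(variantInfo(g)[c("id", "chrom", "pos",
                                       "effect_allele", "maf")],
                      beta = 0.2, se = 0.05,
                      p = c(0.5, 1e-9, 0.5, 0.5, 1e-8, 1e-7, 0.5, 0.5),
                      note = "")
  m <- clumpThreshold(assoc, g, pThreshold = 1e-6)
  sel <- prsVariants(m)$id
  expect_true("v0002" %in% sel)
  expect_false("v0005" %in% sel)
  expect_true("v0006" %in% sel)    # independent significant variant kept
})

test_that("clumping trivia: empty selection and independent variants", {
  g <- generateGenotypes(200, maf = rep(0.4, 5), seed = 16)
  assoc <- data.frame(variantInfo(g)[c("id", "chrom", "pos",
                                       "effect_allele", "maf")],
                      beta = 0.1, se = 0.05, p = rep(0.5, 5), note = "")
  expect_equal(nrow(prsVariants(clumpThreshold(assoc, g))), 0)
  assoc$p <- 1e-8
  ## independent (r^2 ~ 0) variants are all selected
  sel <- prsVariants(clumpThreshold(assoc, g))$id
  expect_setequal(sel, assoc$id)
})

test_that("clumping equals the exhaustive greedy oracle and ignores row order", {
  for (s in 1:12) {
    set.seed(s)
    nv <- sample(8:20, 1)
    lp <- data.frame(i = 1L, j = 2L, r = 0.95)
    g <- generateGenotypes(300, maf = runif(nv, 0.1, 0.5), seed = s,
                           ldPairs = lp)
    assoc <- data.frame(variantInfo(g)[c("id", "chrom", "pos",
                                         "effect_allele", "maf")],
                        beta = rnorm(nv, 0, 0.2), se = 0.05,
                        p = 10^runif(nv, -10, -2), note = "")
    D <- dosages(g)
    r2 <- cor(t(D))^2
    dimnames(r2) <- list(assoc$id, assoc$id)
    oracle <- clumpBrute(assoc, r2, 1e-4, 250000, 0.1)
    got <- prsVariants(clumpThreshold(assoc, g, pThreshold = 1e-4))$id
    expect_identical(got, oracle)
    shuffled <- assoc[sample(nv), ]
    got2 <- prsVariants(clumpThreshold(shuffled, g, pThreshold = 1e-4))$id
    expect_identical(got2, oracle)
  }
})

test_that("PRS arithmetic identities hold", {
  g <- generateGenotypes(50, maf = c(0.3, 0.2), seed = 19)
  mk <- function(w) new("PRSModel",
    variants = data.frame(id = c("v0001", "v0002"), chrom = 1:2,
                          pos = c(200000L, 200000L), effect_allele = "A",
                          weight = w, p = 1e-8, maf = c(0.3, 0.2)),
    pThreshold = 1e-6, windowBp = 250000, r2Max = 0.1, cancer = "")
  expect_true(all(computePRS(g, mk(c(0, 0))) == 0))
  s1 <- computePRS(g, mk(c(1, 0)))
  expect_equal(unname(s1), unname(dosages(g)[1, ]))
  ## dosages (0,1,2) with weight ln 2 score (0, 0.693, 1.386)
  D <- matrix(c(0, 1, 2), 1, 3)
  gd <- GenotypeDosage(D, data.frame(id = "w1", chrom = 1L, pos = 1L,
                                     effect_allele = "A", maf = 0.25))
  mw <- mk(c(log(2), 0)); mw@variants <- mw@variants[1, ]; mw@variants$id <- "w1"
  expect_equal(unname(computePRS(gd, mw)), c(0, log(2), 2 * log(2)))
  ## linearity: weights w1 + w2
  s12 <- computePRS(g, mk(c(0.3, 0.7)))
  expect_equal(s12, computePRS(g, mk(c(0.3, 0))) + computePRS(g, mk(c(0, 0.7))))
  ## absent variant errors with its id
  bad <- mk(c(1, 1)); bad@variants$id <- c("v0001", "nope")
  expect_error(computePRS(g, bad), "nope")
})

test_that("PRS missing dosages fall back to 2*maf", {
  D <- matrix(c(NA, 1, 2), 1, 3)
  g <- GenotypeDosage(D, data.frame(id = "v1", chrom = 1L, pos = 1L,
                                    effect_allele = "A", maf = 0.3))
  m <- new("PRSModel",
           variants = data.frame(id = "v1", chrom = 1L, pos = 1L,
                                 effect_allele = "A", weight = 1, p = 1e-8,
                                 maf = 0.3),
           pThreshold = 1e-6, windowBp = 250000, r2Max = 0.1, cancer = "")
  expect_equal(unname(computePRS(g, m)), c(0.6, 1, 2))
})

test_that("association power: null size, monotonicity, validation", {
  a <- 1e-4
  expect_equal(associationPower(0.1, 1.0, a, 1000, 1000), a,
               tolerance = 1e-12)
  p1 <- associationPower(0.1, 1.2, 1e-6, 5000, 20000)
  expect_gt(associationPower(0.1, 1.2, 1e-6, 10000, 20000), p1)
  expect_gt(associationPower(0.1, 1.2, 1e-6, 5000, 40000), p1)
  expect_gt(associationPower(0.1, 1.5, 1e-6, 5000, 20000), p1)
  expect_gt(associationPower(0.1, 1.2, 1e-4, 5000, 20000), p1)
  expect_error(associationPower(0.6, 1.2, 0.05, 100, 100), "maf")
  expect_error(associationPower(0.1, -1, 0.05, 100, 100), "oddsRatio")
  expect_error(associationPower(0.1, 1.2, 2, 100, 100), "alpha")
})

test_that("a null-phenotype PRS has no out-of-sample discrimination", {
  ## selection on training, evaluation on validation: AUC must sit at 0.5
  cfg <- cohortSimConfig(nParticipants = 20000, nVariants = 60,
                         variantEffects = matrix(0, 60, 3,
                                                 dimnames = list(NULL, skinCancers())),
                         factorSpecs = list(), missingRate = 0, seed = 23)
  sim <- generateCohort(cfg)
  y <- sim$cohort$case_BCC
  train <- seq_len(10000); valid <- 10001:20000
  gT <- sim$genotypes[, train]; gV <- sim$genotypes[, valid]
  assoc <- runGWAS(gT, y[train])
  m <- clumpThreshold(assoc, gT, pThreshold = 0.2)   # force winners in
  expect_gt(nrow(prsVariants(m)), 0)
  prs <- computePRS(gV, m)
  auc <- rocAUC(prs, y[valid])$auc
  expect_gt(auc, 0.48); expect_lt(auc, 0.52)
})
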