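## Independent oracles used to cross-check the package implementations.
## These deliberately avoid the code paths they verify.

## Newton-Raphson logistic regression (hand-rolled IRLS, independent of
## stats::glm.fit)
irlsLogistic <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    score <- crossprod(X, y - mu)
    H <- crossprod(X * W, X)
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

## O(n^2) all-pairs concordance AUC
aucBrute <- function(score, label) {
  s1 <- score[label == 1]; s0 <- score[label == 0]
  tot <- 0
  for (a in s1) tot <- tot + sum(a > s0) + 0.5 * sum(a == s0)
  tot / (length(s1) * length(s0))
}

## exhaustive greedy clumping on small instances: same rule, written
## directly over a precomputed r^2 matrix
clumpBrute <- function(assoc, r2, pThreshold, windowBp, r2Max) {
  cand <- assoc[!is.na(assoc$p) & assoc$p <= pThreshold, , drop = FALSE]
  cand <- cand[order(cand$p, cand$chrom, cand$pos), , drop = FALSE]
  alive <- cand$id
  sel <- character(0)
  while (length(alive)) {
    top <- alive[1]
    sel <- c(sel, top)
    row <- cand[cand$id == top, ]
    keep <- character(0)
    for (v in setdiff(alive, top)) {
      rv <- cand[cand$id == v, ]
      near <- rv$chrom == row$chrom & abs(rv$pos - row$pos) <= windowBp
      if (!(near && r2[top, v] > r2Max)) keep <- c(keep, v)
    }
    alive <- keep
  }
  sel
}

## minimal factor catalog for fast simulations
tinyCatalog <- function(betas = c(0.5, 0.4, 0.8)) {
  list(
    factorSpec("risk_binary", "binary", "Mole", list(prob = 0.2),
               beta = rep(betas[1], 3)),
    factorSpec("risk_ordinal", "ordinal", "Exposure",
               list(probs = c(0.5, 0.3, 0.2)), beta = rep(betas[2], 3)),
    factorSpec("risk_strong", "binary", "Susceptibility", list(prob = 0.1),
               beta = rep(betas[3], 3))
  )
}

tinyConfig <- function(n = 2000, nVariants = 10, seed = 1,
                       betas = c(0.5, 0.4, 0.8), missingRate = 0, ...) {
  cohortSimConfig(
    nParticipants = n, nVariants = nVariants,
    variantEffects = matrix(0, nVariants, 3,
                            dimnames = list(NULL, skinCancers())),
    factorSpecs = tinyCatalog(betas), missingRate = missingRate,
    seed = seed, ...)
}

## constant-hazard, zero-effect configuration (closed-form ground truth)
nullConfig <- function(n, h = c(0.01, 0.005, 0.002), seed = 1, ...) {
  ages <- 30:90
  H <- matrix(rep(h, each = length(ages)), length(ages), 3,
              dimnames = list(ages, skinCancers()))
  cohortSimConfig(
    nParticipants = n, nVariants = 4,
    variantEffects = matrix(0, 4, 3, dimnames = list(NULL, skinCancers())),
    factorSpecs = list(), baselineHazard = H, missingRate = 0,
    sexEffect = c(BCC = 0, SCC = 0, melanoma = 0), fhSlope = 0,
    seed = seed, ...)
}

## random monotone prevalence curve on an integer age grid
randomMonotoneCurve <- function(ages = 30:90) {
  inc <- runif(length(ages), 0, 0.02)
  p <- cumsum(inc)
  p <- p / max(1, max(p) / 0.9)   # keep below 1
  p[1] <- p[1] * runif(1)
  names(p) <- ages
  p
}
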