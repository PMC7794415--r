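#' Principal components of a dosage matrix
#'
#' PCA of the column-standardized participants x variants dosage matrix.
#' Constant variants are excluded with a warning. The sign convention fixes
#' the first nonzero loading of each component to be positive, so results do
#' not depend on the underlying SVD implementation.
#'
#' @param genotypes a [GenotypeDosage-class].
#' @param k number of components (default 5, the usual ancestry covariate
#'   set). `k = 0` returns a zero-column matrix.
#' @return Numeric matrix participants x k of PC coordinates, with an
#'   attribute `"sdev"` carrying the component standard deviations.
#' @export
computePCs <- function(genotypes, k = 5L) {
  X <- t(dosages(genotypes))
  if (k >= min(dim(X))) stop("k must be smaller than both dimensions")
  if (k == 0) {
    out <- matrix(0, nrow(X), 0)
    rownames(out) <- rownames(X)
    return(out)
  }
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant variant(s) excluded from PCA")
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE, rank. = k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(scores))) {
    load <- pc$rotation[, j]
    first <- load[which(abs(load) > 1e-12)[1]]
    if (!is.na(first) && first < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  attr(scores, "sdev") <- pc$sdev[seq_len(k)]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(rot))) {
    first <- rot[which(abs(rot[, j]) > 1e-12)[1], j]
    if (!is.na(first) && first < 0) rot[, j] <- -rot[, j]
  }
  attr(scores, "rotation") <- rot
  attr(scores, "center") <- pc$center
  attr(scores, "scale") <- pc$scale
  scores
}

#' Project new participants onto trained principal components
#'
#' Applies the centering, scaling and loadings fitted by [computePCs()] on a
#' training panel to new participants, so validation coordinates never
#' influence the components.
#'
#' @param genotypes a [GenotypeDosage-class] for the new participants (same
#'   variant panel).
#' @param pcs the training PC matrix returned by [computePCs()].
#' @return Matrix of projected coordinates.
#' @export
projectPCs <- function(genotypes, pcs) {
  rot <- attr(pcs, "rotation")
  if (is.null(rot)) stop("pcs must come from computePCs()")
  X <- t(dosages(genotypes))[, rownames(rot), drop = FALSE]
  X <- sweep(X, 2, attr(pcs, "center"))
  X <- sweep(X, 2, attr(pcs, "scale"), "/")
  out <- X %*% rot
  colnames(out) <- colnames(pcs)
  out
}

## Logistic fit of y on cbind(1, covars, x); returns beta, se, p for the last
## column, with convergence / identifiability flags.
.waldScan <- function(y, base, x) {
  M <- cbind(base, x)
  q <- qr(M)
  if (q$rank < ncol(M))
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                note = "non-identifiable"))
  fit <- suppressWarnings(
    glm.fit(M, y, family = binomial(), control = list(maxit = 50)))
  if (!fit$converged || any(abs(fit$coefficients) > 15))
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                note = "non-converged"))
  ## Wald se from the weighted cross-product
  W <- fit$weights
  XtWX <- crossprod(M * sqrt(W))
  V <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(V))
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                note = "singular"))
  j <- ncol(M)
  beta <- fit$coefficients[j]
  se <- sqrt(V[j, j])
  list(beta = beta, se = se,
       p = 2 * pnorm(-abs(beta / se)), note = "")
}

#' Per-variant logistic association scan
#'
#' For each variant, fits by maximum likelihood the logistic regression of
#' the binary phenotype on the dosage plus the supplied covariates, and
#' reports the dosage's Wald statistics. Variants below the minor-allele
#' frequency floor are skipped; non-converged or non-identifiable fits are
#' flagged with absent p-values so they never enter variant selection.
#'
#' @param genotypes a [GenotypeDosage-class].
#' @param phenotype binary 0/1 vector, one per participant.
#' @param covariates optional numeric matrix / data.frame of covariates
#'   (age, sex, principal components, ...); must be full rank.
#' @param mafFloor variants with empirical MAF below this are skipped
#'   (default 0.01).
#' @return Association table: data.frame with `id`, `chrom`, `pos`,
#'   `effect_allele`, `maf` (empirical), `beta`, `se`, `p`, `note`.
#' @export
runGWAS <- function(genotypes, phenotype, covariates = NULL,
                    mafFloor = 0.01) {
  y <- as.numeric(phenotype)
  if (length(unique(y[!is.na(y)])) < 2)
    stop("phenotype must contain both classes")
  D <- dosages(genotypes)
  if (ncol(D) != length(y)) stop("phenotype length must match participants")
  base <- matrix(1, length(y), 1)
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    base <- cbind(base, C)
    if (qr(base)$rank < ncol(base)) stop("covariates are not full rank")
  }
  info <- variantInfo(genotypes)
  f <- rowMeans(D) / 2
  maf <- pmin(f, 1 - f)
  out <- data.frame(info[c("id", "chrom", "pos", "effect_allele")],
                    maf = maf, beta = NA_real_, se = NA_real_, p = NA_real_,
                    note = "", stringsAsFactors = FALSE)
  for (j in seq_len(nrow(D))) {
    if (maf[j] < mafFloor) { out$note[j] <- "maf_below_floor"; next }
    r <- .waldScan(y, base, D[j, ])
    out$beta[j] <- r$beta; out$se[j] <- r$se; out$p[j] <- r$p
    out$note[j] <- r$note
  }
  rownames(out) <- NULL
  out
}

#' Genomic-control inflation factor
#'
#' Lambda is the median observed 1-df chi-square quantile divided by the
#' median of the null chi-square(1) distribution (0.4549).
#'
#' @param p vector of at least 100 association p-values.
#' @return A single number; 1 under the null.
#' @export
#' @examples
#' genomicControlLambda(runif(1000))
genomicControlLambda <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 100)
    stop("need at least 100 p-values for a stable lambda")
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1)
}

#' Clumping-and-thresholding variant selection
#'
#' Greedy selection for a polygenic risk score: repeatedly take the
#' unselected variant with the smallest p-value at or below `pThreshold`,
#' then discard every unselected variant on the same chromosome within
#' `windowBp` whose empirical dosage r-squared with it exceeds `r2Max`.
#' Ties in p are broken by (chromosome, position). Variants with absent
#' p-values (flagged scan failures) never enter the selection.
#'
#' @param assoc association table from [runGWAS()].
#' @param genotypes the [GenotypeDosage-class] the scan was run on (used for
#'   the dosage correlations).
#' @param pThreshold p-value cut-off (default 1e-6).
#' @param windowBp clumping window (default 250 kb).
#' @param r2Max maximum tolerated dosage r-squared (default 0.1).
#' @param cancer optional outcome label recorded in the model.
#' @return A [PRSModel-class]; empty selection is permitted.
#' @export
clumpThreshold <- function(assoc, genotypes, pThreshold = 1e-6,
                           windowBp = 250000, r2Max = 0.1, cancer = "") {
  cand <- assoc[!is.na(assoc$p) & assoc$p <= pThreshold, , drop = FALSE]
  cand <- cand[order(cand$p, cand$chrom, cand$pos), , drop = FALSE]
  D <- dosages(genotypes)
  sel <- character(0)
  alive <- cand$id
  while (length(alive)) {
    top <- alive[1]
    sel <- c(sel, top)
    row <- cand[cand$id == top, ]
    rest <- setdiff(alive, top)
    if (length(rest)) {
      near <- cand$id %in% rest & cand$chrom == row$chrom &
        abs(cand$pos - row$pos) <= windowBp
      drop <- character(0)
      if (any(near)) {
        r2 <- suppressWarnings(
          as.vector(cor(D[top, ], t(D[cand$id[near], , drop = FALSE])))^2)
        r2[is.na(r2)] <- 0
        drop <- cand$id[near][r2 > r2Max]
      }
      alive <- setdiff(rest, drop)
    } else alive <- character(0)
  }
  v <- assoc[match(sel, assoc$id),
             c("id", "chrom", "pos", "effect_allele", "p", "maf")]
  v$weight <- assoc$beta[match(sel, assoc$id)]
  rownames(v) <- NULL
  new("PRSModel",
      variants = v[c("id", "chrom", "pos", "effect_allele", "weight", "p",
                     "maf")],
      pThreshold = pThreshold, windowBp = windowBp, r2Max = r2Max,
      cancer = cancer)
}

#' Compute a polygenic risk score
#'
#' `score_i = sum_j dosage_ij * weight_j` over the model's variants. Missing
#' dosages are replaced by their expectation `2 * maf_j`.
#'
#' @param genotypes a [GenotypeDosage-class].
#' @param model a [PRSModel-class]; every model variant must be present in
#'   the matrix (an error lists any that are not).
#' @return Named numeric vector of per-participant scores (zero-length model
#'   gives all-zero scores).
#' @export
computePRS <- function(genotypes, model) {
  v <- prsVariants(model)
  if (!nrow(v))
    return(setNames(numeric(ncol(genotypes)), colnames(genotypes)))
  missing <- setdiff(v$id, rownames(genotypes))
  if (length(missing))
    stop("model variants absent from matrix: ",
         paste(missing, collapse = ", "))
  D <- dosages(genotypes)[v$id, , drop = FALSE]
  if (anyNA(D)) {
    fill <- matrix(2 * v$maf, nrow(D), ncol(D))
    D[is.na(D)] <- fill[is.na(D)]
  }
  setNames(as.vector(crossprod(D, v$weight)), colnames(genotypes))
}

#' Analytic power of the additive case-control association test
#'
#' Power of the two-sided Wald test of a per-allele log odds ratio under the
#' case-control allele model. The variance of the estimated log OR uses the
#' Woolf form `1/(2 n_cases pbar (1-pbar)) + 1/(2 n_controls p (1-p))`, with
#' the case-enriched allele frequency `pbar = OR p / (1 - p + OR p)` implied
#' by the odds ratio; power is `P(|Z| > z_{1-alpha/2})` for a normal shifted
#' by the non-centrality `|log OR| / se`.
#'
#' @param maf control/population minor allele frequency in (0, 0.5].
#' @param oddsRatio per-allele odds ratio (> 0); `oddsRatio = 1` returns
#'   exactly `alpha`.
#' @param alpha two-sided significance level in (0, 1).
#' @param nCases,nControls case and control counts.
#' @return Power in `[0,1]`. All arguments recycle, so vectors of scenarios
#'   can be evaluated at once.
#' @export
#' @examples
#' associationPower(0.1, 1.2, 1e-6, 14898, 88110)
associationPower <- function(maf, oddsRatio, alpha, nCases, nControls) {
  if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]")
  if (any(oddsRatio <= 0)) stop("oddsRatio must be > 0")
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must lie in (0, 1)")
  if (any(nCases < 1 | nControls < 1)) stop("counts must be >= 1")
  b <- log(oddsRatio)
  pbar <- oddsRatio * maf / (1 - maf + oddsRatio * maf)
  v <- 1 / (2 * nCases * pbar * (1 - pbar)) +
    1 / (2 * nControls * maf * (1 - maf))
  ncp <- abs(b) / sqrt(v)
  z <- qnorm(1 - alpha / 2)
  pnorm(ncp - z) + pnorm(-ncp - z)
}
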