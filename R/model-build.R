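#' Factor metadata table for a simulated cohort
#'
#' @param config a [CohortSimConfig-class].
#' @return data.frame with `name`, `kind`, `group`, `source` — the metadata
#'   [buildFactorDesign()] needs for a cohort produced by [generateCohort()].
#' @export
specTable <- function(config) {
  do.call(rbind, lapply(config@factorSpecs, function(sp)
    data.frame(name = sp@name, kind = sp@kind, group = sp@group,
               source = sp@params$source %||% "survey",
               stringsAsFactors = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Impute missing phenotype values
#'
#' Continuous and ordinal factors are imputed by predictive mean matching:
#' the target is regressed on the remaining factor columns over its observed
#' rows, and each missing row receives the observed value of a donor drawn
#' among the five nearest regression predictions (falling back to the column
#' mean when no regression is possible). Categorical factors receive the modal class.
#' Columns with at least 50 per cent missingness are excluded with a warning.
#' Non-missing cells are never changed; imputation flags are retained.
#'
#' @param cohort cohort data.frame.
#' @param factorInfo data.frame (`name`, `kind`) as from [specTable()].
#' @return List: `cohort` (complete), `dropped` (excluded column names),
#'   `flags` (named list of logical imputation indicators).
#' @export
imputePhenotypes <- function(cohort, factorInfo) {
  dropped <- character(0)
  flags <- list()
  keep <- factorInfo$name %in% colnames(cohort)
  factorInfo <- factorInfo[keep, , drop = FALSE]
  missFrac <- vapply(factorInfo$name,
                     function(nm) mean(is.na(cohort[[nm]])), numeric(1))
  if (any(missFrac >= 0.5)) {
    dropped <- factorInfo$name[missFrac >= 0.5]
    warning("excluding column(s) with >= 50% missingness: ",
            paste(dropped, collapse = ", "))
    cohort <- cohort[setdiff(colnames(cohort), dropped)]
    factorInfo <- factorInfo[!factorInfo$name %in% dropped, , drop = FALSE]
  }
  numericCols <- factorInfo$name[factorInfo$kind %in%
                                   c("binary", "ordinal", "continuous")]
  for (i in seq_len(nrow(factorInfo))) {
    nm <- factorInfo$name[i]
    x <- cohort[[nm]]
    miss <- is.na(x)
    flags[[nm]] <- miss
    if (!any(miss)) next
    if (factorInfo$kind[i] == "categorical") {
      tab <- table(x[!miss])
      cohort[[nm]][miss] <- names(tab)[which.max(tab)]
    } else {
      preds <- setdiff(numericCols, nm)
      Z <- as.matrix(cohort[preds])
      for (j in seq_len(ncol(Z))) {
        cm <- mean(Z[, j], na.rm = TRUE)
        Z[is.na(Z[, j]), j] <- cm
      }
      fitted <- tryCatch({
        fit <- lm.fit(cbind(1, Z[!miss, , drop = FALSE]), x[!miss])
        cf <- fit$coefficients
        cf[is.na(cf)] <- 0
        as.vector(cbind(1, Z) %*% cf)
      }, error = function(e) NULL)
      if (is.null(fitted)) {
        cohort[[nm]][miss] <- mean(x[!miss])
      } else {
        ## classical PMM: draw the donor among the k nearest predicted
        ## values, so weak predictors do not collapse onto a single donor
        obsIdx <- which(!miss)
        k <- min(5L, length(obsIdx))
        for (r in which(miss)) {
          nearest <- obsIdx[order(abs(fitted[obsIdx] - fitted[r]))[seq_len(k)]]
          cohort[[nm]][r] <- x[nearest[sample.int(k, 1)]]
        }
      }
    }
  }
  list(cohort = cohort, dropped = dropped, flags = flags)
}

#' Select polynomial degrees for continuous factors
#'
#' Sequential likelihood-ratio tests from degree 2 up to `dmax`: the next
#' degree is accepted while the added term improves the single-factor
#' logistic fit at `alpha`. With several outcomes the maximum selected degree
#' across outcomes is used, so all cancers share one design.
#'
#' @param x continuous factor values.
#' @param outcomes list (or single vector) of binary outcomes.
#' @param dmin,dmax degree bounds (default 2 and 4).
#' @param alpha LRT level (default 0.01).
#' @return Selected degree.
#' @export
selectPolyDegree <- function(x, outcomes, dmin = 2L, dmax = 4L,
                             alpha = 0.01) {
  if (!is.list(outcomes)) outcomes <- list(outcomes)
  best <- dmin
  for (y in outcomes) {
    d <- dmin
    devAt <- function(dd) {
      suppressWarnings(
        glm.fit(cbind(1, poly(x, dd)), y, family = binomial())$deviance)
    }
    devPrev <- devAt(d)
    while (d < dmax) {
      devNext <- devAt(d + 1L)
      p <- pchisq(devPrev - devNext, df = 1, lower.tail = FALSE)
      if (is.na(p) || p >= alpha) break
      d <- d + 1L
      devPrev <- devNext
    }
    best <- max(best, d)
  }
  best
}

## recipe entry constructors -------------------------------------------------

.expandFactor <- function(nm, kind, group, x, degree = 2L, refLevel = NULL,
                          polyCoefs = NULL) {
  if (kind %in% c("binary", "ordinal", "numeric")) {
    list(cols = setNames(list(as.numeric(x)), nm), kind = "numeric",
         group = group, degree = NA_integer_, refLevel = NA_character_,
         polyCoefs = NULL, levels = NULL)
  } else if (kind == "continuous") {
    if (is.null(polyCoefs)) {
      P <- poly(x, degree)
      polyCoefs <- attr(P, "coefs")
    } else {
      P <- poly(x, degree = degree, coefs = polyCoefs)
    }
    cols <- lapply(seq_len(degree), function(d) P[, d])
    names(cols) <- paste0(nm, ".poly", seq_len(degree))
    list(cols = cols, kind = "continuous", group = group, degree = degree,
         refLevel = NA_character_, polyCoefs = polyCoefs, levels = NULL)
  } else { # categorical
    x <- as.character(x)
    if (is.null(refLevel)) {
      tab <- sort(table(x), decreasing = TRUE)
      refLevel <- names(tab)[1]
      levels <- names(tab)
    } else {
      levels <- unique(c(refLevel, sort(unique(x))))
    }
    other <- setdiff(levels, refLevel)
    cols <- lapply(other, function(lv) as.numeric(x == lv))
    names(cols) <- paste0(nm, ".", other)
    list(cols = cols, kind = "categorical", group = group,
         degree = NA_integer_, refLevel = refLevel, polyCoefs = NULL,
         levels = levels)
  }
}

#' Build a model design from a cohort
#'
#' Expands risk factors into the numeric design matrix of the risk models:
#' binary/ordinal factors enter as single numeric columns, categorical
#' factors are reference-coded against their most frequent level, continuous
#' factors (and current age) are expanded on orthogonal polynomial bases
#' (degree 2-4) fitted on this sample. Optionally appends the demographic
#' block (age polynomial, sex, ancestry PCs as one "ancestry" factor), the
#' family-history score and a polygenic score. The returned object carries
#' the full expansion recipe so the identical design can be applied to new
#' participants with [applyDesign()].
#'
#' @param cohort cohort data.frame (complete; see [imputePhenotypes()]).
#' @param factorInfo data.frame (`name`, `kind`, `group`) for the risk-factor
#'   columns to include (e.g. from [specTable()]).
#' @param degrees named integer vector of polynomial degrees for continuous
#'   factors (default 2 each; see [selectPolyDegree()]).
#' @param agePoly degree of the current-age polynomial (default 3), used when
#'   `includeDemo` is `TRUE`.
#' @param includeDemo include age, sex and (if `pcs` given) ancestry.
#' @param includeFH include the family-history score column (requires the
#'   four indicator columns; see [familyHistoryScore()]).
#' @param pcs optional participants x k matrix of ancestry PCs.
#' @param prs optional named numeric polygenic score (one factor "PRS").
#' @return A [FactorDesign-class].
#' @export
buildFactorDesign <- function(cohort, factorInfo, degrees = NULL,
                              agePoly = 3L, includeDemo = TRUE,
                              includeFH = TRUE, pcs = NULL, prs = NULL) {
  recipe <- list()
  if (includeDemo) {
    recipe$current_age <- .expandFactor("current_age", "continuous",
                                        "Demographic", cohort$current_age,
                                        degree = agePoly)
    recipe$sex <- list(cols = list(sex.male = as.numeric(cohort$sex == "male")),
                       kind = "sex", group = "Demographic",
                       degree = NA_integer_, refLevel = "female",
                       polyCoefs = NULL, levels = c("female", "male"))
    if (!is.null(pcs)) {
      cols <- lapply(seq_len(ncol(pcs)), function(j) pcs[, j])
      names(cols) <- paste0("ancestry.PC", seq_len(ncol(pcs)))
      recipe$ancestry <- list(cols = cols, kind = "pcs", group = "Demographic",
                              degree = NA_integer_, refLevel = NA_character_,
                              polyCoefs = NULL, levels = NULL)
    }
  }
  if (includeFH) {
    fh <- familyHistoryScore(cohort$fh_father, cohort$fh_mother,
                             cohort$fh_sibling, cohort$fh_child)
    recipe$family_history <- list(cols = list(family_history = as.numeric(fh)),
                                  kind = "fh", group = "Family",
                                  degree = NA_integer_,
                                  refLevel = NA_character_, polyCoefs = NULL,
                                  levels = NULL)
  }
  for (i in seq_len(nrow(factorInfo))) {
    nm <- factorInfo$name[i]
    if (!nm %in% colnames(cohort)) next
    d <- if (!is.null(degrees) && nm %in% names(degrees))
      degrees[[nm]] else 2L
    recipe[[nm]] <- .expandFactor(nm, factorInfo$kind[i], factorInfo$group[i],
                                  cohort[[nm]], degree = d)
  }
  if (!is.null(prs)) {
    recipe$PRS <- list(cols = list(PRS = as.numeric(prs)), kind = "numeric",
                       group = "PRS", degree = NA_integer_,
                       refLevel = NA_character_, polyCoefs = NULL,
                       levels = NULL)
  }
  .assembleDesign(recipe, cohort$id)
}

.assembleDesign <- function(recipe, ids) {
  cols <- unlist(lapply(recipe, function(r) r$cols), recursive = FALSE)
  nms <- unlist(lapply(names(recipe), function(f)
    names(recipe[[f]]$cols)))
  X <- do.call(cbind, cols)
  colnames(X) <- nms
  map <- data.frame(
    column = nms,
    factor = rep(names(recipe),
                 vapply(recipe, function(r) length(r$cols), integer(1))),
    stringsAsFactors = FALSE)
  groups <- data.frame(
    factor = names(recipe),
    group = vapply(recipe, function(r) r$group, character(1)),
    stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  new("FactorDesign", X = X, map = map, groups = groups, recipe = recipe,
      ids = as.character(ids))
}

#' Apply a design recipe to new participants
#'
#' Re-expands a cohort with the recipe fitted on the training sample:
#' training polynomial bases, training reference levels. Required for scoring
#' validation participants without leaking their distribution into the
#' design.
#'
#' @param design a [FactorDesign-class] (or a [RiskModel-class], whose stored
#'   design is used).
#' @param cohort new cohort data.frame.
#' @param pcs,prs demographic PC matrix and polygenic score for the new
#'   participants, when the design contains those factors.
#' @return A [FactorDesign-class] for the new participants.
#' @export
applyDesign <- function(design, cohort, pcs = NULL, prs = NULL) {
  if (is(design, "RiskModel")) design <- design@design
  recipe <- design@recipe
  out <- list()
  for (f in names(recipe)) {
    r <- recipe[[f]]
    if (r$kind == "pcs") {
      if (is.null(pcs)) stop("design contains ancestry PCs; supply `pcs`")
      cols <- lapply(seq_along(r$cols), function(j) pcs[, j])
      names(cols) <- names(r$cols)
      r$cols <- cols
    } else if (f == "PRS") {
      if (is.null(prs)) stop("design contains a PRS; supply `prs`")
      r$cols <- list(PRS = as.numeric(prs))
    } else if (r$kind == "fh") {
      fh <- familyHistoryScore(cohort$fh_father, cohort$fh_mother,
                               cohort$fh_sibling, cohort$fh_child)
      r$cols <- list(family_history = as.numeric(fh))
    } else if (r$kind == "sex") {
      r$cols <- list(sex.male = as.numeric(cohort$sex == "male"))
    } else if (r$kind == "continuous") {
      P <- poly(cohort[[f]], degree = r$degree, coefs = r$polyCoefs)
      cols <- lapply(seq_len(r$degree), function(d) P[, d])
      names(cols) <- names(r$cols)
      r$cols <- cols
    } else if (r$kind == "categorical") {
      x <- as.character(cohort[[f]])
      other <- setdiff(r$levels, r$refLevel)
      cols <- lapply(other, function(lv) as.numeric(x == lv))
      names(cols) <- paste0(f, ".", other)
      r$cols <- cols
    } else {
      r$cols <- setNames(list(as.numeric(cohort[[f]])), f)
    }
    out[[f]] <- r
  }
  .assembleDesign(out, cohort$id)
}

#' Fit a per-cancer logistic risk model
#'
#' Maximum-likelihood binomial GLM with logit link of case status on the
#' design columns. Wald statistics are reported per column; the residual and
#' null deviances give the model's deviance explained. Rank-deficient
#' designs abort with the offending columns named; non-convergence aborts
#' with iteration diagnostics.
#'
#' @param design a [FactorDesign-class].
#' @param outcome binary 0/1 case-status vector.
#' @param cancer outcome label stored in the model.
#' @return A [RiskModel-class].
#' @export
fitRiskGLM <- function(design, outcome, cancer = "") {
  y <- as.numeric(outcome)
  if (length(unique(y)) < 2) stop("outcome must contain both classes")
  X <- designMatrix(design)
  M <- cbind(`(Intercept)` = 1, X)
  q <- qr(M)
  if (q$rank < ncol(M)) {
    bad <- colnames(M)[q$pivot[(q$rank + 1):ncol(M)]]
    stop("design is rank deficient; aliased column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- suppressWarnings(
    glm.fit(M, y, family = binomial(), control = list(maxit = 100)))
  if (!fit$converged)
    stop("GLM did not converge after ", fit$iter, " IRLS iterations")
  V <- solve(crossprod(M * sqrt(fit$weights)))
  se <- sqrt(diag(V))
  beta <- fit$coefficients
  zv <- beta / se
  map <- designMap(design)
  groups <- designGroups(design)
  coefs <- data.frame(
    column = colnames(X),
    factor = map$factor,
    group = groups$group[match(map$factor, groups$factor)],
    beta = beta[-1], se = se[-1], z = zv[-1],
    p = 2 * pnorm(-abs(zv[-1])),
    stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  slim <- design
  slim@X <- matrix(numeric(0), 0, ncol(X),
                   dimnames = list(NULL, colnames(X)))
  new("RiskModel", cancer = cancer, coefficients = coefs,
      intercept = unname(beta[1]), deviance = fit$deviance,
      nullDeviance = fit$null.deviance, design = slim,
      n = length(y))
}

#' SelectionTrace: record of a factor-selection stage
#'
#' @slot perCancer named list of data.frames (`factor`, `min_p`, `kept`).
#' @slot kept union of kept factors over the cancers.
#' @slot alpha p-value rule of the stage.
#' @export
setClass("SelectionTrace", representation(
  perCancer = "list", kept = "character", alpha = "numeric"))

setMethod("show", "SelectionTrace", function(object) {
  cat(sprintf("SelectionTrace: %d factor(s) kept at alpha = %g over %s\n",
              length(object@kept), object@alpha,
              paste(names(object@perCancer), collapse = ", ")))
})

#' Stage-1 factor selection
#'
#' Per cancer, fits the all-factor GLM (with the demographic covariates and
#' family history always retained) and drops survey factors whose every
#' design column has Wald p at or above `alpha`. A factor is kept overall if
#' it passes in at least one cancer (union rule).
#'
#' @param design a [FactorDesign-class] containing all candidate factors.
#' @param outcomes named list of binary case-status vectors (one per cancer).
#' @param alpha per-column Wald level (default 0.05).
#' @param alwaysKeep factors never dropped (default the demographic block,
#'   ancestry and family history).
#' @return A [SelectionTrace-class].
#' @export
stage1Select <- function(design, outcomes, alpha = 0.05,
                         alwaysKeep = c("current_age", "sex", "ancestry",
                                        "family_history")) {
  perCancer <- list()
  for (cc in names(outcomes)) {
    model <- fitRiskGLM(design, outcomes[[cc]], cancer = cc)
    co <- riskCoefficients(model)
    minp <- aggregate(p ~ factor, data = co, FUN = min)
    minp$kept <- minp$p < alpha | minp$factor %in% alwaysKeep
    names(minp)[names(minp) == "p"] <- "min_p"
    perCancer[[cc]] <- minp
  }
  keptEach <- lapply(perCancer, function(d) d$factor[d$kept])
  kept <- sort(unique(unlist(keptEach)))
  new("SelectionTrace", perCancer = perCancer, kept = kept, alpha = alpha)
}

#' Subset a design to a set of factors
#'
#' @param design a [FactorDesign-class].
#' @param factors factor names to keep.
#' @return A [FactorDesign-class] restricted to those factors.
#' @export
subsetDesign <- function(design, factors) {
  unknown <- setdiff(factors, names(design@recipe))
  if (length(unknown))
    stop("unknown factor(s): ", paste(unknown, collapse = ", "))
  .assembleDesign(design@recipe[intersect(names(design@recipe), factors)],
                  design@ids)
}

#' Scan additional phenotypes against a base model
#'
#' Emulates screening a wide phenotype database: each extra phenotype is
#' added individually to the base design and the augmented GLM refitted per
#' cancer; candidates are the phenotypes reaching `p < alpha` in at least one
#' cancer. A conservative threshold (default 1e-8) keeps the expected number
#' of false selections near zero even for several hundred phenotypes.
#' Phenotypes aliased with the base design are skipped with a note.
#'
#' @param design base [FactorDesign-class].
#' @param outcomes named list of binary case-status vectors.
#' @param extra data.frame of candidate phenotypes (numeric or categorical),
#'   rows aligned with the design. Each must be under 50 per cent missing;
#'   missing values are mean/mode-filled for the scan.
#' @param alpha selection threshold (default 1e-8).
#' @return data.frame: `phenotype`, one p column per cancer, `note`,
#'   `candidate`.
#' @export
scanAdditional <- function(design, outcomes, extra, alpha = 1e-8) {
  X <- designMatrix(design)
  M <- cbind(1, X)
  out <- data.frame(phenotype = colnames(extra), stringsAsFactors = FALSE)
  for (cc in names(outcomes)) out[[paste0("p_", cc)]] <- NA_real_
  out$note <- ""
  for (j in seq_len(ncol(extra))) {
    x <- extra[[j]]
    if (mean(is.na(x)) >= 0.5) { out$note[j] <- "too_missing"; next }
    if (is.numeric(x)) {
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      Z <- matrix(x, ncol = 1)
    } else {
      x <- as.character(x)
      tab <- sort(table(x), decreasing = TRUE)
      x[is.na(x)] <- names(tab)[1]
      lev <- names(tab)
      Z <- sapply(lev[-1], function(lv) as.numeric(x == lv))
      Z <- matrix(Z, nrow = length(x))
    }
    Ma <- cbind(M, Z)
    if (qr(Ma)$rank < ncol(Ma)) { out$note[j] <- "aliased"; next }
    for (cc in names(outcomes)) {
      y <- as.numeric(outcomes[[cc]])
      fit <- suppressWarnings(
        glm.fit(Ma, y, family = binomial(), control = list(maxit = 100)))
      V <- tryCatch(solve(crossprod(Ma * sqrt(fit$weights))),
                    error = function(e) NULL)
      if (is.null(V) || !fit$converged) next
      idx <- (ncol(M) + 1):ncol(Ma)
      zv <- fit$coefficients[idx] / sqrt(diag(V)[idx])
      out[[paste0("p_", cc)]][j] <- min(2 * pnorm(-abs(zv)))
    }
  }
  pcols <- paste0("p_", names(outcomes))
  out$candidate <- out$note == "" &
    apply(out[pcols], 1, function(p) any(!is.na(p) & p < alpha))
  out
}

## homogeneity of a cluster of mixed variables: squared correlation
## (quantitative) / correlation ratio (qualitative) with the cluster's first
## principal component
.clusterHomogeneity <- function(vars) {
  Z <- do.call(cbind, lapply(vars, function(x) {
    if (is.numeric(x)) {
      scale(x)
    } else {
      x <- as.character(x)
      lev <- sort(unique(x))
      G <- sapply(lev, function(lv) as.numeric(x == lv))
      p <- colMeans(G)
      sweep(scale(G, scale = FALSE), 2, sqrt(p), "/")
    }
  }))
  u <- svd(Z, nu = 1, nv = 0)$u[, 1]
  sum(vapply(vars, function(x) {
    if (is.numeric(x)) {
      cor(x, u)^2
    } else {
      ## correlation ratio eta^2 = between-class variance of u
      m <- tapply(u, as.character(x), mean)
      n <- tapply(u, as.character(x), length)
      sum(n * (m - mean(u))^2) / sum((u - mean(u))^2)
    }
  }, numeric(1)))
}

#' Cluster candidate variables by homogeneity loss
#'
#' Agglomerative clustering of mixed quantitative/qualitative variables. A
#' cluster's homogeneity is the sum of squared correlations (quantitative)
#' and correlation ratios (qualitative) between its members and its first
#' principal component; at each step the merge with the smallest decrease in
#' total homogeneity is performed, until `nClusters` remain. Each cluster's
#' representative is its member with the best (lowest) scan p-value, ties
#' broken by lowest missingness.
#'
#' @param data data.frame of candidate variables (rows with any `NA` are
#'   dropped for the clustering itself).
#' @param nClusters number of clusters to return.
#' @param pvalues,missingness optional named vectors guiding the
#'   representative choice.
#' @return List: `assignment` (named cluster index), `representatives`
#'   (one column name per cluster), `homogeneityLoss` (per merge).
#' @export
clusterVariables <- function(data, nClusters, pvalues = NULL,
                             missingness = NULL) {
  nms <- colnames(data)
  if (length(nms) < 2) {
    return(list(assignment = setNames(rep(1L, length(nms)), nms),
                representatives = nms, homogeneityLoss = numeric(0)))
  }
  if (nClusters < 1 || nClusters > length(nms))
    stop("nClusters must lie in [1, #variables]")
  cc <- complete.cases(data)
  dat <- data[cc, , drop = FALSE]
  clusters <- as.list(nms)
  H <- vapply(nms, function(nm) .clusterHomogeneity(dat[nm]), numeric(1))
  losses <- numeric(0)
  while (length(clusters) > nClusters) {
    best <- NULL; bestLoss <- Inf; bestH <- NA_real_
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      merged <- c(clusters[[i]], clusters[[j]])
      Hm <- .clusterHomogeneity(dat[merged])
      loss <- H[[i]] + H[[j]] - Hm
      if (loss < bestLoss - 1e-12) {
        bestLoss <- loss; best <- c(i, j); bestH <- Hm
      }
    }
    i <- best[1]; j <- best[2]
    clusters[[j]] <- c(clusters[[j]], clusters[[i]])
    H[[j]] <- bestH
    clusters[[i]] <- NULL
    H <- H[-i]
    losses <- c(losses, bestLoss)
  }
  assignment <- integer(length(nms)); names(assignment) <- nms
  for (k in seq_along(clusters)) assignment[clusters[[k]]] <- k
  reps <- vapply(clusters, function(members) {
    pv <- if (is.null(pvalues)) rep(0, length(members)) else
      pvalues[members]
    ms <- if (is.null(missingness)) rep(0, length(members)) else
      missingness[members]
    ord <- order(rank(pv) + rank(ms))
    members[ord[1]]
  }, character(1))
  list(assignment = assignment, representatives = unname(reps),
       homogeneityLoss = losses)
}

#' Per-factor deviance decomposition
#'
#' Ranks factors by the deviance each explains alone, then recomputes
#' deviance cumulatively by refitting with factors added in that order, so
#' each factor's marginal contribution is evaluated in the context of the
#' stronger factors above it.
#'
#' @param design a [FactorDesign-class].
#' @param outcome binary case-status vector.
#' @return data.frame: `factor`, `single` (deviance explained alone),
#'   `cumulative`, `marginal` — ordered by decreasing single-factor deviance.
#' @export
devianceDecomposition <- function(design, outcome) {
  y <- as.numeric(outcome)
  facs <- designGroups(design)$factor
  single <- vapply(facs, function(f) {
    d <- subsetDesign(design, f)
    fit <- suppressWarnings(glm.fit(cbind(1, designMatrix(d)), y,
                                    family = binomial()))
    1 - fit$deviance / fit$null.deviance
  }, numeric(1))
  ord <- order(single, decreasing = TRUE)
  facs <- facs[ord]; single <- single[ord]
  cumulative <- numeric(length(facs))
  for (k in seq_along(facs)) {
    d <- subsetDesign(design, facs[seq_len(k)])
    fit <- suppressWarnings(glm.fit(cbind(1, designMatrix(d)), y,
                                    family = binomial()))
    cumulative[k] <- 1 - fit$deviance / fit$null.deviance
  }
  data.frame(factor = facs, single = single, cumulative = cumulative,
             marginal = c(cumulative[1], diff(cumulative)),
             stringsAsFactors = FALSE)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing design column `j` on all other
#' columns. Exactly collinear columns are reported as infinite, with the
#' most correlated partner identified in the `"aliased"` attribute.
#'
#' @param design a [FactorDesign-class] or numeric matrix (>= 2 columns).
#' @return Named vector of VIFs, possibly with an `"aliased"` attribute
#'   listing `column` / `partner` pairs.
#' @export
vif <- function(design) {
  X <- if (is(design, "FactorDesign")) designMatrix(design) else
    as.matrix(design)
  if (ncol(X) < 2) stop("need at least 2 columns")
  out <- setNames(numeric(ncol(X)), colnames(X))
  aliased <- NULL
  for (j in seq_len(ncol(X))) {
    yj <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    fit <- lm.fit(Z, yj)
    rss <- sum(fit$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    r2 <- 1 - rss / tss
    if (r2 > 1 - 1e-10) {
      out[j] <- Inf
      cors <- abs(suppressWarnings(cor(yj, X[, -j, drop = FALSE])))
      partner <- colnames(X)[-j][which.max(cors)]
      aliased <- rbind(aliased, data.frame(column = colnames(X)[j],
                                           partner = partner))
    } else out[j] <- 1 / (1 - r2)
  }
  if (!is.null(aliased)) attr(out, "aliased") <- aliased
  out
}

#' Pairwise interaction tests
#'
#' For each factor pair, compares the main-effects model with the model
#' augmented by all products of the two factors' design columns, by
#' likelihood-ratio test (degrees of freedom = rank gain, so aliased product
#' columns are not counted). Pairs involving the age factor test the
#' products with the whole age polynomial block.
#'
#' @param design a [FactorDesign-class].
#' @param outcome binary case-status vector.
#' @param pairs data.frame or 2-column matrix of factor name pairs.
#' @return data.frame: `factor1`, `factor2`, `df`, `devianceGain`, `p`.
#' @export
testInteractions <- function(design, outcome, pairs) {
  y <- as.numeric(outcome)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  colnames(pairs) <- c("factor1", "factor2")
  X <- designMatrix(design)
  map <- designMap(design)
  M0 <- cbind(1, X)
  fit0 <- suppressWarnings(glm.fit(M0, y, family = binomial()))
  rank0 <- qr(M0)$rank
  out <- pairs
  out$df <- NA_integer_; out$devianceGain <- NA_real_; out$p <- NA_real_
  for (r in seq_len(nrow(pairs))) {
    f1 <- pairs$factor1[r]; f2 <- pairs$factor2[r]
    if (identical(f1, f2)) stop("cannot test a factor against itself: ", f1)
    unknown <- setdiff(c(f1, f2), map$factor)
    if (length(unknown))
      stop("unknown factor(s): ", paste(unknown, collapse = ", "))
    B1 <- X[, map$column[map$factor == f1], drop = FALSE]
    B2 <- X[, map$column[map$factor == f2], drop = FALSE]
    prod <- do.call(cbind, lapply(seq_len(ncol(B1)), function(i)
      B1[, i] * B2))
    M1 <- cbind(M0, prod)
    rank1 <- qr(M1)$rank
    df <- rank1 - rank0
    if (df == 0) next
    fit1 <- suppressWarnings(glm.fit(M1, y, family = binomial(),
                                     control = list(maxit = 100)))
    gain <- fit0$deviance - fit1$deviance
    out$df[r] <- df
    out$devianceGain[r] <- gain
    out$p[r] <- pchisq(gain, df = df, lower.tail = FALSE)
  }
  out
}
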