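## Delimited-text interfaces. All artifacts are tab-delimited with a header;
## the missing-value marker in files is the empty cell.

.writeTSV <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
}

.readTSV <- function(path) {
  read.delim(path, sep = "\t", na.strings = "", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read / write a cohort table
#'
#' Tab-delimited with a header; empty cells are missing values. `id`, `sex`
#' and `current_age` are mandatory; unknown columns are preserved.
#' Malformed numeric cells in `current_age` raise an error naming the row.
#'
#' @param path file path.
#' @return `readCohort`: the cohort data.frame.
#' @export
readCohort <- function(path) {
  x <- .readTSV(path)
  need <- c("id", "sex", "current_age")
  miss <- setdiff(need, colnames(x))
  if (length(miss))
    stop("cohort file missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (!is.numeric(x$current_age)) {
    bad <- which(is.na(suppressWarnings(as.numeric(x$current_age))) &
                   !is.na(x$current_age))
    stop("malformed numeric cell in current_age at data row(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  x$id <- as.character(x$id)
  x
}

#' @rdname readCohort
#' @param cohort cohort data.frame.
#' @export
writeCohort <- function(cohort, path) .writeTSV(cohort, path)

#' Read / write genotype dosages
#'
#' The dosage file is participants x variants (first column `id`), the
#' sidecar lists `id`, `chrom`, `pos`, `effect_allele`, `maf` per variant.
#'
#' @param dosagePath,variantPath file paths.
#' @return `readGenotypes`: a [GenotypeDosage-class].
#' @export
readGenotypes <- function(dosagePath, variantPath) {
  d <- .readTSV(dosagePath)
  v <- .readTSV(variantPath)
  need <- c("id", "chrom", "pos", "effect_allele", "maf")
  miss <- setdiff(need, colnames(v))
  if (length(miss))
    stop("variant sidecar missing column(s): ", paste(miss, collapse = ", "))
  ids <- as.character(d$id)
  M <- t(as.matrix(d[setdiff(colnames(d), "id")]))
  if (!identical(rownames(M), as.character(v$id)))
    M <- M[match(v$id, rownames(M)), , drop = FALSE]
  g <- GenotypeDosage(M, v)
  colnames(g) <- ids
  g
}

#' @rdname readGenotypes
#' @param genotypes a [GenotypeDosage-class].
#' @export
writeGenotypes <- function(genotypes, dosagePath, variantPath) {
  D <- t(dosages(genotypes))
  out <- data.frame(id = rownames(D), D, check.names = FALSE)
  .writeTSV(out, dosagePath)
  .writeTSV(variantInfo(genotypes), variantPath)
}

#' Read / write a survival table
#'
#' Two-column delimited text: `age`, `survival`.
#'
#' @param path file path.
#' @return `readSurvivalTable`: a [SurvivalTable-class].
#' @export
readSurvivalTable <- function(path) {
  x <- .readTSV(path)
  if (!all(c("age", "survival") %in% colnames(x)))
    stop("survival table needs columns age, survival")
  survivalTable(x$age, x$survival)
}

#' @rdname readSurvivalTable
#' @param S a [SurvivalTable-class].
#' @export
writeSurvivalTable <- function(S, path) {
  .writeTSV(data.frame(age = S@age, survival = S@survival), path)
}

#' Write an association table or PRS model
#'
#' @param assoc association table from [runGWAS()].
#' @param path file path.
#' @export
writeAssociationTable <- function(assoc, path) .writeTSV(assoc, path)

#' @rdname writeAssociationTable
#' @param model a [PRSModel-class]; its clumping parameters travel in `#`
#'   header comments.
#' @export
writePRSModel <- function(model, path) {
  con <- file(path, "w")
  writeLines(sprintf("# pThreshold=%.17g windowBp=%.17g r2Max=%.17g cancer=%s",
                     model@pThreshold, model@windowBp, model@r2Max,
                     model@cancer), con)
  close(con)
  suppressWarnings(
    write.table(prsVariants(model), path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "", append = TRUE))
}

#' @rdname writeAssociationTable
#' @return `readPRSModel`: a [PRSModel-class].
#' @export
readPRSModel <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-zA-Z0-9]+=[^ ]+", hdr))[[1]]
  vals <- setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
  v <- read.delim(path, sep = "\t", skip = 1, na.strings = "",
                  stringsAsFactors = FALSE)
  new("PRSModel", variants = v,
      pThreshold = as.numeric(vals[["pThreshold"]]),
      windowBp = as.numeric(vals[["windowBp"]]),
      r2Max = as.numeric(vals[["r2Max"]]),
      cancer = if (is.na(vals["cancer"])) "" else unname(vals["cancer"]))
}

#' Write a risk model's coefficient table
#'
#' Tab-delimited: `column`, `factor`, `group`, `beta`, `se`, `z`, `p`, with
#' the intercept as its own row.
#'
#' @param model a [RiskModel-class].
#' @param path file path.
#' @export
writeRiskModel <- function(model, path) {
  co <- riskCoefficients(model)
  co <- rbind(data.frame(column = "(Intercept)", factor = "(Intercept)",
                         group = "", beta = model@intercept, se = NA_real_,
                         z = NA_real_, p = NA_real_), co)
  .writeTSV(co, path)
}

#' Write a score set
#'
#' Long format: `participant`, `cancer`, `score`, `value`, `z_value`.
#'
#' @param x a [ScoreSet-class] of raw scores.
#' @param path file path.
#' @param standardized optional standardized companion
#'   ([standardizeScores()]) supplying `z_value`.
#' @export
writeScoreSet <- function(x, path, standardized = NULL) {
  long <- as.data.frame(x)
  names(long)[names(long) == "value"] <- "value"
  if (!is.null(standardized)) {
    zl <- as.data.frame(standardized)
    long$z_value <- zl$value
  } else long$z_value <- NA_real_
  .writeTSV(long, path)
}
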