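#' Sibling fixed-effects estimator
#'
#' Within-family (family-demeaned) least squares for person-level
#' predictors, the robustness check that controls for everything siblings
#' share — including the parental genomes and family SES. Only families
#' with at least two genotyped children contribute; monozygotic pairs are
#' excluded by default because they carry no within-pair genotype
#' variance, and a family whose siblings have identical scores on every
#' predictor contributes zero information. Standard errors are
#' cluster-robust at the family level.
#'
#' The response is collapsed to the person level (mean over waves) before
#' demeaning, so wave-level noise enters only through the person average.
#'
#' @param data Long person-wave (or person-level) data frame.
#' @param predictors Person-level predictor columns (typically the
#'   standardized PGS columns).
#' @param response Response column name.
#' @param covariates Additional person-level covariates that vary within
#'   family (e.g. age, sex).
#' @param exclude_mz Drop monozygotic twin pairs (default `TRUE`;
#'   requires a `sibship_type` column).
#' @return Object of class `gn_sibfe` with `coefficients`, `se`
#'   (cluster-robust), `n_families`, `n_persons`.
#' @export
sibling_fe <- function(data, predictors, response = "pvt_score",
                       covariates = character(), exclude_mz = TRUE) {
  cols <- c("person_id", "family_id", response, predictors, covariates)
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("columns absent from data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (exclude_mz && "sibship_type" %in% names(data))
    data <- data[data$sibship_type != "mz", , drop = FALSE]

  # person-level collapse
  y <- tapply(data[[response]], data$person_id,
              function(v) mean(v, na.rm = TRUE))
  first <- data[!duplicated(data$person_id), , drop = FALSE]
  first <- first[match(names(y), first$person_id), , drop = FALSE]
  d <- data.frame(person_id = names(y), family_id = first$family_id,
                  y = as.numeric(y),
                  first[, c(predictors, covariates), drop = FALSE],
                  stringsAsFactors = FALSE, row.names = NULL)
  d <- d[complete.cases(d), , drop = FALSE]

  fam_n <- table(d$family_id)
  d <- d[d$family_id %in% names(fam_n)[fam_n >= 2], , drop = FALSE]
  if (nrow(d) == 0) stop("no families with >= 2 siblings", call. = FALSE)

  demean <- function(v) v - ave(v, d$family_id)
  yd <- demean(d$y)
  X <- sapply(c(predictors, covariates), function(v) demean(d[[v]]))
  X <- matrix(X, nrow = nrow(d),
              dimnames = list(NULL, c(predictors, covariates)))
  if (all(apply(X[, predictors, drop = FALSE], 2, var) == 0))
    stop("no within-family variance in any predictor", call. = FALSE)

  fit <- lm(yd ~ 0 + X)
  names(fit$coefficients) <- colnames(X)
  vc <- sandwich::vcovCL(fit, cluster = d$family_id)
  structure(list(coefficients = coef(fit), se = sqrt(diag(vc)),
                 vcov = vc, n_families = length(unique(d$family_id)),
                 n_persons = nrow(d), fit = fit),
            class = "gn_sibfe")
}

#' @export
print.gn_sibfe <- function(x, digits = 3, ...) {
  cat("Sibling fixed-effects model (", x$n_persons, " siblings in ",
      x$n_families, " families)\n", sep = "")
  printCoefmat(coef_matrix(x$coefficients, x$se), digits = digits,
               P.values = TRUE, has.Pvalue = TRUE)
  cat("(cluster-robust SEs by family)\n")
  invisible(x)
}
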