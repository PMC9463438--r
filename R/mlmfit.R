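#' Fit a nested random-intercept model of a two-wave phenotype
#'
#' The workhorse estimator: a Gaussian linear mixed model with a chain of
#' nested random intercepts over person-wave observations. With
#' `random = c("family_id", "person_id")` this is the three-level model
#' \deqn{Y_{tij} = \beta_0 + x_{ij}'B + \mu_j + \nu_{ij} + e_{tij}}
#' with variance components at the family (`sigma^2_u`), person
#' (`sigma^2_v`) and wave (`sigma^2_e`, the residual) levels. With a
#' single clustering column the residual plays the person-level role
#' (the conditional wave-3 specification). Estimation is by REML
#' (default) or ML via [lme4::lmer()]; ML is required whenever fits feed
#' a likelihood-ratio test. A companion single-level OLS fit with the
#' same fixed-effect design supplies the reported `ols_r2`.
#'
#' Rows with missing values in any model variable are dropped (SES
#' predictors should be missing-category coded first, see
#' [encode_categoricals()], so that this only removes rows lacking the
#' response). A rank-deficient fixed-effect design is an error naming
#' the collinear columns. Non-convergence triggers up to `max_restarts`
#' refits from jittered starting values before failing with the last
#' optimizer message.
#'
#' @param fixed Fixed-effects formula, e.g.
#'   `pvt_score ~ pgs_edu_z + mother_edu_hs_some_college + ... + age`.
#' @param data Data frame with the model variables and clustering
#'   columns.
#' @param random Character vector of nested clustering columns, outermost
#'   first.
#' @param method `"REML"` or `"ML"`.
#' @param max_restarts Jittered restarts on convergence failure.
#' @return An object of class `gn_lmm` with `coefficients`, `se`,
#'   `varcomp` (named variance components, variance scale), `m2ll`
#'   (-2 log-likelihood), `npar`, `n_obs`, `n_persons`, `n_families`,
#'   `ols_r2`, and the underlying `lmer` fit. Methods: `print`,
#'   `summary`, `coef`, `vcov`, `predict`, `residuals`, `logLik`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(seed = 3, n_families = 120,
#'                                   n_snps = 50, missing_rate = 0))
#' d <- merge(sim$cohort, sim$truth$persons[, c("person_id", "z_u")])
#' fit_lmm(pvt_score ~ z_u + age, d)
fit_lmm <- function(fixed, data, random = c("family_id", "person_id"),
                    method = c("REML", "ML"), max_restarts = 3) {
  method <- match.arg(method)
  stopifnot(inherits(fixed, "formula"), length(random) >= 1)
  vars <- unique(c(all.vars(fixed), random))
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("variables absent from data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- data[complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
  if (length(unique(df[[random[1]]])) < 2)
    stop("need at least 2 clusters at the top level", call. = FALSE)

  mm <- model.matrix(fixed, df)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  fstr <- paste(deparse(fixed, width.cutoff = 500), collapse = " ")
  full <- as.formula(paste(fstr,
                           paste(sprintf("(1 | %s)", random),
                                 collapse = " + "), sep = " + "))
  fit <- NULL
  msgs <- character()
  for (attempt in 0:max_restarts) {
    start <- if (attempt == 0) NULL else
      list(theta = runif(length(random), 0.05, 1.5))
    res <- tryCatch(
      withCallingHandlers(
        lme4::lmer(full, data = df, REML = (method == "REML"),
                   start = start,
                   control = lme4::lmerControl(calc.derivs = FALSE)),
        warning = function(w) {
          msgs <<- c(msgs, conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) {
        msgs <<- c(msgs, conditionMessage(e)); NULL
      })
    converged <- !is.null(res) &&
      !any(grepl("failed to converge", msgs[length(msgs)]))
    if (!is.null(res)) fit <- res
    if (converged) break
    msgs <- c(msgs, sprintf("restart %d", attempt + 1))
  }
  if (is.null(fit))
    stop("mixed-model fit failed after ", max_restarts, " restarts: ",
         paste(utils::tail(msgs, 2), collapse = "; "), call. = FALSE)

  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- setNames(vc$vcov[match(random, vc$grp)], random)
  resid_var <- vc$vcov[vc$grp == "Residual"]
  labels <- if (length(random) == 2) c("family", "person", "wave")
    else if (length(random) == 1) c("family", "person")
    else c(random, "residual")
  varcomp <- setNames(c(comp, resid_var), labels)

  ll <- logLik(fit)
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  olsfit <- lm(fixed, data = df)

  out <- list(coefficients = beta, se = se, varcomp = varcomp,
              m2ll = as.numeric(-2 * ll), npar = attr(ll, "df"),
              n_obs = nrow(df),
              n_persons = if ("person_id" %in% names(df))
                length(unique(df$person_id)) else NA_integer_,
              n_families = length(unique(df[[random[1]]])),
              ols_r2 = summary(olsfit)$r.squared,
              method = method, fixed = fixed, random = random,
              converged = is.null(fit@optinfo$conv$lme4$messages) ||
                length(fit@optinfo$conv$lme4$messages) == 0,
              fit = fit)
  class(out) <- "gn_lmm"
  out
}

coef_table <- function(est, se) {
  p <- wald_p(est, se)
  data.frame(estimate = unname(est), se = unname(se),
             z = unname(est / se), p = unname(p),
             stars = signif_stars(unname(p)),
             row.names = names(est) %||% seq_along(est))
}

coef_matrix <- function(est, se) {
  tab <- coef_table(est, se)
  m <- cbind(Estimate = tab$estimate, `Std.Error` = tab$se, z = tab$z,
             `Pr(>|z|)` = tab$p)
  rownames(m) <- rownames(tab)
  m
}

#' @export
print.gn_lmm <- function(x, digits = 3, ...) {
  cat("Nested random-intercept model (", x$method, ")\n", sep = "")
  cat("  ", paste(deparse(x$fixed), collapse = ""), "\n", sep = "")
  printCoefmat(coef_matrix(x$coefficients, x$se), digits = digits,
               P.values = TRUE, has.Pvalue = TRUE)
  cat("Variance components (variance scale):\n")
  print(round(x$varcomp, digits))
  cat(sprintf("-2 log-likelihood: %.1f  (parameters: %d)\n",
              x$m2ll, x$npar))
  cat(sprintf("OLS R-squared (companion single-level fit): %.4f\n",
              x$ols_r2))
  cat(sprintf("n: %d observations, %s persons, %d top-level clusters\n",
              x$n_obs, ifelse(is.na(x$n_persons), "?", x$n_persons),
              x$n_families))
  invisible(x)
}

#' @export
summary.gn_lmm <- function(object, ...) {
  out <- object
  out$coef_table <- coef_table(object$coefficients, object$se)
  class(out) <- c("summary.gn_lmm", "gn_lmm")
  out
}

#' @export
print.summary.gn_lmm <- function(x, ...) {
  print.gn_lmm(x, ...)
  invisible(x)
}

#' @export
coef.gn_lmm <- function(object, ...) object$coefficients

#' @export
vcov.gn_lmm <- function(object, ...) as.matrix(vcov(object$fit))

#' @export
predict.gn_lmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) predict(object$fit, ...)
  else predict(object$fit, newdata = newdata, allow.new.levels = TRUE, ...)
}

#' @export
residuals.gn_lmm <- function(object, ...) residuals(object$fit, ...)

#' @export
logLik.gn_lmm <- function(object, ...) {
  structure(-object$m2ll / 2, df = object$npar, class = "logLik")
}

#' Likelihood-ratio test between nested fits
#'
#' `statistic = (-2LL_reduced) - (-2LL_full)`, `df` the parameter-count
#' difference, p-value from the chi-square reference. Both fits must be
#' ML on the same data with the reduced design nested in the full one; a
#' negative statistic signals a nesting violation and is an error, as are
#' REML fits with differing fixed effects.
#'
#' @param reduced,full Either `gn_lmm` objects or bare `c(m2ll, n_par)`
#'   pairs (for worked examples from published fit summaries).
#' @return Object of class `gn_lrt`: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' lrt(c(67064, 22), c(67058, 24))
lrt <- function(reduced, full) {
  info <- function(x) {
    if (inherits(x, "gn_lmm"))
      list(m2ll = x$m2ll, npar = x$npar, method = x$method,
           fixed = paste(deparse(x$fixed), collapse = ""))
    else if (is.numeric(x) && length(x) == 2)
      list(m2ll = x[1], npar = x[2], method = NA, fixed = NA)
    else stop("inputs must be gn_lmm fits or c(m2ll, n_par) pairs",
              call. = FALSE)
  }
  r <- info(reduced); f <- info(full)
  if (identical(r$method, "REML") || identical(f$method, "REML")) {
    if (!identical(r$fixed, f$fixed))
      stop("REML fits with differing fixed effects cannot be compared ",
           "by LRT; refit with method = 'ML'", call. = FALSE)
  }
  df <- f$npar - r$npar
  stat <- r$m2ll - f$m2ll
  if (df < 0 || stat < -1e-6)
    stop("nesting violation: the full model must extend the reduced ",
         "model (statistic = ", format(stat), ", df = ", df, ")",
         call. = FALSE)
  stat <- max(stat, 0)
  p <- if (df == 0) as.numeric(stat <= 0) * 1 else
    pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p), class = "gn_lrt")
}

#' @export
print.gn_lrt <- function(x, ...) {
  cat(sprintf("LRT: chi-square = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Single-level OLS R-squared for a fixed-effect design
#'
#' The coefficient of determination of an ordinary least-squares fit over
#' all person-wave rows, the companion summary reported next to each
#' multilevel fit (a multilevel model has no unique R-squared; the
#' single-level value is the convention adopted here and is isolated so
#' it can be redefined).
#'
#' @param fixed Fixed-effects formula.
#' @param data Data frame.
#' @return The R-squared value.
#' @export
ols_r2 <- function(fixed, data) {
  vars <- all.vars(fixed)
  df <- data[complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
  y <- df[[all.vars(fixed)[1]]]
  if (var(y) == 0) stop("zero response variance", call. = FALSE)
  summary(lm(fixed, data = df))$r.squared
}

#' Gene-environment interaction model
#'
#' Fits the main-effects model (both polygenic scores, the SES summary
#' score, covariates) and the interaction model adding products of each
#' mean-centered PGS with the mean-centered SES score, both by ML, and
#' compares them with a likelihood-ratio test. Centering makes the main
#' effects interpretable at the average SES and leaves the interaction
#' estimates invariant to recentering of the inputs.
#'
#' @param data Person-wave data frame containing the response, the PGS
#'   columns, the SES score column, covariates and clustering columns.
#' @param response Response column name.
#' @param pgs Character vector of PGS column names.
#' @param ses SES summary score column name.
#' @param covariates Character vector of adjustment columns (demographics,
#'   ancestry PCs).
#' @param random Nested clustering columns, as in [fit_lmm()].
#' @return Object of class `gn_gxe`: `main` and `interaction` `gn_lmm`
#'   fits and the `lrt` between them.
#' @export
fit_gxe <- function(data, response = "pvt_score",
                    pgs = c("pgs_edu_z", "pgs_iq_z"), ses = "ses_pc",
                    covariates = character(),
                    random = c("family_id", "person_id")) {
  need <- c(response, pgs, ses, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("columns absent from data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- data
  ctr <- function(v) v - mean(v, na.rm = TRUE)
  for (v in c(pgs, ses)) d[[paste0(".c_", v)]] <- ctr(d[[v]])
  cp <- paste0(".c_", pgs)
  cs <- paste0(".c_", ses)
  main_terms <- c(cp, cs, covariates)
  int_terms <- c(main_terms, paste0(cp, ":", cs))
  f_main <- reformulate(main_terms, response = response)
  f_int <- reformulate(int_terms, response = response)
  main <- fit_lmm(f_main, d, random = random, method = "ML")
  inter <- fit_lmm(f_int, d, random = random, method = "ML")
  structure(list(main = main, interaction = inter,
                 lrt = lrt(main, inter)), class = "gn_gxe")
}

#' @export
print.gn_gxe <- function(x, ...) {
  cat("== Main-effects model ==\n"); print(x$main)
  cat("\n== G x E interaction model ==\n"); print(x$interaction)
  cat("\n"); print(x$lrt)
  invisible(x)
}

#' Conditional wave-3 analysis table
#'
#' Reshapes the long cohort/design to one row per person with the wave-3
#' response and the wave-1 score as the lagged covariate, keeping only
#' persons observed at both waves (persons lacking either wave are
#' excluded from the conditional analysis by construction). Wave-varying
#' columns are taken from the wave-3 row; the wave-1 neighborhood index,
#' if present, is carried as `nbhd_disadvantage_w1`.
#'
#' @param design Long person-wave data frame with `person_id`, `wave` and
#'   a `pvt_score` column.
#' @return Person-level data frame with `pvt_w3` and `pvt_w1`.
#' @export
wave3_conditional_data <- function(design) {
  w1 <- design[design$wave == 1, , drop = FALSE]
  w3 <- design[design$wave == 3, , drop = FALSE]
  both <- intersect(w1$person_id[!is.na(w1$pvt_score)],
                    w3$person_id[!is.na(w3$pvt_score)])
  w3 <- w3[match(both, w3$person_id), , drop = FALSE]
  w1 <- w1[match(both, w1$person_id), , drop = FALSE]
  out <- w3
  out$pvt_w3 <- w3$pvt_score
  out$pvt_w1 <- w1$pvt_score
  if ("nbhd_disadvantage" %in% names(w1))
    out$nbhd_disadvantage_w1 <- w1$nbhd_disadvantage
  out$pvt_score <- NULL
  rownames(out) <- NULL
  out
}
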