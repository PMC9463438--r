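#' Model-implied single-predictor slopes for a simulated cohort
#'
#' Closed-form population regression slopes derived from the covariance
#' matrix of the generative model, used as an independent oracle for
#' validating fitted models on large simulated cohorts.
#'
#' With independent loci, the transmitted half-score T of a parent has
#' variance `v = sum_k w_k^2 p_k (1 - p_k)` and is independent of the
#' non-transmitted half-score, so `Var(U_o) = 2v`,
#' `Var(S*) = 4 gamma^2 v + var_ses_env`, and
#' `Cov(U_o, S*) = 2 gamma v` (only the transmitted halves covary with
#' the child). On standardized scales with
#' `rho = Corr(U_o, S*) = 2 gamma v / sqrt(2 v Var(S*))` the phenotype
#' model `Y = b Z(U_o) + c Z(S*) + noise` implies
#' \itemize{
#'   \item SES-only slope `c + b * rho`;
#'   \item true-score-only slope `b + c * rho`;
#'   \item measured-score-only slope `a (b + c * rho)`, where
#'     `a = Corr(PGS, U_o)` follows from the realized analyst weights:
#'     `a = sum w w~ 2pq / sqrt(sum w^2 2pq * sum w~^2 2pq)`.
#' }
#' Derived for a single unstructured population; with substructure
#' (`n_strata > 1`, `fst > 0`) the mixture inflates dosage variances and
#' the formulas no longer apply, so this errors.
#'
#' @param sim A `gn_sim` object from [simulate_cohort()].
#' @return List with `ses_only`, `pgs_only_true`, `pgs_only_measured`,
#'   `rho`, and the measured-score `reliability` (`a^2`).
#' @export
implied_slopes <- function(sim) {
  cfg <- sim$config
  if (cfg$n_strata > 1 && cfg$fst > 0)
    stop("closed-form slopes are derived for a single unstructured ",
         "population (n_strata == 1 or fst == 0)", call. = FALSE)
  w <- sim$truth$params$weights_true$beta
  wn <- sim$weights$beta
  p <- sim$truth$params$allele_freq_ancestral
  if (is.null(p))   # read back from disk: regenerate not available
    stop("truth record lacks allele frequencies", call. = FALSE)
  pq <- p * (1 - p)
  v <- sum(w^2 * pq)
  var_s <- 4 * cfg$gamma^2 * v + cfg$var_ses_env
  rho <- 2 * cfg$gamma * v / sqrt(2 * v * var_s)
  a <- sum(w * wn * 2 * pq) /
    sqrt(sum(w^2 * 2 * pq) * sum(wn^2 * 2 * pq))
  list(ses_only = cfg$c_env + cfg$b_child * rho,
       pgs_only_true = cfg$b_child + cfg$c_env * rho,
       pgs_only_measured = a * (cfg$b_child + cfg$c_env * rho),
       rho = rho, reliability = a^2)
}
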