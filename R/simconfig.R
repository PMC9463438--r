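#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set that drives [simulate_cohort()].
#' The generator reproduces the causal structure assumed by the
#' decomposition: parental genomes transmit half their alleles to each
#' child (Mendelian transmission), the summed parental genome score raises
#' parental SES with slope `gamma`, and the two-wave phenotype responds to
#' the standardized offspring score (`b_child`), the standardized SES
#' latent (`c_env`), demographic covariates, and nested random effects at
#' the family, person and wave levels.
#'
#' @param seed Integer seed; every stochastic element of the cohort is a
#'   deterministic function of it.
#' @param n_families Number of families.
#' @param sibs_per_family Children per full-sibling family (twin families
#'   always have exactly two children; singleton families one).
#' @param sibship_mix Named proportions over family types
#'   `c(singleton, fullsib, dz, mz)`; must sum to 1.
#' @param n_snps Number of independent biallelic SNPs (K).
#' @param allele_freq_range Range of the uniform draw for ancestral effect
#'   allele frequencies, inside (0, 1).
#' @param n_strata Number of population strata (substructure); 1 disables
#'   substructure.
#' @param fst Balding-Nichols divergence parameter (>= 0) controlling how
#'   far per-stratum allele frequencies drift from the ancestral ones.
#' @param tau Standard deviation scale of the true score: per-SNP weights
#'   are drawn Normal(0, tau^2/K) so the score variance does not depend
#'   on K.
#' @param gamma Effect of the summed parental genome score (both parents,
#'   all alleles) on the parental SES latent.
#' @param b_child Effect of the standardized offspring true score on the
#'   phenotype.
#' @param c_env Effect of the standardized SES latent on the phenotype.
#' @param gxe_effect Coefficient of the product `Z(U_o) * Z(S*)` in the
#'   phenotype model (gene-environment interaction; 0 disables it).
#' @param var_ses_env Environmental variance of the SES latent.
#' @param var_family,var_person,var_wave Variances of the family, person
#'   and wave-level (residual) random effects.
#' @param gwas_noise_sd Standard deviation of the noise added per SNP to
#'   the true weights to form the analyst-visible weight file. The default
#'   `sqrt(2/3) * tau / sqrt(n_snps)` gives the measured score a
#'   reliability (squared correlation with the true score) of 0.6,
#'   placing realized PGS incremental R-squared in the small-percentage
#'   regime typical of education/cognition scores.
#' @param missing_rate Per-cell MCAR probability applied to the household
#'   SES indicator columns of the emitted cohort.
#' @param beta0 Phenotype intercept (test-score scale).
#'
#' @return An object of class `gn_simconfig` (a validated named list).
#' @seealso [simulate_cohort()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_families = 50)
#' cfg
sim_config <- function(seed,
                       n_families = 3000,
                       sibs_per_family = 2,
                       sibship_mix = c(singleton = 0.85, fullsib = 0.09,
                                       dz = 0.04, mz = 0.02),
                       n_snps = 500,
                       allele_freq_range = c(0.05, 0.95),
                       n_strata = 1,
                       fst = 0,
                       tau = 1,
                       gamma = 0.45,
                       b_child = 2.3,
                       c_env = 3.1,
                       gxe_effect = 0,
                       var_ses_env = 0.55,
                       var_family = 30,
                       var_person = 25,
                       var_wave = 40,
                       gwas_noise_sd = NULL,
                       missing_rate = 0.1,
                       beta0 = 100) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` is mandatory and must be a single integer", call. = FALSE)
  seed <- as.integer(seed)

  types <- c("singleton", "fullsib", "dz", "mz")
  if (is.null(names(sibship_mix)) || !all(names(sibship_mix) %in% types))
    stop("`sibship_mix` must be named with: ", paste(types, collapse = ", "),
         call. = FALSE)
  mix <- setNames(numeric(4), types)
  mix[names(sibship_mix)] <- sibship_mix
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    stop("`sibship_mix` proportions must be non-negative and sum to 1",
         call. = FALSE)
  if (any(mix[c("fullsib", "dz", "mz")] > 0) && sibs_per_family < 2)
    stop("infeasible sibship mix: multi-child family types requested with ",
         "sibs_per_family < 2", call. = FALSE)

  stopifnot(n_families >= 1, n_snps >= 1, n_strata >= 1, fst >= 0)
  if (length(allele_freq_range) != 2 ||
      any(allele_freq_range <= 0) || any(allele_freq_range >= 1) ||
      diff(allele_freq_range) < 0)
    stop("`allele_freq_range` must be an increasing pair inside (0, 1)",
         call. = FALSE)
  vars <- c(var_ses_env = var_ses_env, var_family = var_family,
            var_person = var_person, var_wave = var_wave)
  if (any(vars < 0)) stop("all variances must be >= 0", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 1)
    stop("`missing_rate` must be in [0, 1]", call. = FALSE)
  if (is.null(gwas_noise_sd)) gwas_noise_sd <- sqrt(2 / 3) * tau / sqrt(n_snps)
  if (gwas_noise_sd < 0) stop("`gwas_noise_sd` must be >= 0", call. = FALSE)

  cfg <- list(seed = seed, n_families = as.integer(n_families),
              sibs_per_family = as.integer(sibs_per_family),
              sibship_mix = mix, n_snps = as.integer(n_snps),
              allele_freq_range = allele_freq_range,
              n_strata = as.integer(n_strata), fst = fst, tau = tau,
              gamma = gamma, b_child = b_child, c_env = c_env,
              gxe_effect = gxe_effect,
              var_ses_env = var_ses_env, var_family = var_family,
              var_person = var_person, var_wave = var_wave,
              gwas_noise_sd = gwas_noise_sd, missing_rate = missing_rate,
              beta0 = beta0)
  class(cfg) <- "gn_simconfig"
  cfg
}

# Fixed demographic effects on the phenotype (generator constants,
# recorded in the truth record for parameter-recovery checks).
demographic_effects <- function() {
  c(age = 0.4, female = -1.1, us_born = 2.0, english_home = 4.6,
    in_school = 1.5, hispanic = -1.0)
}

#' @export
print.gn_simconfig <- function(x, ...) {
  cat("Synthetic cohort configuration (seed ", x$seed, ")\n", sep = "")
  cat("  families:", x$n_families, " SNPs:", x$n_snps,
      " strata:", x$n_strata, " fst:", x$fst, "\n")
  cat("  sibship mix:",
      paste(sprintf("%s=%.2f", names(x$sibship_mix), x$sibship_mix),
            collapse = " "), "\n")
  cat(sprintf("  gamma=%.3g b_child=%.3g c_env=%.3g var_ses_env=%.3g\n",
              x$gamma, x$b_child, x$c_env, x$var_ses_env))
  cat(sprintf("  variances (family/person/wave): %.3g / %.3g / %.3g\n",
              x$var_family, x$var_person, x$var_wave))
  cat(sprintf("  tau=%.3g gwas_noise_sd=%.4g missing_rate=%.2f\n",
              x$tau, x$gwas_noise_sd, x$missing_rate))
  invisible(x)
}
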