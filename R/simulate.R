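#' Mendelian transmission from one parent
#'
#' Given a parent's two phased haplotypes, draws which of the two alleles
#' is transmitted at every SNP, independently across SNPs with probability
#' 1/2 (independent loci; no linkage). The allele not chosen is returned
#' as the non-transmitted complement, so `transmitted + non_transmitted`
#' always equals the parent's genotype.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param hap1,hap2 0/1 integer vectors of equal length K (the parent's
#'   two haplotypes).
#' @return A list with `transmitted` and `non_transmitted` 0/1 vectors.
#' @export
#' @examples
#' set.seed(1)
#' transmit_alleles(c(0L, 1L, 1L), c(0L, 0L, 1L))
transmit_alleles <- function(hap1, hap2) {
  if (length(hap1) != length(hap2))
    stop("haplotypes must have equal length", call. = FALSE)
  mask <- rbinom(length(hap1), 1L, 0.5)
  list(transmitted = mask * hap1 + (1L - mask) * hap2,
       non_transmitted = (1L - mask) * hap1 + mask * hap2)
}

# 16 detailed occupation labels in increasing prestige order. The same
# ordering underlies the packaged 16 -> 5 class collapse and 16 -> 11
# prestige lookup (inst/extdata/occupation_lookup.csv).
occupation_labels <- function() {
  c("none_or_unemployed", "homemaker", "laborer", "farm_worker",
    "service_worker", "machine_operator", "craftsperson", "military",
    "clerical", "sales_worker", "transport_operator", "technician",
    "teacher_nurse", "manager", "engineer_scientist", "professional")
}

#' Parental SES latent and observable indicators
#'
#' Generates the parental SES latent `S* = gamma * (U_mother + U_father)
#' + e_S`, `e_S ~ Normal(0, var_ses_env)`, plus the observable indicator
#' block derived from it: parental education (3 ordered levels by cohort
#' quantiles), income quintile, detailed parental occupation (16 labels
#' later collapsed through the packaged lookup), reported sibship size, a
#' two-biological-parent flag, and six tract-level proportions per wave
#' whose disadvantage measures decrease in `S*` (poverty, unemployment,
#' female-headed households, adults without a diploma) while the
#' college-degree and managerial-job shares increase in it.
#'
#' Uses the current RNG state; [simulate_cohort()] calls this after
#' seeding.
#'
#' @param u_mother,u_father Numeric vectors of parental true genome
#'   scores, one entry per family.
#' @param config A [sim_config()] object.
#' @return A list with `s_star`, `s_env` (the environmental part), and a
#'   per-family `indicators` data frame (tract proportions carry `_w1` /
#'   `_w3` suffixes).
#' @export
build_parental_ses <- function(u_mother, u_father, config) {
  stopifnot(length(u_mother) == length(u_father))
  n <- length(u_mother)
  eps <- rnorm(n, 0, sqrt(config$var_ses_env))
  s_star <- config$gamma * (u_mother + u_father) + eps
  zs <- if (n > 1 && sd(s_star) > 0) as.numeric(scale(s_star)) else numeric(n)

  cut_by_quantile <- function(latent, probs, labels) {
    qs <- quantile(latent, probs = probs, names = FALSE)
    labels[findInterval(latent, qs) + 1L]
  }
  edu_levels <- c("less_than_hs", "hs_some_college", "college_plus")
  occ <- occupation_labels()

  indicators <- data.frame(
    mother_edu = cut_by_quantile(zs + rnorm(n, 0, 0.8), c(0.16, 0.70),
                                 edu_levels),
    father_edu = cut_by_quantile(zs + rnorm(n, 0, 0.8), c(0.16, 0.70),
                                 edu_levels),
    income_q = cut_by_quantile(zs + rnorm(n, 0, 0.8),
                               c(0.2, 0.4, 0.6, 0.8), paste0("q", 1:5)),
    mother_occ = cut_by_quantile(zs + rnorm(n, 0, 1.0),
                                 seq_len(15) / 16, occ),
    father_occ = cut_by_quantile(zs + rnorm(n, 0, 1.0),
                                 seq_len(15) / 16, occ),
    sibship_size = rpois(n, exp(0.8 - 0.3 * zs)),
    two_bio_parents = rbinom(n, 1L, plogis(0.05 + 0.4 * zs)),
    stringsAsFactors = FALSE
  )
  # Six tract measures, drawn separately for waves 1 and 3.
  tract <- function(intercept, loading) {
    plogis(intercept + loading * zs + rnorm(n, 0, 0.35))
  }
  specs <- list(nbhd_poverty = c(-1.8, -0.9),
                nbhd_unemployed = c(-2.2, -0.7),
                nbhd_female_headed = c(-1.6, -0.6),
                nbhd_no_diploma = c(-1.2, -0.8),
                nbhd_college = c(-1.0, 0.9),
                nbhd_managerial = c(-1.1, 0.8))
  for (w in c(1L, 3L)) {
    for (nm in names(specs)) {
      indicators[[paste0(nm, "_w", w)]] <- tract(specs[[nm]][1],
                                                 specs[[nm]][2])
    }
  }
  list(s_star = as.numeric(s_star), s_env = eps, indicators = indicators)
}

#' Simulate a sibling-clustered two-wave cohort with trio genotypes
#'
#' Generates a full synthetic study: phased parental haplotypes, Mendelian
#' transmission to each child (monozygotic co-twins copy the first twin's
#' transmission outcome; dizygotic twins and full siblings transmit
#' independently), parental SES driven by the summed parental genome
#' score, and a two-wave phenotype
#' `Y_tij = beta0 + b_child * Z(U_o) + c_env * Z(S*) + demographics +
#' u_j + v_ij + e_tij` observed at waves 1 and 3. The analyst-visible
#' GWAS weight files are noisy versions of the true weights: a primary
#' (education-like) file with noise sd `gwas_noise_sd` and a secondary
#' (cognitive-ability-like) file with twice that noise, mimicking a pair
#' of correlated scores of unequal precision for the same trait.
#'
#' @param config A [sim_config()] object.
#' @param detail `"standard"` keeps the child dosage matrix; `"full"`
#'   additionally keeps parental haplotypes and per-child transmitted
#'   allele matrices (memory-heavy; meant for small validation runs);
#'   `"minimal"` keeps no genotype matrices (truth scores only).
#' @return A list of class `gn_sim` with elements `cohort` (long
#'   person-wave data frame), `trios` (genotype bookkeeping, see
#'   `detail`), `truth` (per-person truth record, per-row wave effects,
#'   and the true parameters), `weights` and `weights_iq` (analyst weight
#'   tables: `snp_id`, `effect_allele`, `beta`).
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(seed = 7, n_families = 40,
#'                                   n_snps = 60))
#' head(sim$cohort)
simulate_cohort <- function(config,
                            detail = c("standard", "full", "minimal")) {
  stopifnot(inherits(config, "gn_simconfig"))
  detail <- match.arg(detail)
  set.seed(config$seed)
  K <- config$n_snps
  nfam <- config$n_families

  # SNP metadata: non-complementary allele pairs (A/T and C/G SNPs are
  # strand-ambiguous and deliberately never produced).
  pairs <- rbind(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"),
                 c("C", "A"), c("G", "A"), c("C", "T"), c("G", "T"))
  pick <- sample.int(nrow(pairs), K, replace = TRUE)
  snp_id <- sprintf("snp%05d", seq_len(K))
  effect_allele <- pairs[pick, 1]
  other_allele <- pairs[pick, 2]

  p_anc <- runif(K, config$allele_freq_range[1], config$allele_freq_range[2])
  S <- config$n_strata
  if (S > 1 && config$fst > 0) {
    f <- config$fst
    P <- matrix(rbeta(K * S, rep(p_anc, S) * (1 - f) / f,
                      rep(1 - p_anc, S) * (1 - f) / f), K, S)
    P <- pmin(pmax(P, 0.01), 0.99)
  } else {
    P <- matrix(p_anc, K, S)
  }

  w_true <- rnorm(K, 0, config$tau / sqrt(K))
  beta_edu <- w_true + rnorm(K, 0, config$gwas_noise_sd)
  beta_iq <- w_true + rnorm(K, 0, 2 * config$gwas_noise_sd)

  types <- names(config$sibship_mix)
  fam_type <- sample(types, nfam, replace = TRUE, prob = config$sibship_mix)
  n_children <- ifelse(fam_type == "singleton", 1L,
                       ifelse(fam_type == "fullsib",
                              config$sibs_per_family, 2L))
  stratum <- sample.int(S, nfam, replace = TRUE)
  family_id <- sprintf("f%05d", seq_len(nfam))

  pm <- t(P[, stratum, drop = FALSE])            # nfam x K success probs
  draw_hap <- function() matrix(rbinom(length(pm), 1L, as.vector(pm)),
                                nfam, K)
  m1 <- draw_hap(); m2 <- draw_hap(); f1 <- draw_hap(); f2 <- draw_hap()
  u_mother <- as.numeric((m1 + m2) %*% w_true)
  u_father <- as.numeric((f1 + f2) %*% w_true)

  max_kids <- max(n_children)
  slot_rows <- vector("list", max_kids)   # per-slot family indices
  dos_blocks <- vector("list", max_kids)
  tm_blocks <- vector("list", max_kids)
  tf_blocks <- vector("list", max_kids)
  tmo_blocks <- vector("list", max_kids)  # transmitted maternal score
  tfa_blocks <- vector("list", max_kids)
  mask_m1 <- mask_f1 <- NULL
  for (s in seq_len(max_kids)) {
    idx <- which(n_children >= s)
    mk_m <- matrix(rbinom(length(idx) * K, 1L, 0.5), length(idx), K)
    mk_f <- matrix(rbinom(length(idx) * K, 1L, 0.5), length(idx), K)
    if (s == 1L) {
      mask_m1 <- matrix(0L, nfam, K); mask_f1 <- matrix(0L, nfam, K)
      mask_m1[idx, ] <- mk_m; mask_f1[idx, ] <- mk_f
    } else {
      mz <- fam_type[idx] == "mz"
      if (any(mz)) {                     # MZ co-twin copies twin 1
        mk_m[mz, ] <- mask_m1[idx[mz], , drop = FALSE]
        mk_f[mz, ] <- mask_f1[idx[mz], , drop = FALSE]
      }
    }
    Tm <- mk_m * m1[idx, , drop = FALSE] + (1L - mk_m) * m2[idx, , drop = FALSE]
    Tf <- mk_f * f1[idx, , drop = FALSE] + (1L - mk_f) * f2[idx, , drop = FALSE]
    slot_rows[[s]] <- idx
    dos_blocks[[s]] <- Tm + Tf
    tmo_blocks[[s]] <- as.numeric(Tm %*% w_true)
    tfa_blocks[[s]] <- as.numeric(Tf %*% w_true)
    if (detail == "full") { tm_blocks[[s]] <- Tm; tf_blocks[[s]] <- Tf }
  }

  # Person ordering: by family, then birth order.
  fam_of_person <- unlist(slot_rows)
  slot_of_person <- rep(seq_len(max_kids), vapply(slot_rows, length, 1L))
  ord <- order(fam_of_person, slot_of_person)
  fam_of_person <- fam_of_person[ord]
  slot_of_person <- slot_of_person[ord]
  n_persons <- length(fam_of_person)
  person_id <- sprintf("p%06d", seq_len(n_persons))

  dosage <- do.call(rbind, dos_blocks)[ord, , drop = FALSE]
  colnames(dosage) <- snp_id
  rownames(dosage) <- person_id
  t_mother <- unlist(tmo_blocks)[ord]
  t_father <- unlist(tfa_blocks)[ord]
  u_o <- t_mother + t_father
  stopifnot(max(abs(u_o - as.numeric(dosage %*% w_true))) < 1e-10)

  ses <- build_parental_ses(u_mother, u_father, config)
  zs_fam <- if (sd(ses$s_star) > 0) as.numeric(scale(ses$s_star)) else
    numeric(nfam)
  zu <- if (sd(u_o) > 0) as.numeric(scale(u_o)) else numeric(n_persons)

  # demographics (person level)
  female <- rbinom(n_persons, 1L, 0.52)
  age_w1 <- runif(n_persons, 12, 19)
  us_born <- rbinom(n_persons, 1L, 0.67)
  hispanic <- if (S > 1) as.integer(stratum[fam_of_person] > 1) else
    rbinom(n_persons, 1L, 0.19)
  english_home <- ifelse(hispanic == 1L, rbinom(n_persons, 1L, 0.55),
                         rbinom(n_persons, 1L, 0.99))

  u_fam <- rnorm(nfam, 0, sqrt(config$var_family))
  v_per <- rnorm(n_persons, 0, sqrt(config$var_person))

  de <- demographic_effects()
  waves <- c(1L, 3L)
  rows <- vector("list", 2)
  wave_eff <- vector("list", 2)
  for (k in seq_along(waves)) {
    w <- waves[k]
    age <- if (w == 1L) age_w1 else age_w1 + 6
    in_school <- rbinom(n_persons, 1L, if (w == 1L) 0.9 else 0.35)
    e <- rnorm(n_persons, 0, sqrt(config$var_wave))
    y <- config$beta0 + config$b_child * zu +
      config$c_env * zs_fam[fam_of_person] +
      config$gxe_effect * zu * zs_fam[fam_of_person] +
      de["age"] * age + de["female"] * female + de["us_born"] * us_born +
      de["english_home"] * english_home + de["in_school"] * in_school +
      de["hispanic"] * hispanic +
      u_fam[fam_of_person] + v_per + e
    ind <- ses$indicators[fam_of_person, , drop = FALSE]
    nb <- ind[, paste0(c("nbhd_poverty", "nbhd_unemployed",
                         "nbhd_female_headed", "nbhd_no_diploma",
                         "nbhd_college", "nbhd_managerial"), "_w", w)]
    names(nb) <- sub("_w[13]$", "", names(nb))
    rows[[k]] <- data.frame(
      person_id = person_id, family_id = family_id[fam_of_person],
      tract_id = family_id[fam_of_person],
      sibship_type = fam_type[fam_of_person],
      stratum = stratum[fam_of_person], wave = w,
      pvt_score = as.numeric(y), age = age,
      sex = ifelse(female == 1L, "female", "male"),
      us_born = us_born, english_home = english_home, hispanic = hispanic,
      in_school = in_school,
      mother_edu = ind$mother_edu, father_edu = ind$father_edu,
      mother_occ = ind$mother_occ, father_occ = ind$father_occ,
      income_q = ind$income_q, two_bio_parents = ind$two_bio_parents,
      sibship_size = ind$sibship_size,
      nb, stringsAsFactors = FALSE, row.names = NULL)
    wave_eff[[k]] <- data.frame(person_id = person_id, wave = w,
                                e_wave = e, stringsAsFactors = FALSE)
  }
  cohort <- rbind(rows[[1]], rows[[2]])
  cohort <- cohort[order(cohort$person_id, cohort$wave), , drop = FALSE]
  rownames(cohort) <- NULL

  if (config$missing_rate > 0)
    cohort <- inject_missingness(cohort, config$missing_rate)

  truth_persons <- data.frame(
    person_id = person_id, family_id = family_id[fam_of_person],
    sibship_type = fam_type[fam_of_person],
    stratum = stratum[fam_of_person],
    u_o = u_o, z_u = zu,
    t_score = u_o, nt_score = (u_mother + u_father)[fam_of_person] - u_o,
    t_mother = t_mother, nt_mother = u_mother[fam_of_person] - t_mother,
    t_father = t_father, nt_father = u_father[fam_of_person] - t_father,
    u_mother = u_mother[fam_of_person], u_father = u_father[fam_of_person],
    s_star = ses$s_star[fam_of_person], s_env = ses$s_env[fam_of_person],
    z_s = zs_fam[fam_of_person],
    u_family = u_fam[fam_of_person], v_person = v_per,
    stringsAsFactors = FALSE)

  truth <- list(
    persons = truth_persons,
    waves = rbind(wave_eff[[1]], wave_eff[[2]]),
    params = list(config = config, demographic_effects = as.list(de),
                  weights_true = data.frame(snp_id = snp_id,
                                            effect_allele = effect_allele,
                                            beta = w_true,
                                            stringsAsFactors = FALSE),
                  allele_freq = P, allele_freq_ancestral = p_anc))
  class(truth) <- "gn_truth"

  trios <- list(snp_id = snp_id, effect_allele = effect_allele,
                other_allele = other_allele,
                dosage = if (detail != "minimal") dosage else NULL)
  if (detail == "full") {
    reorder_block <- function(blocks) {
      m <- do.call(rbind, blocks)[ord, , drop = FALSE]
      dimnames(m) <- list(person_id, snp_id)
      m
    }
    trios$transmitted_maternal <- reorder_block(tm_blocks)
    trios$transmitted_paternal <- reorder_block(tf_blocks)
    trios$maternal_haplotypes <- list(h1 = m1, h2 = m2)
    trios$paternal_haplotypes <- list(h1 = f1, h2 = f2)
  }

  out <- list(cohort = cohort, trios = trios, truth = truth,
              weights = data.frame(snp_id = snp_id,
                                   effect_allele = effect_allele,
                                   beta = beta_edu, stringsAsFactors = FALSE),
              weights_iq = data.frame(snp_id = snp_id,
                                      effect_allele = effect_allele,
                                      beta = beta_iq,
                                      stringsAsFactors = FALSE),
              config = config)
  class(out) <- "gn_sim"
  out
}

#' @export
print.gn_sim <- function(x, ...) {
  cat("Synthetic cohort: ", length(unique(x$cohort$person_id)),
      " persons in ", length(unique(x$cohort$family_id)), " families, ",
      nrow(x$cohort), " person-wave rows, ", x$config$n_snps,
      " SNPs (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

# Household SES indicator columns subject to MCAR missingness.
ses_indicator_cols <- function() {
  c("mother_edu", "father_edu", "mother_occ", "father_occ", "income_q",
    "two_bio_parents", "sibship_size")
}

#' Inject MCAR missingness into SES indicators
#'
#' Sets each household SES indicator cell to `NA` independently with the
#' given probability. Phenotype, identifiers, demographics and tract
#' measures are never touched. Uses the current RNG state.
#'
#' @param cohort A cohort data frame (long person-wave format).
#' @param rate Per-cell missingness probability in \[0, 1\].
#' @return The cohort with missing cells set to `NA`.
#' @export
inject_missingness <- function(cohort, rate) {
  if (!is.numeric(rate) || length(rate) != 1 || is.na(rate) ||
      rate < 0 || rate > 1)
    stop("`rate` must be a probability in [0, 1]", call. = FALSE)
  if (rate == 0) return(cohort)
  for (col in intersect(ses_indicator_cols(), names(cohort))) {
    hit <- rbinom(nrow(cohort), 1L, rate) == 1L
    cohort[[col]][hit] <- NA
  }
  cohort
}
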