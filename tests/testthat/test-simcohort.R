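test_that("transmission is deterministic for homozygotes and fair for heterozygotes", {
  set.seed(1)
  # homozygous 0 and homozygous 1 parents leave no choice
  tr0 <- transmit_alleles(rep(0L, 20), rep(0L, 20))
  expect_equal(tr0$transmitted, rep(0L, 20))
  expect_equal(tr0$non_transmitted, rep(0L, 20))
  tr1 <- transmit_alleles(rep(1L, 20), rep(1L, 20))
  expect_equal(tr1$transmitted, rep(1L, 20))
  expect_equal(tr1$non_transmitted, rep(1L, 20))

  # heterozygous parent: binomial oracle, 10,000 draws
  het <- transmit_alleles(rep(1L, 10000), rep(0L, 10000))
  expect_lt(abs(mean(het$transmitted) - 0.5), 3 * sqrt(0.25 / 10000))
  # complement identity
  expect_true(all(het$transmitted + het$non_transmitted == 1L))

  expect_error(transmit_alleles(c(0L, 1L), c(0L, 1L, 1L)), "equal length")
})

test_that("Mendelian identities hold: dosages, T/NT bookkeeping, twins", {
  sim <- small_sim()
  tri <- sim$trios
  tp <- sim$truth$persons

  # offspring dosage = transmitted maternal + transmitted paternal allele
  expect_true(all(tri$dosage ==
                    tri$transmitted_maternal + tri$transmitted_paternal))
  # T + NT per parent equals that parent's total score
  expect_equal(tp$t_mother + tp$nt_mother, tp$u_mother, tolerance = 1e-12)
  expect_equal(tp$t_father + tp$nt_father, tp$u_father, tolerance = 1e-12)
  expect_equal(tp$t_score + tp$nt_score, tp$u_mother + tp$u_father,
               tolerance = 1e-12)

  # MZ co-twins have identical genotypes (hence identical scores)
  mz <- tp[tp$sibship_type == "mz", ]
  for (fam in unique(mz$family_id)) {
    ids <- mz$person_id[mz$family_id == fam]
    expect_identical(tri$dosage[ids[1], ], tri$dosage[ids[2], ])
  }
  expect_true(all(table(mz$family_id) == 2))

  # DZ/full sibs share half their alleles on average (IBD proxy via
  # transmitted-allele agreement with each parent)
  sib <- tp[tp$sibship_type %in% c("dz", "fullsib"), ]
  shares <- vapply(unique(sib$family_id), function(fam) {
    ids <- sib$person_id[sib$family_id == fam][1:2]
    m_share <- mean(tri$transmitted_maternal[ids[1], ] ==
                      tri$transmitted_maternal[ids[2], ])
    p_share <- mean(tri$transmitted_paternal[ids[1], ] ==
                      tri$transmitted_paternal[ids[2], ])
    (m_share + p_share) / 2
  }, numeric(1))
  # identical transmitted alleles at a SNP happen with prob 1/2 when the
  # parent is heterozygous and always otherwise, so expected agreement
  # exceeds 1/2; the IBD proportion itself is the mask agreement, which
  # is Binomial(K, 1/2) per parent.
  expect_gt(mean(shares), 0.5)
})

test_that("cohort assembly: counts, determinism, infeasible mixes", {
  cfg <- sim_config(seed = 5, n_families = 100, n_snps = 30,
                    sibship_mix = c(fullsib = 1), sibs_per_family = 2,
                    missing_rate = 0)
  sim <- simulate_cohort(cfg)
  expect_equal(length(unique(sim$cohort$person_id)), 200)
  expect_equal(nrow(sim$cohort), 400)
  expect_setequal(unique(sim$cohort$wave), c(1, 3))

  sim2 <- simulate_cohort(cfg)
  expect_identical(sim$cohort, sim2$cohort)
  expect_identical(sim$weights, sim2$weights)
  expect_identical(sim$truth$persons, sim2$truth$persons)

  expect_error(sim_config(seed = 1, sibship_mix = c(mz = 1),
                          sibs_per_family = 1), "infeasible")
  expect_error(sim_config(seed = 1,
                          sibship_mix = c(singleton = 0.5, mz = 0.2)),
               "sum to 1")
  expect_error(sim_config(seed = 1, var_wave = -1), "variances")
  expect_error(sim_config(n_families = 10), "seed")
})

test_that("parental SES construction follows the path-B generative model", {
  n <- 4000
  set.seed(9)
  um <- rnorm(n); uf <- rnorm(n)

  # gamma = 0: SES independent of the mid-parent score
  ses0 <- build_parental_ses(um, uf, sim_config(seed = 1, gamma = 0))
  expect_lt(abs(cor(ses0$s_star, um + uf)), 3 / sqrt(n))

  # no environmental noise: SES is a deterministic function of parents
  ses1 <- build_parental_ses(um, uf,
                             sim_config(seed = 1, gamma = 0.5,
                                        var_ses_env = 0))
  expect_equal(cor(ses1$s_star, um + uf), 1, tolerance = 1e-12)

  # default config: offspring score and parental SES positively coupled
  sim <- noiseless_sim()
  tp <- sim$truth$persons
  expect_gt(cor(tp$z_u, tp$s_star), 0)

  # indicators respond to the latent: college share rises with S*
  ind <- ses1$indicators
  hi <- ses1$s_star > quantile(ses1$s_star, 0.8)
  lo <- ses1$s_star < quantile(ses1$s_star, 0.2)
  expect_gt(mean(ind$mother_edu[hi] == "college_plus"),
            mean(ind$mother_edu[lo] == "college_plus"))
  expect_gt(mean(ind$nbhd_poverty_w1[lo]), mean(ind$nbhd_poverty_w1[hi]))
})

test_that("missingness injection is MCAR at the requested rate", {
  sim <- noiseless_sim()
  cohort <- sim$cohort

  expect_identical(inject_missingness(cohort, 0), cohort)

  set.seed(3)
  all_na <- inject_missingness(cohort, 1)
  expect_true(all(is.na(all_na$mother_edu)))
  expect_true(all(is.na(all_na$income_q)))
  expect_false(anyNA(all_na$pvt_score))
  expect_false(anyNA(all_na$person_id))

  set.seed(4)
  big <- cohort[rep(seq_len(nrow(cohort)), length.out = 10000), ]
  out <- inject_missingness(big, 0.3)
  frac <- mean(is.na(out$father_edu))
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))

  expect_error(inject_missingness(cohort, 1.2), "probability")
  expect_error(inject_missingness(cohort, -0.1), "probability")
})

test_that("written artifacts round-trip and follow the .raw contract", {
  sim <- small_sim()
  dir <- tempfile()
  paths <- write_cohort(sim, dir)
  rb <- read_cohort(dir)

  expect_equal(rb$cohort$pvt_score, sim$cohort$pvt_score, tolerance = 1e-14)
  expect_identical(rb$cohort$mother_edu, sim$cohort$mother_edu)
  expect_equal(rb$weights$beta, sim$weights$beta, tolerance = 1e-14)
  expect_equal(rb$truth$persons$u_o, sim$truth$persons$u_o,
               tolerance = 1e-14)
  # dosages identical after read-back (counted allele = effect allele)
  expect_equal(unname(rb$dosages$dosage),
               unname(sim$trios$dosage[rb$dosages$ids, ]))

  header <- strsplit(readLines(paths[["raw"]], n = 1), " ")[[1]]
  expect_identical(header[1:6],
                   c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
  expect_match(header[7], "^snp[0-9]+_[ACGT]$")

  # degenerate case: empty cohort still writes valid headed files
  empty <- sim
  empty$cohort <- sim$cohort[0, ]
  empty$truth$persons <- sim$truth$persons[0, ]
  empty$truth$waves <- sim$truth$waves[0, ]
  dir2 <- tempfile()
  p2 <- write_cohort(empty, dir2)
  expect_identical(readLines(p2[["cohort"]], n = 1),
                   paste(names(sim$cohort), collapse = ","))
  expect_gt(length(readLines(p2[["raw"]])), 0)
})
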