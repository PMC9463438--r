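test_that("categorical blocks are reference-coded, exclusive, schema-stable", {
  sim <- small_sim()
  des <- encode_categoricals(sim$cohort)

  # block of m categories + missing emits m-1+1 columns
  expect_setequal(
    grep("^mother_edu_", names(des), value = TRUE),
    c("mother_edu_hs_some_college", "mother_edu_college_plus",
      "mother_edu_missing"))
  expect_setequal(
    grep("^father_occ_", names(des), value = TRUE),
    c("father_occ_none_other", "father_occ_sales_service_admin",
      "father_occ_professional_managerial", "father_occ_missing"))

  # exclusivity/exhaustiveness: indicators within a block sum to 0
  # (reference) or 1, and missing rows light exactly the missing column
  for (block in list(grep("^mother_edu_", names(des), value = TRUE),
                     grep("^income_q_", names(des), value = TRUE),
                     grep("^sibship_", names(des), value = TRUE))) {
    block <- setdiff(block, "sibship_type")
    sums <- rowSums(des[, block, drop = FALSE])
    expect_true(all(sums %in% c(0, 1)))
  }
  na_rows <- is.na(sim$cohort$mother_edu)
  expect_true(all(des$mother_edu_missing[na_rows] == 1))
  expect_true(all(rowSums(des[na_rows, c("mother_edu_hs_some_college",
                                         "mother_edu_college_plus")]) == 0))

  # missing column present (all zero) even when nothing is missing
  clean <- simulate_cohort(tiny_config(seed = 8))
  des2 <- encode_categoricals(clean$cohort)
  expect_true("mother_edu_missing" %in% names(des2))
  expect_equal(sum(des2$mother_edu_missing), 0)

  bad <- clean$cohort
  bad$mother_edu[1] <- "phd"
  expect_error(encode_categoricals(bad), "mother_edu.*phd")
})

nb_panel <- function(n = 40, waves = c(1, 3), seed = 2) {
  set.seed(seed)
  out <- do.call(rbind, lapply(waves, function(w) {
    lat <- rnorm(n)
    data.frame(tract_id = paste0("t", seq_len(n)), wave = w,
               nbhd_poverty = plogis(-1 + lat),
               nbhd_unemployed = plogis(-1.5 + 0.8 * lat),
               nbhd_female_headed = plogis(-1 + 0.6 * lat),
               nbhd_no_diploma = plogis(-0.5 + 0.9 * lat),
               nbhd_college = plogis(-0.2 - 0.9 * lat),
               nbhd_managerial = plogis(-0.3 - 0.8 * lat))
  }))
  out
}

test_that("neighborhood index: per-wave PC1, poverty-positive, standardized", {
  panel <- nb_panel()
  idx <- neighborhood_index(panel)
  for (w in c(1, 3)) {
    v <- idx$nbhd_disadvantage[idx$wave == w]
    expect_equal(mean(v), 0, tolerance = 1e-10)
    expect_equal(sd(v), 1, tolerance = 1e-10)
    # orientation: disadvantage rises with the poverty share
    expect_gt(cor(v, panel$nbhd_poverty[panel$wave == w]), 0)
  }

  # single common factor with no noise: PC1 explains everything
  lat <- seq(-2, 2, length.out = 30)
  pure <- data.frame(tract_id = paste0("t", 1:30), wave = 1,
                     nbhd_poverty = 0.3 + 0.1 * lat,
                     nbhd_unemployed = 0.2 + 0.05 * lat,
                     nbhd_female_headed = 0.25 + 0.07 * lat,
                     nbhd_no_diploma = 0.4 + 0.1 * lat,
                     nbhd_college = 0.3 - 0.08 * lat,
                     nbhd_managerial = 0.35 - 0.06 * lat)
  idxp <- neighborhood_index(pure)
  expect_equal(abs(cor(idxp$nbhd_disadvantage, lat)), 1, tolerance = 1e-10)

  # affine rescaling of an input measure changes nothing
  resc <- panel
  resc$nbhd_college <- 100 * resc$nbhd_college - 3
  expect_equal(neighborhood_index(resc)$nbhd_disadvantage,
               idx$nbhd_disadvantage, tolerance = 1e-10)
  # ... and negating it leaves the poverty orientation intact
  neg <- panel
  neg$nbhd_college <- -neg$nbhd_college
  idxn <- neighborhood_index(neg)
  expect_gt(cor(idxn$nbhd_disadvantage[idxn$wave == 1],
                panel$nbhd_poverty[panel$wave == 1]), 0)

  flat <- pure
  flat[, 3:8] <- 0.5
  expect_error(neighborhood_index(flat), "zero variance")
})

test_that("SES summary PC tracks a common factor with education-positive sign", {
  sim <- small_sim()
  spc <- ses_summary_pc(sim$cohort)
  expect_equal(sd(spc$ses_pc), 1, tolerance = 1e-10)
  expect_equal(mean(spc$ses_pc), 0, tolerance = 1e-10)

  # deterministic given input
  expect_identical(spc, ses_summary_pc(sim$cohort))

  # tracks the SES latent it was built from
  s_star <- truth_of(sim, "s_star", spc$person_id)
  expect_gt(cor(spc$ses_pc, s_star), 0.8)

  # orientation: a person with maximal education/income/occupation sits
  # above the cohort mean
  top <- sim$cohort
  w1 <- top$wave == 1 & !duplicated(top$person_id)
  best <- which(w1)[1]
  top$mother_edu[best] <- "college_plus"; top$father_edu[best] <- "college_plus"
  top$income_q[best] <- "q5"
  top$mother_occ[best] <- "professional"; top$father_occ[best] <- "professional"
  top$sibship_size[best] <- 0; top$two_bio_parents[best] <- 1
  spc2 <- ses_summary_pc(top)
  expect_gt(spc2$ses_pc[spc2$person_id == top$person_id[best]], 0)

  # indicators proportional to one variable -> |cor| = 1 with it
  n <- 50
  v <- seq_len(n)
  fake <- data.frame(
    person_id = paste0("p", v), tract_id = paste0("t", v), wave = 1,
    stratum = 1,
    mother_edu = c("less_than_hs", "hs_some_college",
                   "college_plus")[cut(v, 3, labels = FALSE)],
    father_edu = c("less_than_hs", "hs_some_college",
                   "college_plus")[cut(v, 3, labels = FALSE)],
    income_q = paste0("q", cut(v, 5, labels = FALSE)),
    mother_occ = occupation_lookup()$occ_detail[
      cut(v, 16, labels = FALSE)],
    father_occ = occupation_lookup()$occ_detail[
      cut(v, 16, labels = FALSE)],
    sibship_size = rev(cut(v, 4, labels = FALSE)),
    two_bio_parents = as.integer(v > n / 2),
    stringsAsFactors = FALSE)
  spc3 <- ses_summary_pc(fake)
  expect_gt(cor(spc3$ses_pc, v), 0.95)
})

test_that("occupation lookup maps all 16 detailed labels onto both scales", {
  lk <- occupation_lookup()
  expect_equal(nrow(lk), 16)
  expect_true(all(lk$prestige11 %in% 1:11))
  expect_setequal(unique(lk$class5),
                  c("none_other", "manual_blue_collar",
                    "sales_service_admin", "professional_managerial"))
})
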