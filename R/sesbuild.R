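#' Occupation coding lookup
#'
#' Loads the packaged mapping from the 16 detailed occupation labels to
#' (a) the 5-category analysis classes (none/other, manual or blue
#' collar, sales/service/administrative, professional or managerial, plus
#' the implicit missing level) and (b) an 11-level prestige scale used by
#' the SES summary component. The table is a package default standing in
#' for external occupational-prestige ratings; users can supply an edited
#' copy via `path`.
#'
#' @param path Optional path to a replacement CSV with columns
#'   `occ_detail`, `class5`, `prestige11`.
#' @return Data frame with the mapping.
#' @export
occupation_lookup <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "occupation_lookup.csv",
                        package = "gnurture")
  lk <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  stopifnot(all(c("occ_detail", "class5", "prestige11") %in% names(lk)))
  lk
}

# Categorical block definitions: levels (reference first) per block.
ses_block_levels <- function() {
  list(
    mother_edu = c("less_than_hs", "hs_some_college", "college_plus"),
    father_edu = c("less_than_hs", "hs_some_college", "college_plus"),
    mother_occ = c("manual_blue_collar", "none_other",
                   "sales_service_admin", "professional_managerial"),
    father_occ = c("manual_blue_collar", "none_other",
                   "sales_service_admin", "professional_managerial"),
    income_q = c("q1", "q2", "q3", "q4", "q5"),
    sibship = c("none", "s1_2", "s3_5", "s6_20")
  )
}

sibship_category <- function(n) {
  ifelse(is.na(n), NA_character_,
    ifelse(n == 0, "none",
      ifelse(n <= 2, "s1_2",
        ifelse(n <= 5, "s3_5", "s6_20"))))
}

# reference-coded indicator block with an always-present missing level
encode_block <- function(values, levels, prefix) {
  known <- levels
  bad <- !is.na(values) & !values %in% known
  if (any(bad))
    stop("unknown category label(s) in `", prefix, "`: ",
         paste(unique(values[bad]), collapse = ", "), call. = FALSE)
  out <- list()
  for (lv in levels[-1])            # reference level carries no column
    out[[paste0(prefix, "_", lv)]] <-
      as.numeric(!is.na(values) & values == lv)
  out[[paste0(prefix, "_missing")]] <- as.numeric(is.na(values))
  as.data.frame(out)
}

#' Build the SES design matrix with explicit missing-category coding
#'
#' Converts the documented cohort columns into reference-coded indicator
#' blocks (mother's/father's education with reference "less than high
#' school", mother's/father's occupation collapsed to the 5-class scheme
#' with reference "manual or blue collar", income quintile with reference
#' the bottom quintile, sibship-size category with reference "no
#' sibling") plus a two-biological-parent flag. Every block always emits
#' its `_missing` column — all-zero when nothing is missing — so the
#' design schema is stable, and missing values never drop rows.
#' Demographic covariates (age, female, nativity, home language,
#' ethnicity flag, in-school) are carried through, and the continuous
#' neighborhood-disadvantage score is computed per wave from the six
#' tract measures (or merged from a supplied [neighborhood_index()]
#' result). SES indicators are wave-matched: each person-wave row uses
#' that wave's values.
#'
#' @param cohort Cohort data frame in the documented long format.
#' @param lookup Occupation lookup, see [occupation_lookup()].
#' @param neighborhood Optional data frame `tract_id, wave,
#'   nbhd_disadvantage`; computed from the cohort's `nbhd_*` columns when
#'   absent and available.
#' @return Data frame (class `gn_design`) with identifiers, `pvt_score`,
#'   demographics, indicator columns, and `nbhd_disadvantage`.
#' @export
encode_categoricals <- function(cohort, lookup = occupation_lookup(),
                                neighborhood = NULL) {
  blocks <- ses_block_levels()
  out <- cohort[, intersect(c("person_id", "family_id", "tract_id",
                              "sibship_type", "stratum", "wave",
                              "pvt_score", "age"), names(cohort)),
                drop = FALSE]
  if ("sex" %in% names(cohort))
    out$female <- as.numeric(cohort$sex == "female")
  for (v in intersect(c("us_born", "english_home", "hispanic", "in_school"),
                      names(cohort)))
    out[[v]] <- cohort[[v]]

  for (b in c("mother_edu", "father_edu"))
    out <- cbind(out, encode_block(cohort[[b]], blocks[[b]], b))

  collapse_occ <- function(detail, col) {
    idx <- match(detail, lookup$occ_detail)
    bad <- !is.na(detail) & is.na(idx)
    if (any(bad))
      stop("unknown category label(s) in `", col, "`: ",
           paste(unique(detail[bad]), collapse = ", "), call. = FALSE)
    lookup$class5[idx]
  }
  for (b in c("mother_occ", "father_occ"))
    out <- cbind(out, encode_block(collapse_occ(cohort[[b]], b),
                                   blocks[[b]], b))

  out <- cbind(out, encode_block(cohort$income_q, blocks$income_q,
                                 "income_q"))
  out$two_bio_parents <- as.numeric(!is.na(cohort$two_bio_parents) &
                                      cohort$two_bio_parents == 1)
  out$two_bio_missing <- as.numeric(is.na(cohort$two_bio_parents))
  out <- cbind(out, encode_block(sibship_category(cohort$sibship_size),
                                 blocks$sibship, "sibship"))

  nb_cols <- c("nbhd_poverty", "nbhd_unemployed", "nbhd_female_headed",
               "nbhd_no_diploma", "nbhd_college", "nbhd_managerial")
  if (is.null(neighborhood) && all(nb_cols %in% names(cohort)) &&
      "tract_id" %in% names(cohort)) {
    panel <- unique(cohort[, c("tract_id", "wave", nb_cols)])
    neighborhood <- neighborhood_index(panel)
  }
  if (!is.null(neighborhood)) {
    key <- paste(cohort$tract_id, cohort$wave)
    nkey <- paste(neighborhood$tract_id, neighborhood$wave)
    out$nbhd_disadvantage <- neighborhood$nbhd_disadvantage[match(key, nkey)]
  }
  class(out) <- c("gn_design", "data.frame")
  out
}

#' Neighborhood-disadvantage index
#'
#' First principal component of the six column-standardized tract
#' measures (share of households below poverty, unemployed adults,
#' female-headed households, adults without a high-school diploma,
#' residents with a college degree, workers in managerial or professional
#' jobs), computed separately per wave. The component is oriented so the
#' poverty measure loads positively (higher score = more disadvantaged)
#' and the per-wave output is standardized to mean 0, sd 1. Because the
#' inputs are standardized first, the index is invariant to affine
#' rescaling of any input measure.
#'
#' @param panel Data frame with `tract_id`, `wave`, and the six
#'   `nbhd_*` measure columns.
#' @return Data frame `tract_id, wave, nbhd_disadvantage`.
#' @export
neighborhood_index <- function(panel) {
  nb_cols <- c("nbhd_poverty", "nbhd_unemployed", "nbhd_female_headed",
               "nbhd_no_diploma", "nbhd_college", "nbhd_managerial")
  stopifnot(all(c("tract_id", "wave", nb_cols) %in% names(panel)))
  out <- panel[, c("tract_id", "wave")]
  out$nbhd_disadvantage <- NA_real_
  for (w in unique(panel$wave)) {
    i <- panel$wave == w
    if (sum(i) < 2)
      stop("need at least 2 tracts per wave", call. = FALSE)
    X <- as.matrix(panel[i, nb_cols])
    sds <- apply(X, 2, sd)
    if (all(sds == 0))
      stop("zero variance in all six neighborhood measures", call. = FALSE)
    keep <- sds > 0
    Z <- scale(X[, keep, drop = FALSE])
    pc <- prcomp(Z, center = FALSE, scale. = FALSE, rank. = 1)
    score <- pc$x[, 1]
    pov <- which(colnames(Z) == "nbhd_poverty")
    orient <- if (length(pov)) sign(pc$rotation[pov, 1]) else
      sign(pc$rotation[which.max(abs(pc$rotation[, 1])), 1])
    if (orient < 0) score <- -score
    out$nbhd_disadvantage[i] <- as.numeric(scale(score))
  }
  out
}

#' SES summary score (first principal component)
#'
#' Collapses the SES block into a single standardized score: the first
#' principal component of the standardized ordinal/continuous SES inputs
#' (mother's and father's education on a 1-3 scale, income quintile 1-5,
#' mother's and father's occupational prestige on the 11-level scale via
#' the packaged lookup, sibship size, the two-biological-parent flag, and
#' the wave-1 neighborhood-disadvantage index). Missing values are
#' mean-substituted within stratum before the PCA, so no person is
#' dropped. The component is oriented so parental education loads
#' positively, and the output has mean 0, sd 1.
#'
#' @param cohort Cohort data frame (long format).
#' @param neighborhood Optional [neighborhood_index()] output; computed
#'   from the cohort's tract columns when absent.
#' @param lookup Occupation lookup, see [occupation_lookup()].
#' @param strata Optional person-level stratum labels for the
#'   mean-substitution (default: the cohort `stratum` column, else one
#'   stratum).
#' @return Data frame `person_id, ses_pc` (one row per person).
#' @export
ses_summary_pc <- function(cohort, neighborhood = NULL,
                           lookup = occupation_lookup(), strata = NULL) {
  persons <- cohort[cohort$wave == min(cohort$wave), , drop = FALSE]
  persons <- persons[!duplicated(persons$person_id), , drop = FALSE]

  ord3 <- c(less_than_hs = 1, hs_some_college = 2, college_plus = 3)
  prestige <- function(detail) lookup$prestige11[match(detail,
                                                       lookup$occ_detail)]
  nb <- NULL
  nb_cols <- c("nbhd_poverty", "nbhd_unemployed", "nbhd_female_headed",
               "nbhd_no_diploma", "nbhd_college", "nbhd_managerial")
  if (is.null(neighborhood) && all(nb_cols %in% names(cohort))) {
    panel <- unique(cohort[, c("tract_id", "wave", nb_cols)])
    neighborhood <- neighborhood_index(panel)
  }
  if (!is.null(neighborhood)) {
    w1 <- neighborhood[neighborhood$wave == min(neighborhood$wave), ]
    nb <- w1$nbhd_disadvantage[match(persons$tract_id, w1$tract_id)]
  }

  X <- cbind(
    mother_edu = unname(ord3[persons$mother_edu]),
    father_edu = unname(ord3[persons$father_edu]),
    income = as.numeric(sub("^q", "", persons$income_q)),
    mother_prestige = prestige(persons$mother_occ),
    father_prestige = prestige(persons$father_occ),
    sibship_size = suppressWarnings(as.numeric(persons$sibship_size)),
    two_bio = suppressWarnings(as.numeric(persons$two_bio_parents)))
  if (!is.null(nb)) X <- cbind(X, nbhd = -nb)  # advantage direction

  complete_per_person <- rowSums(!is.na(X))
  if (any(complete_per_person < 2))
    stop("fewer than 2 complete SES indicators for some person(s)",
         call. = FALSE)

  if (is.null(strata))
    strata <- if ("stratum" %in% names(persons)) persons$stratum else
      rep(1L, nrow(persons))
  for (j in seq_len(ncol(X))) {
    if (anyNA(X[, j])) {
      m <- ave(X[, j], strata, FUN = function(v) mean(v, na.rm = TRUE))
      X[is.na(X[, j]), j] <- m[is.na(X[, j])]
    }
  }
  sds <- apply(X, 2, sd)
  Z <- scale(X[, sds > 0, drop = FALSE])
  pc <- prcomp(Z, center = FALSE, scale. = FALSE, rank. = 1)
  score <- pc$x[, 1]
  edu <- which(colnames(Z) %in% c("mother_edu", "father_edu"))
  if (length(edu) && sum(pc$rotation[edu, 1]) < 0) score <- -score
  data.frame(person_id = persons$person_id,
             ses_pc = as.numeric(scale(score)),
             stringsAsFactors = FALSE)
}
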