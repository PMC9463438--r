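# Full-precision text writers: doubles serialized with %.17g so a
# read-back reproduces the in-memory values exactly.
format_precise <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      x <- df[[j]]
      out <- sprintf("%.17g", x)
      out[is.na(x)] <- NA_character_
      df[[j]] <- out
    }
  }
  df
}

write_csv_precise <- function(df, path) {
  write.table(format_precise(df), path, sep = ",", row.names = FALSE,
              quote = FALSE, na = "NA")
}

#' Write a simulated study to disk as plain-text artifacts
#'
#' Emits `cohort.csv` (long person-wave table), `genotypes.raw` (PLINK
#' `.raw` dialect: header `FID IID PAT MAT SEX PHENOTYPE` followed by one
#' `SNP_effectallele` dosage column per SNP), `weights.tsv` and
#' `weights_iq.tsv` (3-column tab-delimited GWAS weight files),
#' `truth_persons.csv` / `truth_waves.csv`, and `params.json`. Numeric
#' columns are written at full double precision so [read_cohort()]
#' reproduces the in-memory objects exactly.
#'
#' @param sim A `gn_sim` object from [simulate_cohort()] (or a list with
#'   compatible `cohort`, `trios`, `truth`, `weights` elements).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             raw = file.path(dir, "genotypes.raw"),
             weights = file.path(dir, "weights.tsv"),
             weights_iq = file.path(dir, "weights_iq.tsv"),
             truth_persons = file.path(dir, "truth_persons.csv"),
             truth_waves = file.path(dir, "truth_waves.csv"),
             params = file.path(dir, "params.json"))

  write_csv_precise(sim$cohort, paths["cohort"])

  # .raw: one row per person, from the wave-deduplicated cohort.
  persons <- sim$cohort[!duplicated(sim$cohort$person_id), , drop = FALSE]
  dos <- sim$trios$dosage
  if (!is.null(dos)) {
    dos <- dos[match(persons$person_id, rownames(dos)), , drop = FALSE]
  } else {
    dos <- matrix(numeric(0), nrow = nrow(persons), ncol = 0)
  }
  sex_code <- if (nrow(persons)) ifelse(persons$sex == "female", 2L, 1L)
    else integer(0)
  raw <- data.frame(FID = persons$family_id, IID = persons$person_id,
                    PAT = rep(0L, nrow(persons)),
                    MAT = rep(0L, nrow(persons)),
                    SEX = sex_code,
                    PHENOTYPE = rep(-9L, nrow(persons)),
                    stringsAsFactors = FALSE)
  if (ncol(dos)) {
    dosdf <- as.data.frame(dos, stringsAsFactors = FALSE)
    names(dosdf) <- paste0(sim$trios$snp_id, "_", sim$trios$effect_allele)
    raw <- cbind(raw, dosdf)
  } else if (length(sim$trios$snp_id)) {
    for (nm in paste0(sim$trios$snp_id, "_", sim$trios$effect_allele))
      raw[[nm]] <- numeric(nrow(persons))
  }
  write.table(format_precise(raw), paths["raw"], sep = " ",
              row.names = FALSE, quote = FALSE, na = "NA")

  write.table(format_precise(sim$weights), paths["weights"], sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (!is.null(sim$weights_iq))
    write.table(format_precise(sim$weights_iq), paths["weights_iq"],
                sep = "\t", row.names = FALSE, quote = FALSE)
  write_csv_precise(sim$truth$persons, paths["truth_persons"])
  write_csv_precise(sim$truth$waves, paths["truth_waves"])

  par <- sim$truth$params
  par$config <- unclass(par$config)
  par$allele_freq <- NULL    # matrix; regenerable from config seed
  par$allele_freq_ancestral <- NULL
  jsonlite::write_json(par, paths["params"], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}

#' Read back a study written by [write_cohort()]
#'
#' @param dir Directory containing the artifacts.
#' @return A list with `cohort`, `dosages` (a `gn_dosage` object, see
#'   [read_dosages()]), `weights`, `weights_iq` (if present), `truth`
#'   (persons/waves data frames plus parameters).
#' @export
read_cohort <- function(dir) {
  cohort <- read.table(file.path(dir, "cohort.csv"), header = TRUE,
                       sep = ",", stringsAsFactors = FALSE)
  weights <- read_weights(file.path(dir, "weights.tsv"))
  iq_path <- file.path(dir, "weights_iq.tsv")
  weights_iq <- if (file.exists(iq_path)) read_weights(iq_path) else NULL
  dosages <- read_dosages(file.path(dir, "genotypes.raw"), weights)
  truth <- list(
    persons = read.table(file.path(dir, "truth_persons.csv"), header = TRUE,
                         sep = ",", stringsAsFactors = FALSE),
    waves = read.table(file.path(dir, "truth_waves.csv"), header = TRUE,
                       sep = ",", stringsAsFactors = FALSE),
    params = jsonlite::read_json(file.path(dir, "params.json"),
                                 simplifyVector = TRUE))
  list(cohort = cohort, dosages = dosages, weights = weights,
       weights_iq = weights_iq, truth = truth)
}
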