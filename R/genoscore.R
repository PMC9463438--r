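#' Read a GWAS weight file
#'
#' Weight files are tab-delimited with a header and three columns:
#' `snp_id`, `effect_allele` (one of A/C/G/T), `beta` (the per-allele
#' weight applied to the counted effect allele). Row order is preserved.
#'
#' @param path Path to the TSV file.
#' @return A data frame with one record per SNP (class `gn_weights`).
#' @export
read_weights <- function(path) {
  raw <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("snp_id", "effect_allele", "beta")
  if (!all(need %in% names(raw)))
    stop("weight file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  w <- raw[, need]
  dup <- w$snp_id[duplicated(w$snp_id)]
  if (length(dup))
    stop("duplicated snp_id in weight file: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  bad_allele <- !w$effect_allele %in% c("A", "C", "G", "T")
  if (any(bad_allele))
    stop("non-ACGT effect allele at line(s) ",
         paste(which(bad_allele) + 1L, collapse = ", "), call. = FALSE)
  beta <- suppressWarnings(as.numeric(w$beta))
  bad_beta <- is.na(beta) | !is.finite(beta)
  if (any(bad_beta))
    stop("unparseable beta at line(s) ",
         paste(which(bad_beta) + 1L, collapse = ", "), ": ",
         paste(w$beta[bad_beta], collapse = ", "), call. = FALSE)
  w$beta <- beta
  class(w) <- c("gn_weights", "data.frame")
  w
}

dna_complement <- c(A = "T", T = "A", C = "G", G = "C")

#' Read genotype dosages and align them to a weight file
#'
#' Accepts the PLINK `.raw` dialect (header `FID IID PAT MAT SEX
#' PHENOTYPE`, then one `SNP_countedallele` column per SNP) or a plain
#' table whose first column is a person id followed by `SNP_allele`
#' columns. Columns are reordered to match the weight file. When the
#' counted allele differs from the weight file's effect allele the dosage
#' is reflected (`d -> 2 - d`) so scoring always counts the effect
#' allele; if counted and effect allele are strand complements (A/T or
#' C/G) the reflection is applied but flagged with a warning, since
#' strand ambiguity cannot be resolved from a dosage file. Missing
#' entries are imputed to `2p`, twice the observed effect-allele
#' frequency at that SNP.
#'
#' @param path Path to the dosage file.
#' @param weights A `gn_weights` table from [read_weights()].
#' @return An object of class `gn_dosage`: list with `ids`, `snp_id`,
#'   `effect_allele`, and the numeric `dosage` matrix (persons x SNPs,
#'   values in \[0, 2\]).
#' @export
read_dosages <- function(path, weights) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  plink_meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (all(plink_meta %in% names(tab)[seq_len(min(6, ncol(tab)))])) {
    ids <- as.character(tab$IID)
    geno <- tab[, setdiff(names(tab), plink_meta), drop = FALSE]
  } else {
    ids <- as.character(tab[[1]])
    geno <- tab[, -1, drop = FALSE]
  }
  cols <- names(geno)
  snp <- sub("_[ACGT]$", "", cols)
  counted <- sub("^.*_", "", cols)

  missing_snps <- setdiff(weights$snp_id, snp)
  if (length(missing_snps))
    stop("SNP(s) in weight file absent from dosage file: ",
         paste(missing_snps, collapse = ", "), call. = FALSE)
  sel <- match(weights$snp_id, snp)
  dos <- as.matrix(geno[, sel, drop = FALSE])
  storage.mode(dos) <- "double"
  counted <- counted[sel]

  rng <- range(dos, na.rm = TRUE)
  if (nrow(dos) && ncol(dos) && is.finite(rng[1]) &&
      (rng[1] < 0 || rng[2] > 2))
    stop("dosage values outside [0, 2]", call. = FALSE)

  flip <- counted != weights$effect_allele
  ambiguous <- flip & counted == unname(dna_complement[weights$effect_allele])
  if (any(ambiguous))
    warning("strand-ambiguous allele pair(s) at: ",
            paste(weights$snp_id[ambiguous], collapse = ", "),
            "; counted allele treated as the complement-strand ",
            "non-effect allele", call. = FALSE)
  if (any(flip)) dos[, flip] <- 2 - dos[, flip, drop = FALSE]

  # 2p imputation for missing entries (PLINK-style mean imputation).
  if (anyNA(dos)) {
    for (j in which(colSums(is.na(dos)) > 0)) {
      obs <- dos[, j]
      fill <- mean(obs, na.rm = TRUE)
      if (is.nan(fill)) fill <- 1   # no observed entries: p = 0.5
      dos[is.na(obs), j] <- fill
    }
  }
  colnames(dos) <- weights$snp_id
  rownames(dos) <- ids
  structure(list(ids = ids, snp_id = weights$snp_id,
                 effect_allele = weights$effect_allele, dosage = dos),
            class = "gn_dosage")
}

#' @export
print.gn_dosage <- function(x, ...) {
  cat("Dosage matrix:", length(x$ids), "persons x", length(x$snp_id),
      "SNPs (effect-allele counted)\n")
  invisible(x)
}

as_dosage_matrix <- function(dosages) {
  if (inherits(dosages, "gn_dosage")) dosages$dosage
  else as.matrix(dosages)
}

#' Compute raw polygenic scores
#'
#' The score of person i is the weighted sum of effect-allele dosages,
#' `PGS_i = sum_j beta_j X_ij`, over all SNPs in the weight file (no
#' p-value thresholding or clumping).
#'
#' @param weights A `gn_weights` table.
#' @param dosages A `gn_dosage` object (or a plain persons x SNPs matrix
#'   whose columns match `weights$snp_id`).
#' @return Data frame with `person_id` and `pgs_raw`.
#' @export
#' @examples
#' w <- data.frame(snp_id = c("s1", "s2"), effect_allele = c("A", "C"),
#'                 beta = c(0.5, -0.2))
#' compute_pgs(w, matrix(c(2, 1), 1, dimnames = list("p1", c("s1", "s2"))))
compute_pgs <- function(weights, dosages) {
  if (nrow(weights) == 0) stop("empty weight set", call. = FALSE)
  dos <- as_dosage_matrix(dosages)
  if (!identical(colnames(dos), weights$snp_id)) {
    if (!all(weights$snp_id %in% colnames(dos)))
      stop("dosage matrix lacks SNPs present in weights", call. = FALSE)
    dos <- dos[, weights$snp_id, drop = FALSE]
  }
  data.frame(person_id = rownames(dos) %||% as.character(seq_len(nrow(dos))),
             pgs_raw = as.numeric(dos %*% weights$beta),
             stringsAsFactors = FALSE)
}

#' Standardize polygenic scores within strata
#'
#' Z-standardizes the raw score within each stratum with that stratum's
#' own mean and sample standard deviation (n - 1 denominator), so a
#' regression coefficient on the result reads as the effect of one
#' standard deviation of the score. Standardization within ancestry
#' strata (or within the combined sample via a single stratum) mirrors
#' standard practice for ancestry-specific score scales.
#'
#' @param scores Data frame from [compute_pgs()].
#' @param strata Optional vector of stratum labels aligned with
#'   `scores$person_id` (default: one stratum).
#' @return `scores` with added `pgs_z` and `stratum` columns.
#' @export
standardize_pgs <- function(scores, strata = NULL) {
  if (is.null(strata)) strata <- rep("all", nrow(scores))
  stopifnot(length(strata) == nrow(scores))
  z <- numeric(nrow(scores))
  for (s in unique(strata)) {
    i <- strata == s
    if (sum(i) < 2)
      stop("stratum '", s, "' has fewer than 2 persons", call. = FALSE)
    sdev <- sd(scores$pgs_raw[i])
    if (sdev == 0)
      stop("zero within-stratum score variance in stratum '", s, "'",
           call. = FALSE)
    z[i] <- (scores$pgs_raw[i] - mean(scores$pgs_raw[i])) / sdev
  }
  scores$pgs_z <- z
  scores$stratum <- strata
  scores
}

#' Ancestry principal components of the dosage matrix
#'
#' Computes the top-k principal components of the column-standardized
#' dosage matrix, the usual covariates for absorbing population
#' stratification in genetic association models. Monomorphic SNPs are
#' dropped before standardization. Each component's sign is fixed by the
#' rule that its largest-magnitude SNP loading is positive.
#'
#' @param dosages A `gn_dosage` object or persons x SNPs matrix.
#' @param k Number of components (default 10, the "ten or so" convention;
#'   capped at `min(persons - 1, polymorphic SNPs)`).
#' @return List with `scores` (persons x k matrix, columns `PC1..PCk`),
#'   `loadings`, and `sdev`.
#' @export
genotype_pcs <- function(dosages, k = 10) {
  dos <- as_dosage_matrix(dosages)
  v <- apply(dos, 2, var)
  poly <- v > 0
  if (!any(poly)) stop("all SNPs are monomorphic", call. = FALSE)
  X <- scale(dos[, poly, drop = FALSE])
  k <- min(k, ncol(X), nrow(X) - 1L)
  pc <- prcomp(X, center = FALSE, scale. = FALSE, rank. = k)
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))]) < 0
  }, logical(1))
  pc$rotation[, flip] <- -pc$rotation[, flip, drop = FALSE]
  pc$x[, flip] <- -pc$x[, flip, drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(dos)
  list(scores = scores, loadings = pc$rotation[, seq_len(k), drop = FALSE],
       sdev = pc$sdev[seq_len(k)])
}
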