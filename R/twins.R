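#' Falconer twin heritability
#'
#' The classical estimator `h^2 = 2 (r_MZ - r_DZ)` from monozygotic and
#' dizygotic within-pair correlations, truncated to \[0, 1\]. A purely
#' descriptive quantity here.
#'
#' @param r_mz,r_dz Within-pair correlations in \[-1, 1\].
#' @param n_mz_pairs,n_dz_pairs Optional pair counts carried through for
#'   reporting.
#' @return Object of class `gn_twin` with `h2`, `r_mz`, `r_dz` and the
#'   pair counts.
#' @export
#' @examples
#' falconer_h2(0.50, 0.31)$h2   # 0.38
falconer_h2 <- function(r_mz, r_dz, n_mz_pairs = NA_integer_,
                        n_dz_pairs = NA_integer_) {
  if (abs(r_mz) > 1 || abs(r_dz) > 1)
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  h2 <- min(max(2 * (r_mz - r_dz), 0), 1)
  structure(list(h2 = h2, r_mz = r_mz, r_dz = r_dz,
                 n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs),
            class = "gn_twin")
}

#' @export
print.gn_twin <- function(x, ...) {
  cat(sprintf("Twin summary: r_MZ = %.3f (%s pairs), r_DZ = %.3f (%s pairs)\n",
              x$r_mz, x$n_mz_pairs, x$r_dz, x$n_dz_pairs))
  cat(sprintf("Falconer heritability 2(r_MZ - r_DZ), truncated: %.3f\n",
              x$h2))
  invisible(x)
}

#' Twin correlations and heritability from a cohort
#'
#' Standardizes the response within wave, averages it per person, forms
#' MZ and DZ twin pairs by family, and computes double-entry Pearson
#' within-pair correlations (each pair enters as both (a, b) and (b, a),
#' making the correlation symmetric in twin order). At least 2 pairs of
#' each type are required.
#'
#' @param cohort Long cohort data frame with `sibship_type` in
#'   `{"mz", "dz", ...}`.
#' @param response Response column name.
#' @return A `gn_twin` object, see [falconer_h2()].
#' @export
twin_summary <- function(cohort, response = "pvt_score") {
  z <- ave(cohort[[response]], cohort$wave,
           FUN = function(v) (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE))
  score <- tapply(z, cohort$person_id, function(v) mean(v, na.rm = TRUE))
  first <- cohort[!duplicated(cohort$person_id), , drop = FALSE]
  first <- first[match(names(score), first$person_id), , drop = FALSE]

  pair_r <- function(type) {
    d <- first[first$sibship_type == type, , drop = FALSE]
    s <- score[d$person_id]
    fams <- split(seq_len(nrow(d)), d$family_id)
    fams <- fams[vapply(fams, length, 1L) == 2L]
    if (length(fams) < 2)
      stop("need at least 2 ", type, " pairs", call. = FALSE)
    a <- vapply(fams, function(i) s[i[1]], numeric(1))
    b <- vapply(fams, function(i) s[i[2]], numeric(1))
    list(r = cor(c(a, b), c(b, a)), n = length(fams))
  }
  mz <- pair_r("mz")
  dz <- pair_r("dz")
  falconer_h2(mz$r, dz$r, n_mz_pairs = mz$n, n_dz_pairs = dz$n)
}
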