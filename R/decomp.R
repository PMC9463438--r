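infer_scale <- function(values, what = "R-squared") {
  scales <- ifelse(abs(values) > 1, "percent", "proportion")
  if (length(unique(scales)) > 1)
    stop("mixed ", what, " scales (percent vs proportion) in inputs: ",
         paste(format(values), collapse = ", "), call. = FALSE)
  scales[1]
}

#' Percent reduction of a coefficient between nested models
#'
#' `100 * (effect_without - effect_with) / effect_without`,
#' sign-preserving: the percentage of a predictor's "nominal" effect that
#' disappears once the competing block (PGS terms for an SES coefficient,
#' SES terms for a PGS coefficient) enters the model. Under
#' parental-genome confounding this reduction estimates one half of the
#' genomic component carried by the coefficient.
#'
#' @param effect_without Estimate from the model without the competing
#'   block (must be nonzero).
#' @param effect_with Estimate from the model including it.
#' @return Percent reduction (vectorized).
#' @export
#' @examples
#' coefficient_reduction(0.44, 0.41)   # 6.8% (ability-PGS example)
coefficient_reduction <- function(effect_without, effect_with) {
  if (any(effect_without == 0))
    stop("zero baseline effect; percent reduction undefined", call. = FALSE)
  100 * (effect_without - effect_with) / effect_without
}

#' Environmental-SES correction (the x2 rule)
#'
#' Corrects a parental-SES coefficient for its parental-genome component:
#' `enviSES = ParentalSES - 2 * ReducedSES`, where `ReducedSES` is the
#' amount by which the SES coefficient shrinks when the offspring
#' polygenic scores are added. Because a child inherits half of each
#' parent's alleles, conditioning on the offspring genome removes about
#' half of the genomic component in the SES coefficient; doubling the
#' observed reduction estimates the whole of it. The implied genomic
#' share `2 * ReducedSES / ParentalSES` is reported alongside.
#'
#' @param parental_ses_effect SES estimate from the model without PGSs.
#' @param reduced_amount `parental_ses_effect` minus the SES estimate
#'   with PGSs included (same scale).
#' @return List with `envses`, `genomic_share_pct`, and the inputs.
#' @export
#' @examples
#' envses_correction(10, 1.5)   # enviSES 7, genomic share 30%
envses_correction <- function(parental_ses_effect, reduced_amount) {
  list(envses = parental_ses_effect - 2 * reduced_amount,
       genomic_share_pct = 100 * 2 * reduced_amount / parental_ses_effect,
       parental_ses_effect = parental_ses_effect,
       reduced_amount = reduced_amount)
}

#' Incremental R-squared between nested designs
#'
#' @param r2_larger_model,r2_smaller_model R-squared of the larger and of
#'   the nested smaller design on identical data, both on the same scale
#'   (percent or proportion; inferred and preserved).
#' @return The difference, on the input scale.
#' @export
#' @examples
#' incremental_r2(21.9, 20.4)   # 1.5 (percent scale)
incremental_r2 <- function(r2_larger_model, r2_smaller_model) {
  infer_scale(c(r2_larger_model, r2_smaller_model))
  d <- r2_larger_model - r2_smaller_model
  if (d < -1e-12)
    stop("nesting violation: the larger model's R-squared is smaller ",
         "than the nested model's", call. = FALSE)
  d
}

as_r2 <- function(x, name) {
  if (inherits(x, "gn_lmm")) return(x$ols_r2)
  if (is.numeric(x) && length(x) == 1) return(as.numeric(x))
  stop("`", name, "` must be a gn_lmm fit or a single R-squared value",
       call. = FALSE)
}

#' Incremental R-squared decomposition ledger
#'
#' Partitions the explanatory power of a full model (SES + polygenic
#' scores + ancestry PCs) into three pieces:
#' \itemize{
#'   \item `net_pgs_r2 = R2_full - R2_ses_pc`: offspring genome above and
#'     beyond SES (net of population stratification);
#'   \item `ses_incremental_r2 = R2_full - R2_pgs_pc`: parental SES above
#'     and beyond offspring genome — but still containing about half of
#'     the genomic component in parental SES;
#'   \item the genomic component in parental SES, unobservable without
#'     parental genotypes, bounded above by the net-PGS increment (the
#'     offspring genome's own increment; transmitted-allele effects are
#'     empirically larger than non-transmitted ones, so the genomic-in-SES
#'     contribution cannot exceed it). The default
#'     `genomic_in_ses_bound = net_pgs_r2` implements that rule and can
#'     be overridden.
#' }
#' The environmental-SES contribution is then
#' `env_ses_r2 = ses_incremental_r2 - genomic_in_ses_bound` and the total
#' genomic contribution `total_genomic_r2 = net_pgs_r2 +
#' genomic_in_ses_bound`. These identities hold exactly by construction.
#'
#' Optionally a coefficient-reduction table is computed from a pair of
#' fits sharing terms (per non-reference indicator level, never pooled),
#' with the enviSES correction applied to each SES term.
#'
#' @param fit_full,fit_ses_pc,fit_pgs_pc `gn_lmm` fits (their companion
#'   OLS R-squared is used) or bare R-squared values, all on one scale.
#' @param reductions Optional named list of pairs for the reduction
#'   table: each element is `list(without = fit-or-coefs, with =
#'   fit-or-coefs, terms = character())`; coefficient vectors may be
#'   passed directly.
#' @param bound Override for the genomic-in-SES upper bound (same scale
#'   as the R-squared inputs).
#' @return Object of class `gn_ledger`.
#' @export
#' @examples
#' build_ledger(21.9, 20.4, 12.6)   # the percent-scale worked example
build_ledger <- function(fit_full, fit_ses_pc, fit_pgs_pc,
                         reductions = NULL, bound = NULL) {
  r2_full <- as_r2(fit_full, "fit_full")
  r2_ses <- as_r2(fit_ses_pc, "fit_ses_pc")
  r2_pgs <- as_r2(fit_pgs_pc, "fit_pgs_pc")
  scale <- infer_scale(c(r2_full, r2_ses, r2_pgs))

  net_pgs <- incremental_r2(r2_full, r2_ses)
  ses_inc <- incremental_r2(r2_full, r2_pgs)
  bound <- bound %||% net_pgs
  env_ses <- ses_inc - bound

  red_tab <- NULL
  if (!is.null(reductions)) {
    get_coefs <- function(x) if (inherits(x, "gn_lmm")) coef(x) else x
    rows <- lapply(names(reductions), function(nm) {
      spec <- reductions[[nm]]
      cw <- get_coefs(spec$without)
      cf <- get_coefs(spec$with)
      terms <- spec$terms %||% intersect(names(cw), names(cf))
      terms <- setdiff(terms, "(Intercept)")
      data.frame(block = nm, term = terms,
                 effect_without = unname(cw[terms]),
                 effect_with = unname(cf[terms]),
                 reduction_pct = coefficient_reduction(cw[terms], cf[terms]),
                 envses = vapply(terms, function(t)
                   envses_correction(cw[[t]], cw[[t]] - cf[[t]])$envses,
                   numeric(1)),
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    red_tab <- do.call(rbind, rows)
  }

  out <- list(r2_full = r2_full, r2_ses_pc = r2_ses, r2_pgs_pc = r2_pgs,
              net_pgs_r2 = net_pgs, ses_incremental_r2 = ses_inc,
              genomic_in_ses_bound = bound, env_ses_r2 = env_ses,
              total_genomic_r2 = net_pgs + bound,
              scale = scale, reduction_table = red_tab)
  class(out) <- "gn_ledger"
  out
}

#' @export
print.gn_ledger <- function(x, digits = 4, ...) {
  unit <- if (x$scale == "percent") "%" else ""
  f <- function(v) paste0(format(round(v, digits)), unit)
  cat("Incremental R-squared decomposition (", x$scale, " scale)\n",
      sep = "")
  cat("  R2: full ", f(x$r2_full), " | SES+PCs ", f(x$r2_ses_pc),
      " | PGSs+PCs ", f(x$r2_pgs_pc), "\n", sep = "")
  cat("  offspring genome (net PGS):        ", f(x$net_pgs_r2), "\n")
  cat("  genomic component in parental SES: ", f(x$genomic_in_ses_bound),
      " (upper bound)\n", sep = "")
  cat("  environmental parental SES:        ", f(x$env_ses_r2), "\n")
  cat("  -- total genomic:                  ", f(x$total_genomic_r2), "\n")
  cat("  -- total environmental:            ", f(x$env_ses_r2), "\n")
  if (!is.null(x$reduction_table)) {
    cat("Coefficient reductions:\n")
    print(x$reduction_table, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.gn_ledger <- function(x, ...) {
  vals <- c(`net PGS` = x$net_pgs_r2,
            `genomic in SES` = x$genomic_in_ses_bound,
            `environmental SES` = x$env_ses_r2)
  barplot(vals, ylab = paste0("incremental R-squared",
                              if (x$scale == "percent") " (%)" else ""),
          main = "Decomposition of explained variance", ...)
  invisible(x)
}

#' Serialize a ledger (or fit) to JSON
#'
#' Fixed key names; numbers written at full precision so reruns with the
#' same inputs are byte-identical.
#'
#' @param x A `gn_ledger`, `gn_lmm`, `gn_gxe`, `gn_sibfe` or plain list.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(x, path) {
  payload <- if (inherits(x, "gn_lmm")) {
    list(estimates = as.list(x$coefficients), se = as.list(x$se),
         varcomp = as.list(x$varcomp), m2ll = x$m2ll, npar = x$npar,
         n = list(obs = x$n_obs, persons = x$n_persons,
                  families = x$n_families),
         ols_r2 = x$ols_r2, method = x$method)
  } else if (inherits(x, "gn_ledger")) {
    x$reduction_table <- if (!is.null(x$reduction_table))
      x$reduction_table else NULL
    unclass(x)
  } else if (inherits(x, "gn_sibfe")) {
    list(estimates = as.list(x$coefficients), se = as.list(x$se),
         n = list(persons = x$n_persons, families = x$n_families))
  } else if (inherits(x, "gn_gxe")) {
    list(main = jsonlite::fromJSON(write_fit_json_string(x$main)),
         interaction = jsonlite::fromJSON(write_fit_json_string(
           x$interaction)),
         lrt = unclass(x$lrt))
  } else unclass(x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

write_fit_json_string <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_fit_json(x, tmp)
  paste(readLines(tmp), collapse = "\n")
}
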