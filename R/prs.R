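# Polygenic risk scores: PRS = sum_i beta_i * x_i over the sites of a
# weight model, where x_i is the dosage of the effect allele, followed by
# z-score normalization within the analysis cohort. Missing sites are
# skipped (no mean imputation); coverage is reported instead.

#' Orient a dosage to the effect allele of a model site
#'
#' The alternate-allele dosage counts the VCF ALT allele; a model site
#' whose effect allele is the REF allele contributes `2 - dosage`. A site
#' whose effect allele matches neither panel allele is unmatched
#' (NA — excluded and counted, not an error).
#'
#' @param ref,alt panel alleles at the position.
#' @param effect_allele the model's effect allele.
#' @param dosage alternate-allele dosage(s) in \[0,2\].
#' @return oriented dosage(s), or NA if the site is unmatched.
#' @export
match_effect_allele <- function(ref, alt, effect_allele, dosage) {
  if (effect_allele == alt) return(dosage)
  if (effect_allele == ref) return(2 - dosage)
  rep(NA_real_, length(dosage))
}

#' Compute polygenic risk scores for every sample of a panel
#'
#' Raw score per sample: the sum over matched model sites of
#' `beta * oriented dosage`. Sites are matched to panel variants by
#' chromosome + position when the model carries coordinates, else by rsID
#' (panels simulated here carry no rsIDs, so coordinate matching is the
#' norm); strand flips are never attempted. Sites absent from the panel, or
#' whose effect allele matches neither panel allele, are skipped and
#' counted. High-quality sites are those with imputation quality > 0.80.
#'
#' @param panel a [dosage_panel()].
#' @param model a `prs_model` from [read_pgs_scoring_file()].
#' @param quality_threshold high-quality cutoff (default 0.80).
#' @return data.frame with one row per sample: `sample_id`, `model_id`,
#'   `raw`, `n_sites_total`, `n_sites_used`, `n_sites_high_quality`.
#' @export
compute_prs <- function(panel, model, quality_threshold = 0.80) {
  sites <- model$sites
  v <- panel$variants
  pkey <- paste(v$chrom, v$pos, sep = ":")
  skey <- paste(sites$chrom, sites$pos, sep = ":")
  idx <- match(skey, pkey)
  n_total <- nrow(sites)
  raw <- setNames(numeric(length(panel$samples)), panel$samples)
  n_used <- 0L
  n_hq <- 0L
  for (i in seq_len(n_total)) {
    j <- idx[i]
    if (is.na(j)) next
    x <- match_effect_allele(v$ref[j], v$alt[j], sites$effect_allele[i],
                             panel$dosages[j, ])
    if (anyNA(x)) next
    raw <- raw + sites$beta[i] * x
    n_used <- n_used + 1L
    if (!is.na(v$quality[j]) && v$quality[j] > quality_threshold)
      n_hq <- n_hq + 1L
  }
  if (n_used == 0L)
    stop("no model sites matched the panel for model ", model$model_id)
  data.frame(sample_id = panel$samples, model_id = model$model_id,
             raw = unname(raw), n_sites_total = n_total,
             n_sites_used = n_used, n_sites_high_quality = n_hq,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Z-score normalization of raw PRS across a cohort
#'
#' `z = (raw - mean) / sd` with the cohort's sample standard deviation, so
#' the normalized scores have mean 0 and SD 1 within the analysis cohort.
#'
#' @param raw numeric vector of raw scores, length >= 2.
#' @return numeric vector of z-scores.
#' @export
zscore <- function(raw) {
  stopifnot(length(raw) >= 2, all(is.finite(raw)))
  s <- sd(raw)
  if (s == 0) stop("zero standard deviation: z-scores undefined")
  (raw - mean(raw)) / s
}

#' Per-model and pooled imputation coverage of PRS sites
#'
#' For each model (and pooled over models) reports the number of sites,
#' how many were imputed in the panel, how many of those were high
#' quality, and the corresponding percentages at both integer and
#' one-decimal rounding.
#'
#' @param panel a [dosage_panel()].
#' @param models list of `prs_model` objects.
#' @param quality_threshold high-quality cutoff (default 0.80).
#' @return data.frame with one row per model plus a `pooled` row.
#' @export
prs_site_coverage <- function(panel, models, quality_threshold = 0.80) {
  v <- panel$variants
  pkey <- paste(v$chrom, v$pos, sep = ":")
  one <- function(model) {
    sites <- model$sites
    idx <- match(paste(sites$chrom, sites$pos, sep = ":"), pkey)
    imputed <- !is.na(idx)
    hq <- imputed & !is.na(v$quality[idx]) &
      v$quality[idx] > quality_threshold
    data.frame(model_id = model$model_id,
               n_sites = nrow(sites),
               n_imputed = sum(imputed),
               n_high_quality = sum(hq),
               stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, lapply(models, one))
  pooled <- data.frame(model_id = "pooled",
                       n_sites = sum(tab$n_sites),
                       n_imputed = sum(tab$n_imputed),
                       n_high_quality = sum(tab$n_high_quality))
  tab <- rbind(tab, pooled)
  tab$pct_imputed <- round(100 * tab$n_imputed / tab$n_sites, 1)
  tab$pct_imputed_int <- round(100 * tab$n_imputed / tab$n_sites)
  tab$pct_high_quality <- round(100 * tab$n_high_quality /
                                  pmax(tab$n_imputed, 1), 1)
  tab$pct_high_quality_int <- round(100 * tab$n_high_quality /
                                      pmax(tab$n_imputed, 1))
  tab
}
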