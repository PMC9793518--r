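# Paired-panel dosage concordance: aggregate r^2 in MAF bins with
# percentile-bootstrap CIs, stratified by imputation quality and by the
# copy-number state of the variant's containing segment.

#' Default MAF bin edges for concordance reporting
#'
#' Log-spaced edges spanning the imputable MAF range; configurable in
#' [binned_concordance()].
#' @export
DEFAULT_MAF_BINS <- c(0.0005, 0.001, 0.005, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)

#' Aggregate squared Pearson correlation of paired dosages
#'
#' The concordance statistic for one sample: the squared Pearson
#' correlation of its per-variant dosage pairs. Undefined (NA, with a
#' warning) when either vector is constant.
#'
#' @param dosages_a,dosages_b equal-length numeric vectors (length >= 2).
#' @return squared Pearson correlation in \[0,1\], or NA.
#' @export
aggregate_r2 <- function(dosages_a, dosages_b) {
  stopifnot(length(dosages_a) == length(dosages_b), length(dosages_a) >= 2)
  if (var(dosages_a) == 0 || var(dosages_b) == 0) {
    warning("constant dosage vector: r^2 undefined")
    return(NA_real_)
  }
  cor(dosages_a, dosages_b)^2
}

#' Label variants by the copy-number state of their containing segment
#'
#' Segments are 0-based half-open, variant positions 1-based: position p is
#' inside \[start, end) iff start <= p - 1 < end. Variants outside every
#' segment are labeled neutral; segments are classified by
#' [classify_segment()] thresholds (artifact segments label their variants
#' "artifact", which downstream strata exclude).
#'
#' @param panel a [dosage_panel()] or a data.frame with `chrom` and `pos`.
#' @param segments data.frame of segments (chrom, start, end, log2_ratio).
#' @return character vector of states, one per variant.
#' @export
annotate_cn_state <- function(panel, segments) {
  v <- if (inherits(panel, "dosage_panel")) panel$variants else panel
  state <- rep("neutral", nrow(v))
  if (is.null(segments) || nrow(segments) == 0) return(state)
  seg_state <- vapply(segments$log2_ratio, classify_segment, character(1))
  vchrom <- normalize_chrom(v$chrom)
  schrom <- normalize_chrom(segments$chrom)
  for (ch in unique(schrom)) {
    si <- which(schrom == ch)
    vi <- which(vchrom == ch)
    if (!length(vi)) next
    s <- segments[si, ]
    o <- order(s$start)
    s <- s[o, ]
    st <- seg_state[si][o]
    p0 <- v$pos[vi] - 1L            # 0-based variant coordinate
    idx <- findInterval(p0, s$start)
    inside <- idx >= 1 & p0 < s$end[pmax(idx, 1)]
    state[vi[inside]] <- st[idx[inside]]
  }
  state
}

percentile_boot_r2 <- function(a, b, n_boot, conf = 0.95) {
  m <- length(a)
  stats <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    idx <- sample.int(m, m, replace = TRUE)
    va <- var(a[idx]); vb <- var(b[idx])
    stats[i] <- if (va == 0 || vb == 0) NA_real_ else cor(a[idx], b[idx])^2
  }
  alpha <- (1 - conf) / 2
  quantile(stats, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
}

#' MAF-binned dosage concordance between two panels
#'
#' For every sample x MAF bin x stratum cell, computes the aggregate r^2
#' of the paired dosages ([aggregate_r2()]) over the variants in the cell,
#' with a percentile-bootstrap 95% CI (variants resampled with
#' replacement). Cells with fewer than `min_snps` variants are emitted with
#' missing r^2 (the count is still reported). Strata: `all` (every
#' variant), `high_quality` (quality > `quality_threshold` in both panels),
#' and — when `segments` is supplied — `neutral`/`gain`/`loss`
#' (copy-number state of high-quality variants; artifact segments are
#' excluded).
#'
#' @param panel_a,panel_b paired [dosage_panel()]s over the same variants
#'   and samples (typically blood and tissue).
#' @param bins MAF bin edges (default [DEFAULT_MAF_BINS]).
#' @param quality_threshold imputation-quality filter (default 0.80).
#' @param segments optional copy-number segments for CN strata.
#' @param min_snps minimum variants per cell (default 1000).
#' @param n_boot bootstrap iterations (default 1000); 0 skips CIs.
#' @param seed bootstrap seed.
#' @return data.frame with `sample_id`, `maf_lo`, `maf_hi`, `stratum`,
#'   `n_snps`, `r2`, `ci_lo`, `ci_hi`.
#' @export
binned_concordance <- function(panel_a, panel_b, bins = DEFAULT_MAF_BINS,
                               quality_threshold = 0.80, segments = NULL,
                               min_snps = 1000L, n_boot = 1000L, seed = 1L) {
  ka <- variant_keys(panel_a); kb <- variant_keys(panel_b)
  if (length(ka) != length(kb) || any(ka != kb)) {
    off <- head(union(setdiff(ka, kb), setdiff(kb, ka)), 5)
    stop("panels do not share the same variant set; first offenders: ",
         paste(off, collapse = ", "))
  }
  if (!identical(panel_a$samples, panel_b$samples))
    stop("panels do not share the same samples")
  set.seed(seed)
  maf <- panel_a$variants$maf
  bin_idx <- cut(maf, bins, include.lowest = TRUE, right = FALSE)
  hq <- panel_a$variants$quality > quality_threshold &
    panel_b$variants$quality > quality_threshold
  strata <- list(all = rep(TRUE, length(maf)), high_quality = hq)
  if (!is.null(segments)) {
    cn <- annotate_cn_state(panel_b, segments)
    for (st in c("neutral", "gain", "loss"))
      strata[[st]] <- hq & cn == st
  }
  out <- list()
  for (s in seq_along(panel_a$samples)) {
    da <- panel_a$dosages[, s]; db <- panel_b$dosages[, s]
    for (bi in seq_len(length(bins) - 1)) {
      in_bin <- !is.na(bin_idx) & as.integer(bin_idx) == bi
      for (st in names(strata)) {
        sel <- in_bin & strata[[st]]
        n_snps <- sum(sel)
        r2 <- ci <- c(NA_real_, NA_real_)
        r2v <- NA_real_
        if (n_snps >= max(min_snps, 2)) {
          r2v <- suppressWarnings(aggregate_r2(da[sel], db[sel]))
          if (!is.na(r2v) && n_boot > 0)
            ci <- percentile_boot_r2(da[sel], db[sel], n_boot)
        }
        out[[length(out) + 1L]] <- data.frame(
          sample_id = panel_a$samples[s],
          maf_lo = bins[bi], maf_hi = bins[bi + 1], stratum = st,
          n_snps = n_snps, r2 = r2v, ci_lo = ci[1], ci_hi = ci[2],
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Average per-sample binned concordance across samples
#'
#' The aggregate view of a [binned_concordance()] table: mean r^2 per
#' bin x stratum over the samples whose cell passed the `min_snps` rule.
#'
#' @param binned output of [binned_concordance()].
#' @return data.frame with `maf_lo`, `maf_hi`, `stratum`, `n_samples`,
#'   `mean_r2`.
#' @export
summarize_binned_concordance <- function(binned) {
  key <- interaction(binned$maf_lo, binned$stratum, drop = TRUE)
  res <- do.call(rbind, lapply(split(binned, key), function(d) {
    ok <- !is.na(d$r2)
    data.frame(maf_lo = d$maf_lo[1], maf_hi = d$maf_hi[1],
               stratum = d$stratum[1], n_samples = sum(ok),
               mean_r2 = if (any(ok)) mean(d$r2[ok]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  res <- res[order(res$stratum, res$maf_lo), ]
  rownames(res) <- NULL
  res
}

#' Spearman correlation of paired per-sample scores
#'
#' Rank correlation (average ranks for ties) between paired score vectors,
#' e.g. blood vs tissue PRS across individuals, with a Bonferroni-corrected
#' q-value for a stated number of parallel tests.
#'
#' @param scores_a,scores_b paired numeric vectors, n >= 3.
#' @param n_tests_adjustment Bonferroni multiplier for the q-value
#'   (default 1).
#' @return list with `spearman_r`, `p`, `q`, `n`.
#' @export
paired_score_correlation <- function(scores_a, scores_b,
                                     n_tests_adjustment = 1) {
  if (length(scores_a) != length(scores_b) || length(scores_a) < 3)
    stop("need paired vectors of length >= 3")
  ct <- suppressWarnings(cor.test(scores_a, scores_b, method = "spearman"))
  list(spearman_r = unname(ct$estimate), p = ct$p.value,
       q = min(1, ct$p.value * n_tests_adjustment), n = length(scores_a))
}
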