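# HLA allele-string handling and concordance scoring between imputed and
# gold-standard typings at 2- or 4-field resolution. Typings carry no
# phase, so allele pairs are compared as unordered multisets with a
# maximum-matching rule.

#' Parse an HLA allele string
#'
#' @param allele string of form `"GENE*f1:f2[:f3[:f4]]"`; an expression
#'   suffix letter on the last field (N, L, S, C, A, Q) is stripped.
#' @return list with `gene` and character vector `fields` (length 1-4).
#' @export
parse_hla_allele <- function(allele) {
  parts <- strsplit(allele, "*", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !nzchar(parts[1]))
    stop("malformed HLA allele string: ", allele)
  fields <- strsplit(parts[2], ":", fixed = TRUE)[[1]]
  if (length(fields) < 1 || length(fields) > 4)
    stop("HLA allele must carry 1-4 fields: ", allele)
  last <- fields[length(fields)]
  stripped <- sub("[NLSCAQ]$", "", last)
  if (stripped != last) {
    message("stripped expression suffix from ", allele)
    fields[length(fields)] <- stripped
  }
  list(gene = toupper(parts[1]), fields = fields)
}

#' Truncate an HLA allele to a coarser field resolution
#'
#' Removes trailing fields; an allele typed at fewer fields than requested
#' is returned unchanged with a `flagged` attribute (comparison then
#' happens at the coarser available resolution).
#'
#' @param allele allele string.
#' @param n_fields target resolution in \{1, 2, 3, 4\}.
#' @return truncated allele string; attribute `flagged` is TRUE when the
#'   input had fewer fields than requested.
#' @export
truncate_allele <- function(allele, n_fields) {
  stopifnot(n_fields %in% 1:4)
  p <- parse_hla_allele(allele)
  flagged <- length(p$fields) < n_fields
  k <- min(length(p$fields), n_fields)
  out <- paste0(p$gene, "*", paste(p$fields[seq_len(k)], collapse = ":"))
  attr(out, "flagged") <- flagged
  out
}

#' Concordance of two unordered allele pairs for one gene
#'
#' Both pairs are truncated to `n_fields` and compared as unordered pairs:
#' the score is the size of the maximum matching between them (both
#' pairings are evaluated and the larger taken), so a single predicted
#' allele can never match both gold alleles of a heterozygote.
#'
#' @param pred_pair,gold_pair character vectors of length 2.
#' @param n_fields comparison resolution (default 4).
#' @return integer in \{0, 1, 2\}.
#' @export
gene_concordance <- function(pred_pair, gold_pair, n_fields = 4) {
  stopifnot(length(pred_pair) == 2, length(gold_pair) == 2)
  tp <- vapply(pred_pair, function(a) as.character(truncate_allele(a, n_fields)),
               character(1))
  tg <- vapply(gold_pair, function(a) as.character(truncate_allele(a, n_fields)),
               character(1))
  straight <- (tp[1] == tg[1]) + (tp[2] == tg[2])
  crossed <- (tp[1] == tg[2]) + (tp[2] == tg[1])
  as.integer(max(straight, crossed))
}

#' Score concordance for every sample x gene shared by two typing tables
#'
#' @param pred,gold HLA tables (see [read_hla_table()]); genes present in
#'   only one table are excluded and counted in the `n_unpaired` attribute.
#' @param n_fields comparison resolution (default 4).
#' @return data.frame with `sample_id`, `gene`, `class_label`, `n_matched`
#'   (0/1/2) and `posterior` (from `pred`).
#' @export
score_hla_concordance <- function(pred, gold, n_fields = 4) {
  kp <- paste(pred$sample_id, pred$gene)
  kg <- paste(gold$sample_id, gold$gene)
  shared <- intersect(kp, kg)
  n_unpaired <- length(setdiff(union(kp, kg), shared))
  if (n_unpaired > 0)
    message(n_unpaired, " sample-gene record(s) present in only one table; excluded")
  rows <- lapply(shared, function(k) {
    p <- pred[match(k, kp), ]
    g <- gold[match(k, kg), ]
    data.frame(sample_id = p$sample_id, gene = p$gene,
               class_label = unname(HLA_GENE_CLASS[p$gene]),
               n_matched = gene_concordance(c(p$allele1, p$allele2),
                                            c(g$allele1, g$allele2),
                                            n_fields),
               posterior = p$posterior,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_unpaired") <- n_unpaired
  out
}

#' Per-class summary of HLA concordance counts
#'
#' Per class (I = A/B/C, II = DRB1/DQB1): concordant alleles = sum of
#' per-gene matches, total alleles = 2 x genes compared (a homozygous gold
#' pair contributes 2 comparable alleles), percentage to one decimal.
#'
#' @param gene_concordances output of [score_hla_concordance()].
#' @return data.frame with `class_label`, `n_concordant`, `n_total`,
#'   `pct_concordant`.
#' @export
summarize_concordance <- function(gene_concordances) {
  stopifnot(nrow(gene_concordances) >= 1)
  res <- do.call(rbind, lapply(split(gene_concordances,
                                     gene_concordances$class_label),
                               function(d) data.frame(
    class_label = d$class_label[1],
    n_concordant = sum(d$n_matched),
    n_total = 2L * nrow(d),
    stringsAsFactors = FALSE)))
  res$pct_concordant <- round(100 * res$n_concordant / res$n_total, 1)
  rownames(res) <- NULL
  res
}

#' Compare imputation posteriors between concordant and discordant calls
#'
#' Splits gene calls into perfect (both alleles match) vs with-errors and
#' reports group means plus a rank-based two-group comparison (two-sided
#' Wilcoxon rank-sum). With one group empty, only the other group's mean
#' is reported and the test is skipped.
#'
#' @param gene_concordances output of [score_hla_concordance()] with
#'   posteriors present.
#' @return list with `mean_perfect`, `mean_errors`, `n_perfect`,
#'   `n_errors`, `p` (NA when a group is empty).
#' @export
posterior_by_concordance <- function(gene_concordances) {
  d <- gene_concordances[!is.na(gene_concordances$posterior), ]
  perfect <- d$posterior[d$n_matched == 2]
  errors <- d$posterior[d$n_matched < 2]
  p <- if (length(perfect) && length(errors)) {
    suppressWarnings(wilcox.test(perfect, errors)$p.value)
  } else NA_real_
  if (is.nan(p)) p <- 1   # fully tied groups: no separation
  list(mean_perfect = if (length(perfect)) mean(perfect) else NA_real_,
       mean_errors = if (length(errors)) mean(errors) else NA_real_,
       n_perfect = length(perfect), n_errors = length(errors), p = p)
}
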