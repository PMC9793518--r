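# Supporting statistics for the outcome analysis: Fisher's exact test by
# hypergeometric enumeration, case-control incidence weights, Harrell's
# C-index by pairwise enumeration, the Li-Ji effective number of tests,
# and the two-group PRS comparison.

#' Two-sided Fisher exact test for a 2x2 table by enumeration
#'
#' With margins fixed, enumerates every admissible table, computes its
#' hypergeometric probability, and sums the probabilities of all tables no
#' more probable than the observed one (within relative tolerance 1e-7) —
#' the standard two-sided definition.
#'
#' @param a,b,c,d non-negative integer cells, layout `rbind(c(a, b),
#'   c(c, d))`; every margin must be positive.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0)) stop("empty margin in 2x2 table")
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Control weight for incidence-reweighted case-control survival analysis
#'
#' A case-control cohort over-represents events relative to the population
#' incidence at the study horizon. Cases keep weight 1; each sampled
#' control gets weight 1/p where p is the proportion of controls sampled
#' out of the number needed to reflect the target incidence:
#' `controls_needed = n_cases * (1 - incidence) / incidence`,
#' `weight = controls_needed / n_controls_sampled`.
#'
#' @param n_cases number of cases in the analysis set.
#' @param n_controls_sampled number of sampled controls.
#' @param incidence target event proportion at the horizon, in (0, 1)
#'   (e.g. 0.15 for a 15% 10-year incidence).
#' @return list with `controls_needed`, `p`, `control_weight` (warns when
#'   more controls were sampled than needed, i.e. weight < 1).
#' @export
control_weight <- function(n_cases, n_controls_sampled, incidence) {
  stopifnot(n_cases > 0, n_controls_sampled > 0,
            incidence > 0, incidence < 1)
  controls_needed <- n_cases * (1 - incidence) / incidence
  p <- n_controls_sampled / controls_needed
  if (p > 1)
    warning("more controls sampled than needed; control weight < 1")
  list(controls_needed = controls_needed, p = p, control_weight = 1 / p)
}

#' Harrell's concordance index by direct pairwise enumeration
#'
#' Over comparable pairs — the member with the earlier time had the event —
#' the fraction in which the earlier-event member carries the higher
#' linear predictor; predictor ties count 1/2. Pairs are weighted by the
#' product of the members' case weights.
#'
#' @param linear_predictors risk scores (higher = riskier).
#' @param times follow-up times.
#' @param events logical event indicators.
#' @param weights optional case weights (default 1).
#' @return C-index in \[0,1\].
#' @export
harrell_c <- function(linear_predictors, times, events, weights = NULL) {
  n <- length(times)
  stopifnot(n >= 2, length(linear_predictors) == n, length(events) == n)
  events <- as.logical(events)
  if (!any(events)) stop("no events: C-index undefined")
  if (is.null(weights)) weights <- rep(1, n)
  num <- den <- 0
  for (i in which(events)) {
    for (j in seq_len(n)) {
      if (j == i) next
      # pair comparable iff i's event time precedes j's observed time
      if (times[i] < times[j] || (times[i] == times[j] && !events[j])) {
        wij <- weights[i] * weights[j]
        den <- den + wij
        if (linear_predictors[i] > linear_predictors[j]) num <- num + wij
        else if (linear_predictors[i] == linear_predictors[j])
          num <- num + wij / 2
      }
    }
  }
  if (den == 0) stop("no comparable pairs: C-index undefined")
  num / den
}

#' Li-Ji effective number of tests from a score matrix
#'
#' Eigenvalues lambda of the Pearson correlation matrix of the score
#' columns give `m_eff = sum_i [ I(lambda_i >= 1) +
#' (lambda_i - floor(lambda_i)) ]`: k independent columns give m_eff = k,
#' perfectly correlated columns give 1. Bonferroni q-values are
#' `min(1, p * m_eff)`.
#'
#' @param score_matrix numeric matrix, >= 3 rows, >= 2 non-constant
#'   columns (e.g. the per-patient scores of correlated PRS models).
#' @param p_values optional p-values to correct.
#' @return list with `eigenvalues`, `m_eff`, and `q_values` when p-values
#'   were supplied.
#' @export
li_ji_meff <- function(score_matrix, p_values = NULL) {
  score_matrix <- as.matrix(score_matrix)
  stopifnot(ncol(score_matrix) >= 2, nrow(score_matrix) >= 3)
  if (any(apply(score_matrix, 2, sd) == 0))
    stop("constant score column: correlation undefined")
  lambda <- eigen(cor(score_matrix), symmetric = TRUE,
                  only.values = TRUE)$values
  # round before flooring: the integer-part term is discontinuous, and
  # numerically 4 - 1e-15 must count as 4 (perfect correlation -> m_eff 1)
  lambda <- pmax(round(lambda, 9), 0)
  m_eff <- sum((lambda >= 1) + (lambda - floor(lambda)))
  out <- list(eigenvalues = lambda, m_eff = m_eff)
  if (!is.null(p_values)) out$q_values <- pmin(1, p_values * m_eff)
  out
}

#' Compare normalized PRS between event and event-free groups
#'
#' Reports group means, the fold change of group means shifted to a
#' positive scale (mean + offset ratio on normalized scores, with offset
#' chosen so both shifted means are positive — reported as the plain ratio
#' of means when both are already positive), and a two-sided Wilcoxon
#' rank-sum p-value. Groups of size < 2 get means only.
#'
#' @param prs normalized PRS values.
#' @param event_flags logical event indicators.
#' @return list with `mean_event`, `mean_no_event`, `fold_change`
#'   (ratio of shifted means), `p` (NA when a group is too small).
#' @export
prs_group_comparison <- function(prs, event_flags) {
  event_flags <- as.logical(event_flags)
  g1 <- prs[event_flags]; g0 <- prs[!event_flags]
  if (!length(g1) || !length(g0)) stop("both groups must be non-empty")
  m1 <- mean(g1); m0 <- mean(g0)
  offset <- if (min(m1, m0) > 0) 0 else -min(m1, m0, 0) + 1
  fc <- (m1 + offset) / (m0 + offset)
  p <- if (length(g1) >= 2 && length(g0) >= 2) {
    suppressWarnings(wilcox.test(g1, g0)$p.value)
  } else NA_real_
  list(mean_event = m1, mean_no_event = m0, fold_change = fc, p = p,
       n_event = length(g1), n_no_event = length(g0))
}
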