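# Copy-number segment classification, genomic burden, and burden-tertile
# grade imputation. Thresholds are strict inequalities on the log2 copy
# ratio: > 0.3 gain, < -0.3 loss, < -15 artifact (excluded downstream).

#' Classify a copy-number segment from its log2 ratio
#'
#' @param log2_ratio finite numeric scalar (vectorized over inputs of
#'   length > 1 via `vapply` by callers).
#' @return one of `"artifact"` (< -15), `"gain"` (> 0.3), `"loss"`
#'   (< -0.3) or `"neutral"`; the boundary values 0.3 and -0.3 are neutral
#'   (strict inequalities).
#' @export
classify_segment <- function(log2_ratio) {
  if (length(log2_ratio) != 1 || !is.finite(log2_ratio))
    stop("log2_ratio must be a single finite number")
  if (log2_ratio < -15) return("artifact")
  if (log2_ratio > 0.3) return("gain")
  if (log2_ratio < -0.3) return("loss")
  "neutral"
}

#' Genomic copy-number burden of a segment profile
#'
#' Burden is the summed length of gain and loss segments divided by the
#' summed length of all segments. Artifact segments (log2 ratio < -15) are
#' removed before both sums.
#'
#' @param segments data.frame with `chrom`, `start`, `end`, `log2_ratio`
#'   (0-based half-open, non-overlapping).
#' @param sample_id optional label carried into the result.
#' @return list with `sample_id`, `burden`, `total_bp`, `altered_bp`.
#' @export
cn_burden <- function(segments, sample_id = NA_character_) {
  if (is.null(segments) || nrow(segments) == 0)
    stop("empty segment set: burden undefined")
  state <- vapply(segments$log2_ratio, classify_segment, character(1))
  keep <- state != "artifact"
  segments <- segments[keep, , drop = FALSE]
  state <- state[keep]
  if (nrow(segments) == 0) stop("all segments are artifacts: burden undefined")
  len <- segments$end - segments$start
  total_bp <- sum(len)
  altered_bp <- sum(len[state %in% c("gain", "loss")])
  list(sample_id = sample_id, burden = altered_bp / total_bp,
       total_bp = total_bp, altered_bp = altered_bp)
}

#' Impute missing nuclear grade from copy-number burden tertiles
#'
#' Nuclear grade correlates strongly with genomic instability, so patients
#' with missing grade are assigned 1/2/3 according to the bottom/middle/top
#' tertile of the cohort's burden distribution. Tertile cut points use the
#' inclusive linear-interpolation quantile definition
#' (`quantile(type = 7)`); ties at a cut point break toward the lower
#' grade. Observed grades are never overwritten. When all burdens are equal
#' the tertiles are degenerate: every missing grade becomes 2, with a
#' warning.
#'
#' @param cohort data.frame with `patient_id` and `grade` columns.
#' @param burdens named numeric vector of burdens, names = patient ids;
#'   must cover every grade-missing patient, length >= 3.
#' @return the cohort with missing grades filled and a logical
#'   `grade_imputed` column.
#' @export
impute_grade_from_burden <- function(cohort, burdens) {
  if (length(burdens) < 3) stop("need at least 3 burden values for tertiles")
  missing_g <- which(is.na(cohort$grade))
  cohort$grade_imputed <- FALSE
  if (!length(missing_g)) return(cohort)
  need <- cohort$patient_id[missing_g]
  if (!all(need %in% names(burdens)))
    stop("burden missing for patient(s): ",
         paste(setdiff(need, names(burdens)), collapse = ", "))
  cuts <- quantile(burdens, c(1, 2) / 3, type = 7, names = FALSE)
  if (cuts[1] == cuts[2] && diff(range(burdens)) == 0) {
    warning("degenerate burden tertiles (all burdens equal); assigning grade 2")
    cohort$grade[missing_g] <- 2L
  } else {
    b <- burdens[cohort$patient_id[missing_g]]
    cohort$grade[missing_g] <- ifelse(b <= cuts[1], 1L,
                                      ifelse(b <= cuts[2], 2L, 3L))
  }
  cohort$grade_imputed[missing_g] <- TRUE
  cohort
}
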