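# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with the qualitative structure real lc-WGS imputation
# exhibits: dosage error grows as MAF shrinks, as coverage shrinks, and in
# copy-loss regions; imputation quality scores decrease with realized error.
# All generators are deterministic under a seed.

#' Configuration for the dosage simulator
#'
#' @param n_variants number of SNPs.
#' @param n_samples number of individuals.
#' @param maf_shape1,maf_shape2 Beta parameters of the MAF spectrum,
#'   truncated to \[0.0005, 0.5\]. The default (0.2, 1.8) skews strongly
#'   toward rare variants, as a neutral site-frequency spectrum does.
#' @param coverage mean sequencing depth (x); lc-WGS is < 1x.
#' @param error_scale base dosage-noise SD at MAF 0.5, 1x coverage, copy
#'   neutral. 0 gives error-free dosages.
#' @param cn_profile optional per-sample copy-number profiles: a named list
#'   of segment data.frames (as from [simulate_cn_profile()]).
#' @param chrom_lengths toy genome; default 2 chromosomes x 5 Mb.
#' @param seed integer seed.
#' @return a `dosage_sim_config` list.
#' @export
dosage_sim_config <- function(n_variants = 1000L, n_samples = 4L,
                              maf_shape1 = 0.2, maf_shape2 = 1.8,
                              coverage = 0.7, error_scale = 0.15,
                              cn_profile = NULL,
                              chrom_lengths = c(`1` = 5e6, `2` = 5e6),
                              seed = 1L) {
  stopifnot(n_variants >= 1, n_samples >= 1, coverage > 0, error_scale >= 0)
  structure(list(n_variants = as.integer(n_variants),
                 n_samples = as.integer(n_samples),
                 maf_shape1 = maf_shape1, maf_shape2 = maf_shape2,
                 coverage = coverage, error_scale = error_scale,
                 cn_profile = cn_profile, chrom_lengths = chrom_lengths,
                 seed = as.integer(seed)),
            class = "dosage_sim_config")
}

draw_maf_spectrum <- function(n, shape1, shape2, lo = 5e-4, hi = 0.5) {
  # fold a Beta draw to the minor allele and truncate by redrawing
  q <- rbeta(n, shape1, shape2)
  q <- pmin(q, 1 - q)
  while (any(bad <- q < lo | q > hi)) {
    q2 <- rbeta(sum(bad), shape1, shape2)
    q[bad] <- pmin(q2, 1 - q2)
  }
  q
}

#' Simulate true genotypes under Hardy-Weinberg equilibrium
#'
#' Per variant, the MAF is drawn from the configured spectrum (or taken
#' from `maf` if supplied) and genotypes are drawn per sample from
#' \{0, 1, 2\} with HWE probabilities (1-q)^2, 2q(1-q), q^2 where q is the
#' alternate-allele frequency (identified with the MAF).
#'
#' @param config a [dosage_sim_config()].
#' @param maf optional fixed per-variant MAF vector overriding the spectrum.
#' @return list with `variants` (chrom, pos, ref, alt, maf) and `genotypes`
#'   (integer matrix, variants x samples).
#' @export
simulate_true_genotypes <- function(config, maf = NULL) {
  set.seed(config$seed)
  n <- config$n_variants
  if (is.null(maf)) {
    maf <- draw_maf_spectrum(n, config$maf_shape1, config$maf_shape2)
  } else {
    stopifnot(length(maf) == n, all(maf >= 0 & maf <= 0.5))
  }
  lens <- config$chrom_lengths
  chrom <- sample(names(lens), n, replace = TRUE,
                  prob = lens / sum(lens))
  pos <- as.integer(floor(runif(n) * lens[chrom])) + 1L
  o <- order(match(chrom, names(lens)), pos)
  alleles <- t(vapply(seq_len(n), function(i) sample(VALID_BASES, 2L),
                      character(2)))
  geno <- matrix(rbinom(n * config$n_samples, 2L, rep(maf, config$n_samples)),
                 nrow = n, ncol = config$n_samples)
  colnames(geno) <- sprintf("S%02d", seq_len(config$n_samples))
  list(variants = data.frame(chrom = chrom, pos = pos,
                             ref = alleles[, 1], alt = alleles[, 2],
                             maf = maf, stringsAsFactors = FALSE)[o, ],
       genotypes = geno[o, , drop = FALSE],
       config = config)
}

# error multipliers: f decreasing in MAF (1 at MAF 0.5), g decreasing in
# coverage (1 at 1x), h > 1 only in copy-loss regions
maf_error_factor <- function(maf) (0.5 / pmax(maf, 5e-4))^0.3
coverage_error_factor <- function(coverage) 1 / sqrt(coverage)
cn_error_factor <- function(state) ifelse(state == "loss", 2, 1)

#' Simulate a pair of imputed dosage panels (blood-like and tissue-like)
#'
#' Adds Gaussian noise to the true genotypes on the dosage scale, with
#' per-variant, per-sample SD `error_scale * f(maf) * g(coverage) *
#' h(cn_state)`: `f` decreases with MAF, `g` with coverage, and `h` doubles
#' the noise in copy-loss regions. Dosages are clipped to \[0,2\]. The
#' per-variant quality score is a decreasing function of the realized
#' root-mean-square noise, mapped to \[0,1\] — it emulates, not computes,
#' an imputation INFO score. The blood panel is copy neutral; the tissue
#' panel carries the configured per-sample copy-number profiles.
#'
#' @param truth output of [simulate_true_genotypes()].
#' @param config a [dosage_sim_config()]; `config$cn_profile`, if given,
#'   must be a named list (one entry per sample) of segment data.frames on
#'   the truth's chromosomes.
#' @param blood_coverage mean depth for the blood-like panel (default 0.92x,
#'   typical for a blood lc-WGS arm vs 0.7x tissue).
#' @return list with `blood` and `tissue` [dosage_panel()]s sharing the
#'   truth's variant keys.
#' @export
simulate_imputed_dosages <- function(truth, config = truth$config,
                                     blood_coverage = 0.92) {
  set.seed(config$seed + 1L)
  v <- truth$variants
  n <- nrow(v)
  ns <- ncol(truth$genotypes)
  cn_state <- matrix("neutral", n, ns)
  if (!is.null(config$cn_profile)) {
    profs <- config$cn_profile
    if (is.null(names(profs)) || !all(names(profs) %in% colnames(truth$genotypes)))
      stop("cn_profile must be a named list keyed by sample id")
    for (sid in names(profs)) {
      seg <- profs[[sid]]
      if (!all(normalize_chrom(seg$chrom) %in% normalize_chrom(v$chrom)))
        stop("cn_profile chromosomes do not match the simulated genome")
      st <- annotate_cn_state(v, seg)
      cn_state[, match(sid, colnames(truth$genotypes))] <- st
    }
  }
  make_panel <- function(coverage, states) {
    sdm <- config$error_scale * maf_error_factor(v$maf) *
      coverage_error_factor(coverage) * cn_error_factor(states)
    noise <- matrix(rnorm(n * ns), n, ns) * sdm
    ds <- pmin(pmax(truth$genotypes + noise, 0), 2)
    colnames(ds) <- colnames(truth$genotypes)
    # monotone map from realized noise to [0,1], calibrated so that
    # common-SNP noise at lc-WGS defaults (~0.2 dosage SD) scores ~0.9
    # and rare-SNP noise (~0.6 SD) falls below the 0.80 filter
    rmse <- sqrt(rowMeans(noise^2))
    quality <- exp(-2 * rmse^2)
    dosage_panel(cbind(v, quality = quality), ds)
  }
  blood <- make_panel(blood_coverage, matrix("neutral", n, ns))
  tissue <- make_panel(config$coverage, cn_state)
  list(blood = blood, tissue = tissue, cn_state = cn_state)
}

#' Simulate a copy-number segment profile on a toy genome
#'
#' Tiles each chromosome with fixed-width bins and assigns contiguous runs
#' of bins to gain (log2 ratio +0.58, i.e. 3 copies) and loss (-1.0, one
#' copy) so that the realized altered fraction is within one bin of the
#' request; the rest is neutral (0). Adjacent same-state bins are merged.
#'
#' @param fraction_gain,fraction_loss requested genome fractions, sum <= 1.
#' @param seed integer seed (placement of the altered runs is random).
#' @param chrom_lengths named genome; default 2 chromosomes x 5 Mb.
#' @param bin_bp bin width (default 100 kb).
#' @return data.frame of segments (chrom, start, end, log2_ratio), 0-based
#'   half-open.
#' @export
simulate_cn_profile <- function(fraction_gain, fraction_loss, seed = 1L,
                                chrom_lengths = c(`1` = 5e6, `2` = 5e6),
                                bin_bp = 1e5) {
  stopifnot(fraction_gain >= 0, fraction_loss >= 0)
  if (fraction_gain + fraction_loss > 1)
    stop("fraction_gain + fraction_loss must not exceed 1")
  set.seed(seed)
  n_bins <- setNames(as.integer(round(chrom_lengths / bin_bp)),
                     names(chrom_lengths))
  total <- sum(n_bins)
  k_gain <- round(fraction_gain * total)
  k_loss <- round(fraction_loss * total)
  state <- rep("neutral", total)
  start_at <- if (total - k_gain - k_loss > 0)
    sample.int(total - k_gain - k_loss, 1L) else 1L
  if (k_gain > 0) state[seq(start_at, length.out = k_gain)] <- "gain"
  if (k_loss > 0) state[seq(start_at + k_gain, length.out = k_loss)] <- "loss"
  ratio <- c(neutral = 0, gain = 0.58, loss = -1.0)
  chrom <- rep(names(n_bins), n_bins)
  bin_i <- unlist(lapply(n_bins, seq_len)) - 1L
  segs <- data.frame(chrom = chrom,
                     start = bin_i * bin_bp,
                     end = (bin_i + 1) * bin_bp,
                     log2_ratio = unname(ratio[state]),
                     stringsAsFactors = FALSE)
  # merge adjacent bins with equal ratio
  run <- cumsum(c(TRUE, segs$chrom[-1] != segs$chrom[-nrow(segs)] |
                    segs$log2_ratio[-1] != segs$log2_ratio[-nrow(segs)]))
  merged <- do.call(rbind, lapply(split(segs, run), function(s)
    data.frame(chrom = s$chrom[1], start = min(s$start), end = max(s$end),
               log2_ratio = s$log2_ratio[1], stringsAsFactors = FALSE)))
  merged <- merged[order(match(merged$chrom, names(chrom_lengths)), merged$start), ]
  rownames(merged) <- NULL
  merged
}

#' Simulate gold-standard and imputed HLA typings
#'
#' Gold alleles are drawn per gene from a bundled 4-field allele frequency
#' table (`inst/extdata/hla_allele_freqs_synthetic.tsv` — allele names are
#' real nomenclature, the frequencies are synthetic round numbers). Each imputed allele is independently replaced by
#' a different allele of the same gene with its class error rate. Posterior
#' probabilities are drawn from Beta(12, 2) for fully concordant gene calls
#' and Beta(4, 3) for calls carrying an error, so concordant calls have
#' higher posteriors on average.
#'
#' @param n_samples number of individuals.
#' @param class1_error per-allele error rate for HLA-A/B/C.
#' @param class2_error per-allele error rate for DRB1/DQB1.
#' @param seed integer seed.
#' @return list with `gold` and `imputed` HLA tables (see
#'   [read_hla_table()] for the layout).
#' @export
simulate_hla_truth_and_calls <- function(n_samples, class1_error = 0.05,
                                         class2_error = 0.18, seed = 1L) {
  stopifnot(class1_error >= 0, class1_error <= 1,
            class2_error >= 0, class2_error <= 1)
  set.seed(seed)
  freqs <- hla_allele_freqs()
  genes <- names(HLA_GENE_CLASS)
  rows <- list()
  for (s in seq_len(n_samples)) {
    sid <- sprintf("S%03d", s)
    for (g in genes) {
      tab <- freqs[freqs$gene == g, ]
      gold <- sample(tab$allele, 2L, replace = TRUE, prob = tab$freq)
      err_rate <- if (HLA_GENE_CLASS[[g]] == "I") class1_error else class2_error
      imput <- vapply(gold, function(a) {
        if (runif(1) < err_rate && nrow(tab) > 1) {
          sample(setdiff(tab$allele, a), 1L)
        } else a
      }, character(1))
      n_err <- sum(imput != gold)
      post <- if (n_err == 0) rbeta(1, 12, 2) else rbeta(1, 4, 3)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, gene = g,
        gold1 = gold[1], gold2 = gold[2],
        imp1 = unname(imput[1]), imp2 = unname(imput[2]),
        posterior = post, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  cls <- unname(HLA_GENE_CLASS[df$gene])
  list(
    gold = data.frame(sample_id = df$sample_id, gene = df$gene,
                      allele1 = df$gold1, allele2 = df$gold2,
                      posterior = NA_real_, class_label = cls,
                      stringsAsFactors = FALSE),
    imputed = data.frame(sample_id = df$sample_id, gene = df$gene,
                         allele1 = df$imp1, allele2 = df$imp2,
                         posterior = df$posterior, class_label = cls,
                         stringsAsFactors = FALSE))
}

hla_allele_freqs <- function() {
  path <- system.file("extdata", "hla_allele_freqs_synthetic.tsv",
                      package = "archivalgeno", mustWork = TRUE)
  as.data.frame(data.table::fread(path))
}

#' Configuration for the cohort simulator
#'
#' Defaults emulate a DCIS case-control cohort: covariate marginals follow
#' a clinical table (grade mostly 1-2, lesion ~1 cm, diagnosis in the
#' 40-80 decade bands, predominantly European ancestry), events arise
#' under proportional hazards with a PRS effect, and case-control
#' subsampling keeps all events plus a stated fraction of non-events.
#'
#' @param n_patients cohort size before subsampling (>= 10).
#' @param true_log_hr_per_sd log hazard ratio per SD of the normalized PRS.
#' @param baseline_rate baseline event rate per year. The default 0.016
#'   gives roughly 15% cumulative incidence at 10 years, the epidemiological
#'   rate for surgically treated disease used by the weighting scheme.
#' @param covariate_effects named log-HRs for `grade`, `size_cm`, `age`
#'   (per decade) and `european_ancestry`.
#' @param censor_time_years administrative censoring horizon.
#' @param control_fraction fraction of non-events kept by case-control
#'   subsampling; 1 disables subsampling.
#' @param grade_missing_rate fraction of patients whose grade is masked to
#'   `NA` (to exercise burden-tertile grade imputation).
#' @param seed integer seed.
#' @return a `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_patients = 50L, true_log_hr_per_sd = log(2),
                              baseline_rate = 0.016,
                              covariate_effects = c(grade = 0.25,
                                                    size_cm = 0.10,
                                                    age = 0.05,
                                                    european_ancestry = 0.0),
                              censor_time_years = 15,
                              control_fraction = 1,
                              grade_missing_rate = 0,
                              seed = 1L) {
  stopifnot(n_patients >= 10, baseline_rate > 0, censor_time_years > 0,
            control_fraction > 0, control_fraction <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 true_log_hr_per_sd = true_log_hr_per_sd,
                 baseline_rate = baseline_rate,
                 covariate_effects = covariate_effects,
                 censor_time_years = censor_time_years,
                 control_fraction = control_fraction,
                 grade_missing_rate = grade_missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate a case-control survival cohort with a PRS effect
#'
#' PRS values are standard normal; covariates are drawn from clinical-table
#' marginals; event times are exponential with rate
#' `baseline_rate * exp(lp)` where the linear predictor sums the PRS and
#' covariate effects (covariates centered so the baseline rate applies to
#' an average patient); administrative censoring at `censor_time_years`.
#' Optional subsampling retains all events and `control_fraction` of the
#' non-events, mirroring outcome-based retrospective selection.
#'
#' @param config a [cohort_sim_config()].
#' @return data.frame with `patient_id`, `event`, `time` (years), `grade`,
#'   `size_cm`, `age_group`, `european_ancestry`, `prs`.
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  n <- config$n_patients
  prs <- rnorm(n)
  grade <- sample(1:3, n, replace = TRUE, prob = c(0.35, 0.45, 0.20))
  size_cm <- round(pmin(pmax(exp(rnorm(n, log(0.9), 0.5)), 0.1), 5), 1)
  bands <- c("41-50", "51-60", "61-70", "71-80", "81-90")
  age_group <- sample(bands, n, replace = TRUE,
                      prob = c(0.25, 0.35, 0.2, 0.15, 0.05))
  age_dec <- (age_band_midpoint(age_group) - 55) / 10
  eur <- runif(n) < 0.9
  ce <- config$covariate_effects
  lp <- config$true_log_hr_per_sd * prs +
    ce[["grade"]] * (grade - 2) +
    ce[["size_cm"]] * (size_cm - 1) +
    ce[["age"]] * age_dec +
    ce[["european_ancestry"]] * (eur - 0.5)
  rate <- config$baseline_rate * exp(lp)
  if (sum(1 - exp(-rate * config$censor_time_years)) < 1e-8)
    stop("configuration yields essentially zero expected events")
  t_event <- rexp(n, rate = rate)
  event <- t_event <= config$censor_time_years
  time <- pmin(t_event, config$censor_time_years)
  cohort <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                       event = event, time = time,
                       grade = grade, size_cm = size_cm,
                       age_group = age_group,
                       european_ancestry = eur, prs = prs,
                       stringsAsFactors = FALSE)
  if (config$grade_missing_rate > 0) {
    mask <- runif(n) < config$grade_missing_rate
    cohort$grade[mask] <- NA_integer_
  }
  if (config$control_fraction < 1) {
    ctrl <- which(!cohort$event)
    keep_ctrl <- sort(sample(ctrl, round(length(ctrl) * config$control_fraction)))
    cohort <- cohort[sort(c(which(cohort$event), keep_ctrl)), ]
    rownames(cohort) <- NULL
  }
  cohort
}
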