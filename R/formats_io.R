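# Readers/writers for the external formats the pipeline touches:
# dosage VCF, PGS-Catalog scoring files, segment tables, cohort tables,
# HLA typing tables. Coordinate conventions: variants are 1-based (VCF),
# segments are 0-based half-open (BED); a variant at position p lies in
# segment [start, end) iff start <= p - 1 < end.

VALID_BASES <- c("A", "C", "G", "T")

#' Strip any "chr" prefix from chromosome labels
#'
#' Inputs from different pipelines mix "chr1" and "1" styles; all internal
#' matching is done on the stripped form.
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector without a leading "chr".
#' @export
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom), ignore.case = TRUE)
}

#' Construct a dosage panel
#'
#' A dosage panel holds per-variant records (chromosome, 1-based position,
#' ref/alt single-base alleles, global minor allele frequency, imputation
#' quality score in \[0,1\]) together with a variants x samples matrix of
#' expected alternate-allele dosages in \[0,2\].
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `maf`, `quality`.
#' @param dosages numeric matrix, `nrow(variants)` rows, one column per
#'   sample; column names are sample ids.
#' @return an object of class `dosage_panel`.
#' @export
dosage_panel <- function(variants, dosages) {
  stopifnot(is.data.frame(variants), is.matrix(dosages),
            nrow(variants) == nrow(dosages))
  req <- c("chrom", "pos", "ref", "alt", "maf", "quality")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols))
    stop("variants is missing columns: ", paste(missing_cols, collapse = ", "))
  variants$chrom <- normalize_chrom(variants$chrom)
  if (any(variants$ref == variants$alt))
    stop("ref and alt alleles must differ")
  if (!all(variants$ref %in% VALID_BASES & variants$alt %in% VALID_BASES))
    stop("only biallelic SNPs (single-base A/C/G/T alleles) are supported")
  if (any(variants$maf < 0 | variants$maf > 0.5, na.rm = TRUE))
    stop("maf must lie in [0, 0.5]")
  if (any(variants$quality < 0 | variants$quality > 1, na.rm = TRUE))
    stop("quality must lie in [0, 1]")
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE))
    stop("dosages must lie in [0, 2]")
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("S", seq_len(ncol(dosages)))
  structure(list(variants = as.data.frame(variants, row.names = NULL),
                 dosages = dosages,
                 samples = colnames(dosages)),
            class = "dosage_panel")
}

#' @export
print.dosage_panel <- function(x, ...) {
  cat(sprintf("dosage_panel: %d variants x %d samples\n",
              nrow(x$variants), length(x$samples)))
  cat("samples:", paste(head(x$samples, 8), collapse = ", "),
      if (length(x$samples) > 8) "..." else "", "\n")
  invisible(x)
}

#' Variant keys ("chrom:pos:ref:alt") for a panel
#' @param panel a [dosage_panel()].
#' @return character vector of keys.
#' @export
variant_keys <- function(panel) {
  with(panel$variants, paste(chrom, pos, ref, alt, sep = ":"))
}

#' Read a dosage VCF into a dosage panel
#'
#' Reads a VCF carrying per-genotype expected alternate-allele dosages and a
#' per-variant imputation-quality INFO annotation (the output style of
#' lc-WGS imputation tools). Only biallelic SNP records are retained;
#' multi-allelic records and indels are dropped with a logged count.
#'
#' @param path VCF file (plain or bgzipped).
#' @param dosage_field FORMAT tag holding the dosage (default `"DS"`).
#' @param quality_field INFO tag holding the imputation quality score;
#'   a leading `"INFO/"` prefix is accepted (default `"INFO/INFO_SCORE"`).
#' @param maf_field INFO tag holding the minor allele frequency.
#' @return a [dosage_panel()].
#' @export
read_dosage_vcf <- function(path, dosage_field = "DS",
                            quality_field = "INFO/INFO_SCORE",
                            maf_field = "MAF") {
  quality_field <- sub("^INFO/", "", quality_field)
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt_l <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(alt_l)
  alt <- rep(NA_character_, length(ref))
  alt[n_alt == 1] <- as.character(unlist(alt_l[n_alt == 1]))
  keep <- n_alt == 1 & !is.na(alt) &
    ref %in% VALID_BASES & alt %in% VALID_BASES
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(sprintf("read_dosage_vcf: dropped %d non-SNP/multi-allelic record(s)",
                    n_drop))
  g <- VariantAnnotation::geno(vcf)
  if (!dosage_field %in% names(g))
    stop(sprintf("VCF '%s' has no FORMAT field '%s' (first record: %s)",
                 path, dosage_field, rownames(vcf)[1]))
  ds <- g[[dosage_field]]
  if (is.list(ds) || length(dim(ds)) > 2) ds <- matrix(unlist(ds), nrow = nrow(vcf))
  storage.mode(ds) <- "double"
  colnames(ds) <- colnames(vcf)
  info <- VariantAnnotation::info(vcf)
  qual <- if (quality_field %in% names(info)) {
    as.numeric(unlist(info[[quality_field]]))
  } else rep(NA_real_, nrow(vcf))
  maf <- if (maf_field %in% names(info)) {
    as.numeric(unlist(info[[maf_field]]))
  } else rep(NA_real_, nrow(vcf))
  pos <- GenomicRanges::start(rr)
  if (any(is.na(pos[keep])))
    stop("malformed variant position in ", path)
  variants <- data.frame(
    chrom = normalize_chrom(as.character(GenomicRanges::seqnames(rr)))[keep],
    pos = pos[keep], ref = ref[keep], alt = alt[keep],
    maf = maf[keep], quality = qual[keep],
    stringsAsFactors = FALSE)
  dosage_panel(variants, ds[keep, , drop = FALSE])
}

#' Write a dosage panel as a VCF
#'
#' Emits a minimal VCF 4.2 file with `MAF` and a quality score as INFO
#' fields and the dosage as a FORMAT field, round-trippable by
#' [read_dosage_vcf()].
#'
#' @inheritParams read_dosage_vcf
#' @param panel a [dosage_panel()].
#' @param digits decimal places for dosages (default 6).
#' @return `path`, invisibly.
#' @export
write_dosage_vcf <- function(panel, path, dosage_field = "DS",
                             quality_field = "INFO/INFO_SCORE",
                             maf_field = "MAF", digits = 6) {
  quality_field <- sub("^INFO/", "", quality_field)
  v <- panel$variants
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=archivalgeno",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Minor allele frequency\">",
            maf_field),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Imputation quality score\">",
            quality_field),
    sprintf("##FORMAT=<ID=%s,Number=1,Type=Float,Description=\"Expected alternate allele dosage\">",
            dosage_field),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t"))
  info <- sprintf("%s=%s;%s=%s", maf_field, formatC(v$maf, format = "g", digits = 8),
                  quality_field, formatC(v$quality, format = "g", digits = 8))
  ds_chr <- formatC(panel$dosages, format = "f", digits = digits)
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info,
                dosage_field,
                apply(ds_chr, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a PGS-Catalog-style scoring file
#'
#' Tab-delimited with a header; `#` comment lines are skipped. Variant
#' identity columns may be genomic (`chr_name`/`chr_position` plus
#' `effect_allele`/`other_allele`) or an `rsID` column; the weight column is
#' `effect_weight` (a per-allele log odds ratio). Duplicate variant rows
#' keep the first occurrence with a warning.
#'
#' @param path scoring file.
#' @param model_id identifier for the score; defaults to the file name.
#' @return a `prs_model`: list with `model_id` and a `sites` data.frame
#'   (`chrom`, `pos`, `rsid`, `effect_allele`, `other_allele`, `beta`).
#' @export
read_pgs_scoring_file <- function(path, model_id = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, skip = "")
  # fread drops '#'-prefixed lines only when told; detect them manually
  first <- readLines(path, n = 200L)
  n_comment <- sum(startsWith(first, "#"))
  if (n_comment > 0)
    dt <- data.table::fread(path, sep = "\t", header = TRUE, skip = n_comment)
  nm <- names(dt)
  pick <- function(cands) {
    hit <- intersect(cands, nm)
    if (length(hit)) dt[[hit[1]]] else rep(NA, nrow(dt))
  }
  beta_raw <- pick(c("effect_weight", "beta", "weight"))
  beta <- suppressWarnings(as.numeric(beta_raw))
  bad <- which(is.na(beta) & !is.na(beta_raw))
  if (length(bad))
    stop(sprintf("non-numeric effect weight at data line %d of %s", bad[1], path))
  sites <- data.frame(
    chrom = normalize_chrom(pick(c("chr_name", "chrom", "chr"))),
    pos = suppressWarnings(as.integer(pick(c("chr_position", "pos", "position")))),
    rsid = as.character(pick(c("rsID", "rsid", "rs_id", "variant_id"))),
    effect_allele = toupper(as.character(pick(c("effect_allele", "A1")))),
    other_allele = toupper(as.character(pick(c("other_allele", "reference_allele", "A2")))),
    beta = beta,
    stringsAsFactors = FALSE)
  key <- ifelse(is.na(sites$pos), sites$rsid,
                paste(sites$chrom, sites$pos, sep = ":"))
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("%d duplicated site(s) in %s; keeping first occurrence",
                    sum(dup), path))
    sites <- sites[!dup, , drop = FALSE]
  }
  if (is.null(model_id)) model_id <- sub("\\.[^.]*$", "", basename(path))
  structure(list(model_id = model_id,
                 sites = as.data.frame(sites, row.names = NULL)),
            class = "prs_model")
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("prs_model '%s': %d sites\n", x$model_id, nrow(x$sites)))
  invisible(x)
}

#' Read a BED-like copy-number segment table
#'
#' Tab- or comma-delimited with columns `chrom`, `start` (0-based,
#' inclusive), `end` (0-based, exclusive), `log2_ratio`, and optionally
#' `sample_id`. Overlapping segments on one chromosome (within a sample)
#' are a hard error.
#'
#' @param path segment file.
#' @return data.frame of segments.
#' @export
read_segments <- function(path) {
  dt <- as.data.frame(data.table::fread(path))
  req <- c("chrom", "start", "end", "log2_ratio")
  if (!all(req %in% names(dt)))
    stop("segment file must have columns: ", paste(req, collapse = ", "))
  dt$chrom <- normalize_chrom(dt$chrom)
  if (any(dt$end <= dt$start))
    stop("segments must satisfy end > start")
  check_segment_overlap(dt)
  dt
}

check_segment_overlap <- function(seg) {
  grp <- if ("sample_id" %in% names(seg)) {
    paste(seg$sample_id, seg$chrom)
  } else seg$chrom
  for (g in unique(grp)) {
    s <- seg[grp == g, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("overlapping segments on chromosome ", s$chrom[1])
  }
  invisible(seg)
}

#' Read a cohort table
#'
#' Comma- or tab-delimited table of one row per patient with columns
#' `patient_id`, `event` (yes/no or logical), `time` (days to event or last
#' follow-up), `grade` (1/2/3 or empty), `size_cm` (or empty), `age_range`
#' (decade band such as "41-50"), `european_ancestry` (logical, or a `race`
#' column from which it is derived as race == "White"). Missing grade and
#' size are preserved as `NA`.
#'
#' @param path cohort file.
#' @return data.frame with typed columns, one row per patient.
#' @export
read_cohort <- function(path) {
  dt <- as.data.frame(data.table::fread(path, na.strings = c("", "NA")))
  if (!all(c("patient_id", "event", "time") %in% names(dt)))
    stop("cohort file needs at least patient_id, event, time columns")
  ev <- dt$event
  if (!is.logical(ev))
    ev <- tolower(as.character(ev)) %in% c("yes", "true", "1", "y")
  out <- data.frame(patient_id = as.character(dt$patient_id),
                    event = ev,
                    time = as.numeric(dt$time),
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$time) | out$time <= 0))
    stop("time must be positive for every patient")
  out$grade <- if ("grade" %in% names(dt)) {
    g <- suppressWarnings(as.integer(dt$grade))
    if (any(!g %in% c(1L, 2L, 3L) & !is.na(g)))
      stop("grade must be 1, 2 or 3 when present")
    g
  } else NA_integer_
  out$size_cm <- if ("size_cm" %in% names(dt)) as.numeric(dt$size_cm) else NA_real_
  out$age_group <- if ("age_range" %in% names(dt)) {
    as.character(dt$age_range)
  } else if ("age_group" %in% names(dt)) as.character(dt$age_group) else NA_character_
  out$european_ancestry <- if ("european_ancestry" %in% names(dt)) {
    as.logical(dt$european_ancestry)
  } else if ("race" %in% names(dt)) {
    toupper(as.character(dt$race)) %in% c("WHITE", "EUROPEAN")
  } else NA
  out
}

#' Midpoint (in years) of a decade age band such as "41-50"
#' @param age_group character vector of bands.
#' @return numeric midpoints.
#' @export
age_band_midpoint <- function(age_group) {
  vapply(strsplit(as.character(age_group), "-"), function(p) {
    if (length(p) != 2) return(NA_real_)
    mean(suppressWarnings(as.numeric(p)))
  }, numeric(1))
}

#' Read an HLA typing table
#'
#' Tab- or comma-delimited with columns `sample_id`, `gene` (A, B, C, DRB1
#' or DQB1), `allele1`, `allele2` (colon-delimited field strings such as
#' `A*02:01:01:01`) and an optional `posterior` column in \[0,1\].
#'
#' @param path typing file.
#' @return data.frame with a derived `class_label` column (I or II).
#' @export
read_hla_table <- function(path) {
  dt <- as.data.frame(data.table::fread(path, na.strings = c("", "NA")))
  req <- c("sample_id", "gene", "allele1", "allele2")
  if (!all(req %in% names(dt)))
    stop("HLA table must have columns: ", paste(req, collapse = ", "))
  gene <- toupper(as.character(dt$gene))
  bad <- setdiff(unique(gene), names(HLA_GENE_CLASS))
  if (length(bad)) stop("unsupported HLA gene(s): ", paste(bad, collapse = ", "))
  out <- data.frame(sample_id = as.character(dt$sample_id),
                    gene = gene,
                    allele1 = as.character(dt$allele1),
                    allele2 = as.character(dt$allele2),
                    posterior = if ("posterior" %in% names(dt))
                      as.numeric(dt$posterior) else NA_real_,
                    stringsAsFactors = FALSE)
  out$class_label <- unname(HLA_GENE_CLASS[out$gene])
  out
}

HLA_GENE_CLASS <- c(A = "I", B = "I", C = "I", DRB1 = "II", DQB1 = "II")
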