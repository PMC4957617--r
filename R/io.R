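# Readers and writers for the pipeline's on-disk formats.
#
# Genotypes travel either as VCF (FORMAT fields GT and DS; DS preferred on
# read) or as a TSV dosage table: one row per individual, first column
# `sample_id`, remaining columns one per SNP id, missing dosage written as
# -9. Phenotypes are one TSV row per individual with named columns. All
# writers round-trip with the readers (checked in the test suite).

MISSING_DOSAGE <- -9

#' Write a dosage matrix as VCF
#'
#' Writes a minimal VCFv4.2 file with `GT` (rounded hard call) and `DS`
#' (dosage of the effect allele) per sample. The effect allele is stored as
#' ALT so that the dosage counts ALT copies; the other allele is REF.
#'
#' @param dosage matrix (individuals x SNPs), `NA` = missing.
#' @param snps data.frame with `id`, `effect_allele`, `other_allele` and
#'   optionally `chrom`, `pos`.
#' @param path output file.
#' @param sample_ids optional sample names (default `S1..Sn`).
#' @return `path`, invisibly.
#' @export
write_dosage_vcf <- function(dosage, snps, path, sample_ids = NULL) {
  stopifnot(is.matrix(dosage), nrow(snps) == ncol(dosage))
  n <- nrow(dosage)
  sample_ids <- sample_ids %||% sprintf("S%d", seq_len(n))
  chrom <- snps$chrom %||% rep("7", nrow(snps))
  pos <- snps$pos %||% seq_len(nrow(snps)) * 1000L
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=igfmr-%s", as.character(packageVersion("igfmr"))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype (hard call)\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the ALT (effect) allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            sample_ids), collapse = "\t")
  )
  gt_str <- function(d) {
    ifelse(is.na(d), "./.:.",
           paste0(c("0/0", "0/1", "1/1")[pmin(pmax(round(d), 0), 2) + 1],
                  ":", formatC(d, format = "g", digits = 6)))
  }
  body <- vapply(seq_len(nrow(snps)), function(j) {
    paste(c(chrom[j], pos[j], snps$id[j], snps$other_allele[j],
            snps$effect_allele[j], ".", "PASS", ".", "GT:DS",
            gt_str(dosage[, j])), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read dosages from a VCF
#'
#' Uses `VariantAnnotation::readVcf()`. The `DS` FORMAT field is preferred
#' when present; otherwise dosages are hard calls counted from `GT` (number
#' of ALT alleles). The effect allele is taken to be ALT.
#'
#' @param path VCF file.
#' @return list with `dosage` (individuals x SNPs matrix, `NA` for missing)
#'   and `snps` (data.frame `id`, `effect_allele`, `other_allele`, `chrom`,
#'   `pos`).
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_dosage_vcf() needs the VariantAnnotation package")
  }
  v <- VariantAnnotation::readVcf(path)
  g <- VariantAnnotation::geno(v)
  if ("DS" %in% names(g)) {
    D <- t(as.matrix(g$DS))
    storage.mode(D) <- "double"
  } else if ("GT" %in% names(g)) {
    gt <- t(g$GT)
    D <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    D[] <- vapply(gt, function(s) {
      if (is.na(s) || s %in% c("./.", ".")) return(NA_real_)
      sum(as.integer(strsplit(s, "[/|]")[[1]]) > 0)
    }, numeric(1))
  } else stop("VCF has neither DS nor GT FORMAT fields")
  rr <- SummarizedExperiment::rowRanges(v)
  alt <- as.character(unlist(rr$ALT))
  snps <- data.frame(
    id = names(rr),
    effect_allele = alt,
    other_allele = as.character(rr$REF),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    stringsAsFactors = FALSE
  )
  colnames(D) <- snps$id
  list(dosage = D, snps = snps)
}

#' Write / read the TSV dosage dialect
#'
#' One row per individual; first column `sample_id`, then one column per
#' SNP id. Missing dosage is stored as -9 (outside \[0,2\]) and mapped back
#' to `NA` on read.
#'
#' @param dosage matrix (individuals x SNPs) with SNP id column names.
#' @param path file path.
#' @param sample_ids optional sample names.
#' @return `path` (writer) or the dosage matrix with sample ids as row
#'   names (reader).
#' @export
write_dosage_tsv <- function(dosage, path, sample_ids = NULL) {
  stopifnot(is.matrix(dosage), !is.null(colnames(dosage)))
  sample_ids <- sample_ids %||% sprintf("S%d", seq_len(nrow(dosage)))
  out <- as.data.frame(dosage)
  out[is.na(out)] <- MISSING_DOSAGE
  out <- cbind(sample_id = sample_ids, out)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (names(df)[1] != "sample_id") stop("first column must be sample_id")
  D <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(D) <- "double"
  D[D == MISSING_DOSAGE] <- NA_real_
  rownames(D) <- df$sample_id
  D
}

#' Write / read a phenotype table for an `mr_cohort`
#'
#' One row per individual: `sample_id`, `study`, `disease`, `grade`,
#' `stage`, `time`, `event`, then one column per biomarker (ng/mL) and per
#' covariate.
#'
#' @param cohort an `mr_cohort`.
#' @param path file path.
#' @param sample_ids optional sample names.
#' @return `path` (writer); the reader returns an `mr_cohort` when given
#'   the matching dosage matrix and biomarker panel.
#' @export
write_phenotype_tsv <- function(cohort, path, sample_ids = NULL) {
  n <- nrow(cohort$dosage)
  sample_ids <- sample_ids %||% sprintf("S%d", seq_len(n))
  df <- data.frame(
    sample_id = sample_ids, study = as.character(cohort$study),
    disease = cohort$disease, grade = cohort$grade, stage = cohort$stage,
    time = cohort$time, event = cohort$event,
    check.names = FALSE
  )
  df <- cbind(df, as.data.frame(cohort$biomarkers), cohort$covariates)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @param dosage dosage matrix aligned to the phenotype rows.
#' @param snps SNP table (`id`, `effect_allele`, `other_allele`, `eaf`).
#' @param biomarker_info biomarker panel data.frame (`name`, `mean`, `sd`,
#'   `log_normal`) naming which phenotype columns are biomarkers.
#' @export
read_phenotype_tsv <- function(path, dosage, snps, biomarker_info) {
  df <- read.delim(path, check.names = FALSE)
  need <- c("sample_id", "study", "disease", "grade", "stage", "time", "event")
  if (!all(need %in% names(df))) {
    stop("phenotype TSV missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (nrow(df) != nrow(dosage)) stop("phenotype and dosage row counts differ")
  bm <- as.matrix(df[, biomarker_info$name, drop = FALSE])
  covars <- df[, setdiff(names(df), c(need, biomarker_info$name)), drop = FALSE]
  validate_cohort(structure(list(
    dosage = dosage, biomarkers = bm, biomarker_info = biomarker_info,
    covariates = covars, disease = df$disease, grade = df$grade,
    stage = df$stage, time = df$time, event = df$event,
    study = factor(df$study), snps = snps
  ), class = "mr_cohort"))
}
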