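# Genotype QC: allele accounting, Hardy-Weinberg testing, dosage-based LD.
#
# Missing dosages are NA internally (the TSV dialect uses -9 as the on-disk
# sentinel); every operation skips missing values pairwise. Fractional
# (imputed) dosages are hard-called with tolerance 0.1 before HWE testing:
# HWE on posterior dosages is ill-defined.

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' One-degree-of-freedom chi-square goodness-of-fit of observed genotype
#' counts against the Hardy-Weinberg proportions implied by the sample
#' allele frequency. An exact (Wigginton-Cutler-Abecasis) test is available
#' for rare variants via `exact = TRUE`.
#'
#' @param counts integer vector `c(n_AA, n_Aa, n_aa)` where A is the effect
#'   allele.
#' @param exact use the exact conditional test instead of chi-square.
#' @return list with `chi2`, `p`, `eaf` and `monomorphic`; monomorphic
#'   input returns `chi2 = 0`, `p = 1` with the flag set.
#' @export
hwe_test <- function(counts, exact = FALSE) {
  counts <- as.numeric(counts)
  if (length(counts) != 3 || any(counts < 0)) stop("counts must be 3 non-negative numbers")
  n <- sum(counts)
  if (n <= 0) stop("zero total genotype count")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p <= 0 || p >= 1) {
    return(list(chi2 = 0, p = 1, eaf = p, monomorphic = TRUE))
  }
  if (exact) {
    return(list(chi2 = NA_real_, p = hwe_exact_p(counts), eaf = p, monomorphic = FALSE))
  }
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((counts - e)^2 / e)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       eaf = p, monomorphic = FALSE)
}

# Exact HWE p-value: sum of conditional probabilities of heterozygote
# counts at most as likely as the observed one, given allele counts.
hwe_exact_p <- function(counts) {
  nAA <- round(counts[1]); nAa <- round(counts[2]); naa <- round(counts[3])
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  rare <- min(nA, 2 * n - nA)
  het_vals <- seq(rare %% 2, rare, by = 2)
  # unnormalised log P(het = h | allele counts)
  lp <- vapply(het_vals, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) + h * log(2)
  }, numeric(1))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  obs <- if (nA <= 2 * n - nA) nAa else nAa # het count is coding-invariant
  min(1, sum(pr[pr <= pr[het_vals == obs] + 1e-12]))
}

#' Allele summary statistics from dosages
#'
#' @param dosages numeric vector of additive dosages in \[0,2\]; `NA` =
#'   missing.
#' @return list with `eaf` (mean dosage / 2 over non-missing entries),
#'   `maf`, `call_rate`, `n` and `monomorphic`.
#' @export
allele_stats <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("all dosages missing")
  d <- dosages[ok]
  if (any(d < 0 | d > 2)) stop("dosages outside [0,2]")
  eaf <- mean(d) / 2
  list(eaf = eaf, maf = min(eaf, 1 - eaf), call_rate = mean(ok),
       n = sum(ok), monomorphic = (max(d) - min(d)) == 0)
}

#' Pairwise LD as squared dosage correlation
#'
#' Composite LD: the squared Pearson correlation of additive dosages
#' (phased haplotypes are not required). Symmetric and invariant to allele
#' flipping (replacing a vector by `2 - vector`).
#'
#' @param dosages_a,dosages_b equal-length dosage vectors; missing values
#'   are dropped pairwise.
#' @return r2 in \[0,1\].
#' @export
ld_r2 <- function(dosages_a, dosages_b) {
  if (length(dosages_a) != length(dosages_b)) stop("dosage vectors differ in length")
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  a <- dosages_a[ok]; b <- dosages_b[ok]
  if (length(a) < 2 || sd(a) == 0 || sd(b) == 0) stop("monomorphic or empty input")
  cor(a, b)^2
}

#' Hard-call mask for fractional dosages
#'
#' @param dosages numeric dosages.
#' @param tol maximum distance from an integer genotype.
#' @return logical: TRUE where the dosage is within `tol` of 0, 1 or 2.
#' @export
hard_call_mask <- function(dosages, tol = 0.1) {
  !is.na(dosages) & abs(dosages - round(dosages)) < tol
}

#' Per-SNP QC table for a dosage matrix
#'
#' Computes allele statistics and the Hardy-Weinberg test (on the
#' hard-called subset) for every SNP, flagging rather than dropping: the
#' exclusion threshold is a pipeline decision.
#'
#' @param dosage matrix (individuals x SNPs) with SNP ids as column names.
#' @param hwe_flag_p flag SNPs with HWE p below this threshold.
#' @param exact use the exact HWE test.
#' @return data.frame, one row per SNP: `id`, `eaf`, `maf`, `call_rate`,
#'   `monomorphic`, `n_hard`, `hwe_chi2`, `hwe_p`, `hwe_flag`.
#' @export
snp_qc <- function(dosage, hwe_flag_p = 1e-4, exact = FALSE) {
  stopifnot(is.matrix(dosage), !is.null(colnames(dosage)))
  rows <- lapply(colnames(dosage), function(id) {
    d <- dosage[, id]
    st <- allele_stats(d)
    hm <- hard_call_mask(d)
    g <- round(d[hm])
    if (sum(hm) > 0 && !st$monomorphic) {
      cnt <- c(sum(g == 2), sum(g == 1), sum(g == 0)) # AA, Aa, aa (A = effect)
      hw <- hwe_test(cnt, exact = exact)
    } else {
      hw <- list(chi2 = 0, p = 1)
    }
    data.frame(id = id, eaf = st$eaf, maf = st$maf, call_rate = st$call_rate,
               monomorphic = st$monomorphic, n_hard = sum(hm),
               hwe_chi2 = hw$chi2, hwe_p = hw$p,
               hwe_flag = hw$p < hwe_flag_p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
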