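# Instrument validation: per-allele exposure effects, instrument strength
# (partial F, incremental R2), confounder screens and pleiotropy matrices.
#
# Additive (per-allele) coding throughout; two-sided p-values from the t
# distribution. Incremental R2 is full-model R2 minus covariate-only R2,
# so the reported variance explained is the share attributable to the SNP
# after age / principal-component adjustment.

#' Per-allele SNP-biomarker regression
#'
#' Ordinary least squares of the (possibly natural-log-transformed)
#' biomarker on additive dosage plus covariates. The reported `beta` is the
#' mean biomarker difference per effect allele (ng/mL, or log units under
#' `transform = "log"`), `F` is the partial F for the dosage term (equal to
#' t^2), and `r2` the incremental R2 attributable to dosage.
#'
#' @param dosage additive dosage vector in \[0,2\].
#' @param biomarker biomarker concentrations (ng/mL); must be positive
#'   everywhere when `transform = "log"`.
#' @param covariates optional data.frame / matrix of adjustment covariates.
#' @param transform `"none"` or `"log"` (natural log).
#' @param snp_id,biomarker_name labels carried into the result.
#' @return object of class `exposure_assoc`: `snp`, `biomarker`, `beta`,
#'   `se`, `ci` (95\%), `p`, `F`, `r2`, `r2_adj` (adjusted incremental R2),
#'   `n`, `transform`, `covariates`.
#' @export
exposure_regression <- function(dosage, biomarker, covariates = NULL,
                                transform = c("none", "log"),
                                snp_id = "snp", biomarker_name = "biomarker") {
  transform <- match.arg(transform)
  X <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  ok <- !is.na(dosage) & !is.na(biomarker)
  if (!is.null(X)) ok <- ok & complete.cases(X)
  if (sum(ok) < 10) stop("fewer than 10 complete cases")
  d <- dosage[ok]; y <- biomarker[ok]
  if (sd(d) == 0) stop("monomorphic SNP")
  if (transform == "log") {
    if (any(y <= 0)) stop("biomarker must be positive for log transform")
    y <- log(y)
  }
  dat <- data.frame(.y = y, .dosage = d)
  if (!is.null(X)) dat <- cbind(dat, X[ok, , drop = FALSE])
  rhs <- c(".dosage", if (!is.null(X)) colnames(X))
  fit <- lm(as.formula(paste(".y ~", paste(rhs, collapse = " + "))), data = dat)
  cf <- coef(fit)
  if (anyNA(cf)) stop("singular design (collinear covariates)")
  sm <- summary(fit)
  b <- sm$coefficients[".dosage", ]
  n <- length(y); df_res <- fit$df.residual

  r2_full <- sm$r.squared
  adj_full <- sm$adj.r.squared
  if (is.null(X)) {
    r2_red <- 0; adj_red <- 0
  } else {
    fit0 <- lm(as.formula(paste(".y ~", paste(colnames(X), collapse = " + "))),
               data = dat)
    sm0 <- summary(fit0)
    r2_red <- sm0$r.squared; adj_red <- sm0$adj.r.squared
  }
  structure(list(
    snp = snp_id, biomarker = biomarker_name,
    beta = unname(b["Estimate"]), se = unname(b["Std. Error"]),
    ci = unname(b["Estimate"] + c(-1, 1) * qt(0.975, df_res) * b["Std. Error"]),
    p = unname(b["Pr(>|t|)"]),
    F = unname(b["t value"]^2),
    r2 = r2_full - r2_red,
    r2_adj = adj_full - adj_red,
    n = n, df = df_res, transform = transform,
    covariates = if (is.null(X)) character(0) else colnames(X)
  ), class = "exposure_assoc")
}

#' @export
print.exposure_assoc <- function(x, ...) {
  cat(sprintf(
    "%s -> %s: beta %.3f (95%% CI %.3f, %.3f)%s, p = %.3g, F = %.1f, R2 = %.2f%%, n = %d\n",
    x$snp, x$biomarker, x$beta, x$ci[1], x$ci[2],
    if (x$transform == "log") " [log units]" else " ng/mL",
    x$p, x$F, 100 * x$r2, x$n
  ))
  invisible(x)
}

#' Classify an instrument as strong or weak
#'
#' An instrument is weak when its partial F falls below the threshold;
#' the boundary is inclusive on the strong side (only F < threshold is
#' weak).
#'
#' @param assoc an `exposure_assoc` or a bare F statistic.
#' @param threshold weak-instrument cutoff (default 10).
#' @return `"strong"` or `"weak"`.
#' @export
classify_instrument <- function(assoc, threshold = 10) {
  f <- if (inherits(assoc, "exposure_assoc")) assoc$F else as.numeric(assoc)
  if (!is.finite(f)) stop("F statistic must be finite")
  if (f >= threshold) "strong" else "weak"
}

#' Screen a SNP against potential confounders
#'
#' Regresses each variable on dosage: linear regression for continuous
#' variables, logistic for binary ones (exactly two distinct non-missing
#' values). Flags associations surviving a Bonferroni correction; the full
#' table is always returned, flagged or not.
#'
#' @param dosage additive dosage vector.
#' @param variables data.frame of candidate confounders / other variables
#'   (e.g. age, PSA, BMI, height, BPH, diabetes).
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @param n_tests Bonferroni divisor; defaults to `ncol(variables)`. When
#'   screening several SNPs, pass the total number of (SNP, variable)
#'   tests.
#' @return data.frame of class `screen_result`: `variable`, `type`,
#'   `beta`, `se`, `p`, `flagged` (`p < alpha / n_tests`).
#' @export
confounder_screen <- function(dosage, variables, alpha = 0.05, n_tests = NULL) {
  variables <- as.data.frame(variables)
  if (ncol(variables) < 1) stop("no variables to screen")
  n_tests <- n_tests %||% ncol(variables)
  thr <- alpha / n_tests
  rows <- lapply(names(variables), function(v) {
    y <- variables[[v]]
    ok <- !is.na(y) & !is.na(dosage)
    vals <- unique(y[ok])
    if (length(vals) < 2) {
      warning("skipping constant variable: ", v)
      return(NULL)
    }
    if (length(vals) == 2) {
      yb <- as.integer(y[ok] == max(vals))
      fit <- glm(yb ~ dosage[ok], family = binomial())
      cf <- summary(fit)$coefficients[2, ]
      data.frame(variable = v, type = "binary", beta = cf[["Estimate"]],
                 se = cf[["Std. Error"]], p = cf[["Pr(>|z|)"]])
    } else {
      fit <- lm(y[ok] ~ dosage[ok])
      cf <- summary(fit)$coefficients[2, ]
      data.frame(variable = v, type = "continuous", beta = cf[["Estimate"]],
                 se = cf[["Std. Error"]], p = cf[["Pr(>|t|)"]])
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("all variables constant")
  out$flagged <- out$p < thr
  attr(out, "alpha") <- alpha
  attr(out, "n_tests") <- n_tests
  attr(out, "threshold") <- thr
  class(out) <- c("screen_result", class(out))
  out
}

#' Cross-biomarker pleiotropy matrix
#'
#' Runs [exposure_regression()] for every (SNP, biomarker) pair and marks
#' SNPs that are strong instruments (partial F at or above the threshold)
#' for two or more biomarkers as pleiotropic.
#'
#' @param dosage matrix (individuals x SNPs) with SNP id column names.
#' @param biomarkers matrix (individuals x biomarkers) on the analysis
#'   scale, with biomarker names as column names (see
#'   [analysis_biomarkers()]).
#' @param covariates optional adjustment covariates.
#' @param f_threshold weak-instrument cutoff.
#' @return list with `table` (data.frame of all pairwise associations,
#'   including `strength`) and `pleiotropic` (named logical per SNP).
#' @export
pleiotropy_matrix <- function(dosage, biomarkers, covariates = NULL,
                              f_threshold = 10) {
  stopifnot(is.matrix(dosage), is.matrix(biomarkers) || is.data.frame(biomarkers))
  biomarkers <- as.matrix(biomarkers)
  if (ncol(biomarkers) < 2) stop("need at least two biomarkers")
  rows <- list()
  for (s in colnames(dosage)) {
    for (b in colnames(biomarkers)) {
      a <- exposure_regression(dosage[, s], biomarkers[, b], covariates,
                               snp_id = s, biomarker_name = b)
      rows[[length(rows) + 1]] <- data.frame(
        snp = s, biomarker = b, beta = a$beta, se = a$se,
        ci_low = a$ci[1], ci_high = a$ci[2], p = a$p, F = a$F,
        r2 = a$r2, n = a$n,
        strength = classify_instrument(a, f_threshold),
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  strong_counts <- tapply(tab$strength == "strong", tab$snp, sum)
  pleio <- strong_counts >= 2
  list(table = tab, pleiotropic = pleio[colnames(dosage)])
}

#' Write an instrument table as TSV
#'
#' Columns mirror the usual instrument-validation layout: SNP, alleles,
#' biomarker, per-allele beta with CI and p, F and R2.
#'
#' @param table the `table` element of [pleiotropy_matrix()].
#' @param snps SNP data.frame carrying `id`, `effect_allele`,
#'   `other_allele`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_instrument_tsv <- function(table, snps, path) {
  idx <- match(table$snp, snps$id)
  out <- data.frame(
    snp = table$snp,
    effect_allele = snps$effect_allele[idx],
    other_allele = snps$other_allele[idx],
    biomarker = table$biomarker,
    beta = table$beta, ci_low = table$ci_low, ci_high = table$ci_high,
    p = table$p, F = table$F, r2_pct = 100 * table$r2, n = table$n,
    strength = table$strength
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
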