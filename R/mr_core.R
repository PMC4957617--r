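# Two-sample ratio (Wald) instrumental-variable estimation.
#
# The gene->exposure association (per-allele beta, from the exposure
# sample) and the gene->outcome association (per-allele log-OR / log-HR,
# from the outcome sample) are combined into an SD-scaled causal effect:
# causal log-effect = scale_sd * log_gy / beta_gx. The default standard
# error is the first-order delta method (denominator uncertainty
# ignored), which is what reproduces published ratio-estimator intervals
# computed from per-allele components; second-order delta and Fieller
# intervals are available for weak-denominator settings.

#' SD-scaled Wald ratio causal estimate
#'
#' @param beta_gx per-effect-allele exposure effect (ng/mL per allele)
#'   from the exposure sample; must be non-zero.
#' @param se_gx its standard error (used by `"delta2"` / `"fieller"`; may
#'   be `NA` for `"delta1"`).
#' @param log_gy per-effect-allele log-OR or log-HR from the outcome
#'   sample.
#' @param se_gy its standard error.
#' @param scale_sd exposure SD used for scaling (ng/mL); the causal effect
#'   is reported per one SD increase in the exposure. Supplied externally
#'   (exposure sample or literature), never from the outcome sample.
#' @param se_method `"delta1"` (first-order delta, default), `"delta2"`
#'   (adds the denominator-uncertainty term) or `"fieller"` (interval from
#'   the ratio quadratic; unbounded when the instrument is too weak).
#' @param conf confidence level.
#' @param exposure,outcome,snp labels carried into the result.
#' @return object of class `wald_estimate`: `causal_log_effect` (per SD),
#'   `se`, `effect` (= exp, an OR or HR), `ci` (effect scale), the
#'   components, and a `weak_instrument` flag (|beta_gx/se_gx| < 2).
#' @export
wald_ratio <- function(beta_gx, se_gx = NA, log_gy, se_gy, scale_sd = 1,
                       se_method = c("delta1", "delta2", "fieller"),
                       conf = 0.95,
                       exposure = "exposure", outcome = "outcome", snp = "snp") {
  se_method <- match.arg(se_method)
  if (!is.finite(beta_gx) || abs(beta_gx) < 1e-12) stop("beta_gx must be non-zero")
  if (scale_sd <= 0) stop("scale_sd must be positive")
  if (se_gy <= 0) stop("se_gy must be positive")
  if (se_method != "delta1" && (is.na(se_gx) || se_gx <= 0)) {
    stop("se_gx required for ", se_method)
  }
  weak <- !is.na(se_gx) && se_gx > 0 && abs(beta_gx / se_gx) < 2
  if (weak) warning("weak instrument: |beta_gx / se_gx| < 2; ratio estimate may be unstable")

  z <- qnorm(1 - (1 - conf) / 2)
  est <- scale_sd * log_gy / beta_gx
  se1 <- scale_sd * se_gy / abs(beta_gx)
  se <- switch(se_method,
    delta1 = se1,
    delta2 = sqrt(se1^2 + (scale_sd * log_gy * se_gx / beta_gx^2)^2),
    fieller = se1 # point SE reported as first-order; the CI is Fieller's
  )
  if (se_method == "fieller") {
    # roots of (log_gy - r*beta_gx)^2 = z^2 (se_gy^2 + r^2 se_gx^2)
    a <- beta_gx^2 - z^2 * se_gx^2
    bq <- -2 * log_gy * beta_gx
    cq <- log_gy^2 - z^2 * se_gy^2
    disc <- bq^2 - 4 * a * cq
    if (a > 0 && disc >= 0) {
      r <- sort((-bq + c(-1, 1) * sqrt(disc)) / (2 * a))
      ci_log <- scale_sd * r
    } else {
      warning("Fieller interval unbounded (instrument too weak at this confidence level)")
      ci_log <- c(-Inf, Inf)
    }
  } else {
    ci_log <- est + c(-1, 1) * z * se
  }
  structure(list(
    exposure = exposure, outcome = outcome, snp = snp,
    scale_sd = scale_sd, causal_log_effect = est, se = se,
    effect = exp(est), ci = exp(ci_log), conf = conf, se_method = se_method,
    weak_instrument = weak,
    components = c(beta_gx = beta_gx, se_gx = se_gx, log_gy = log_gy, se_gy = se_gy)
  ), class = "wald_estimate")
}

#' @export
print.wald_estimate <- function(x, ...) {
  cat(sprintf(
    "causal effect of %s on %s per %g ng/mL (1 SD), instrument %s:\n  %.3f (%.0f%% CI %.3f, %.3f) [%s]%s\n",
    x$exposure, x$outcome, x$scale_sd, x$snp,
    x$effect, 100 * x$conf, x$ci[1], x$ci[2], x$se_method,
    if (x$weak_instrument) " WEAK INSTRUMENT" else ""
  ))
  invisible(x)
}

#' Harmonize effect-allele orientation between two summary records
#'
#' Aligns an outcome association to the exposure association's effect
#' allele, flipping the outcome log-effect sign (and effect-allele
#' frequency) when the effect/other alleles are swapped, accepting strand
#' complements, and flagging strand-ambiguous (A/T, C/G palindromic)
#' pairs.
#'
#' @param exposure,outcome lists (or one-row data.frames) carrying
#'   `effect_allele`, `other_allele`, an effect (`beta` or `log_effect`)
#'   and optionally `eaf`.
#' @return list with the aligned `outcome`, plus flags `flipped`,
#'   `strand_flipped` and `ambiguous`.
#' @export
harmonize <- function(exposure, outcome) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  al <- function(x) toupper(c(x$effect_allele, x$other_allele))
  ex <- al(exposure); ou <- al(outcome)
  if (any(!ex %in% names(comp)) || any(!ou %in% names(comp))) {
    stop("alleles must be A/C/G/T")
  }
  effect_field <- if (!is.null(outcome$log_effect)) "log_effect" else "beta"
  flip <- function(o) {
    o[[effect_field]] <- -o[[effect_field]]
    if (!is.null(o$eaf)) o$eaf <- 1 - o$eaf
    tmp <- o$effect_allele; o$effect_allele <- o$other_allele; o$other_allele <- tmp
    o
  }
  strand <- FALSE
  if (identical(ex, ou)) {
    flipped <- FALSE
  } else if (identical(ex, rev(ou))) {
    outcome <- flip(outcome); flipped <- TRUE
  } else if (identical(ex, unname(comp[ou]))) {
    flipped <- FALSE; strand <- TRUE
  } else if (identical(ex, unname(comp[rev(ou)]))) {
    outcome <- flip(outcome); flipped <- TRUE; strand <- TRUE
  } else {
    stop("incompatible allele sets: ", paste(ex, collapse = "/"), " vs ",
         paste(ou, collapse = "/"))
  }
  ambiguous <- ex[1] == comp[ex[2]]
  if (ambiguous) warning("strand-ambiguous (palindromic) pair: ", paste(ex, collapse = "/"))
  list(exposure = exposure, outcome = outcome,
       flipped = flipped, strand_flipped = strand, ambiguous = ambiguous)
}

#' Wald estimates for every validated instrument and pooled outcome
#'
#' One [wald_ratio()] per (instrument, exposure, outcome) triple, using
#' only instruments classified strong (partial F at or above
#' `f_threshold`). Multiple instruments for one exposure are reported
#' separately, never combined. Weak instruments are excluded with a
#' message; an empty intersection yields an empty table with a warning.
#'
#' @param instruments data.frame with columns `snp`, `biomarker`, `beta`,
#'   `se`, `F` (the [pleiotropy_matrix()] table).
#' @param outcomes data.frame with columns `snp`, `outcome`, `beta`, `se`
#'   (pooled log-ORs, or log-HRs for mortality outcomes).
#' @param sd_table named numeric: exposure SD (ng/mL, analysis scale) per
#'   biomarker.
#' @param f_threshold weak-instrument cutoff.
#' @param se_method passed to [wald_ratio()].
#' @return data.frame of class `mr_report_table`, one row per estimate.
#' @export
mr_report <- function(instruments, outcomes, sd_table, f_threshold = 10,
                      se_method = "delta1") {
  stopifnot(all(c("snp", "biomarker", "beta", "se", "F") %in% names(instruments)),
            all(c("snp", "outcome", "beta", "se") %in% names(outcomes)))
  rows <- list()
  for (i in seq_len(nrow(instruments))) {
    ins <- instruments[i, ]
    if (classify_instrument(ins$F, f_threshold) == "weak") {
      message("excluding weak instrument ", ins$snp, " for ", ins$biomarker,
              " (F = ", round(ins$F, 1), ")")
      next
    }
    if (!ins$biomarker %in% names(sd_table)) next
    hits <- outcomes[outcomes$snp == ins$snp, , drop = FALSE]
    for (j in seq_len(nrow(hits))) {
      w <- wald_ratio(ins$beta, ins$se, hits$beta[j], hits$se[j],
                      scale_sd = sd_table[[ins$biomarker]],
                      se_method = se_method,
                      exposure = ins$biomarker, outcome = hits$outcome[j],
                      snp = ins$snp)
      rows[[length(rows) + 1]] <- data.frame(
        snp = w$snp, exposure = w$exposure, outcome = w$outcome,
        scale_sd = w$scale_sd, causal_log_effect = w$causal_log_effect,
        se = w$se, effect = w$effect, ci_low = w$ci[1], ci_high = w$ci[2],
        se_method = w$se_method, F = ins$F, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    warning("no strong instrument / outcome pairs: empty MR report")
    out <- data.frame(snp = character(0), exposure = character(0),
                      outcome = character(0), scale_sd = numeric(0),
                      causal_log_effect = numeric(0), se = numeric(0),
                      effect = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), se_method = character(0),
                      F = numeric(0))
  } else {
    out <- do.call(rbind, rows)
  }
  class(out) <- c("mr_report_table", class(out))
  out
}

#' Read a summary-statistics TSV
#'
#' Expected columns: `snp`, `effect_allele`, `other_allele`, `beta` (or
#' log-OR), `se`, and optionally `eaf`, `n`, `trait`. This lets the MR
#' stage run from printed numbers alone.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_sumstats <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  need <- c("snp", "effect_allele", "other_allele", "beta", "se")
  if (!all(need %in% names(df))) {
    stop("summary-statistics TSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df
}
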