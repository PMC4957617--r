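# Synthetic genotype -> biomarker -> outcome cohort generator.
#
# Genotypes are built from two latent-Gaussian haplotypes per individual so
# that Hardy-Weinberg proportions hold exactly in expectation and pairwise
# LD (dosage r2) can be dialled in through a Gaussian-copula calibration.
# Biomarkers are linear in dosage plus confounders plus Gaussian residual,
# with the residual sized so the *total* SD matches the configured SD.
# Disease / grade / stage come from logistic models in the biomarkers;
# survival (among cases) from an exponential hazard scaled by the
# biomarkers, with independent uniform censoring.

#' Build and validate a simulation configuration
#'
#' The configuration fixes the full data-generating model for
#' [simulate_cohort()] and [simulate_consortium()]: SNPs (effect-allele
#' frequencies and optional pairwise LD targets), biomarker panel
#' (means/SDs in ng/mL; log-normal biomarkers are parameterised on the
#' natural-log scale), per-allele SNP effects, confounders, the logistic
#' disease/grade/stage model and the exponential survival model.
#'
#' @param n individuals per study.
#' @param snps data.frame with columns `id`, `effect_allele`,
#'   `other_allele`, `eaf` (effect-allele frequency in (0,1)). Dosage counts
#'   copies of the effect allele.
#' @param biomarkers data.frame with columns `name`, `mean`, `sd`,
#'   `log_normal` (logical). For `log_normal` biomarkers `mean`/`sd` (and
#'   the corresponding rows of `effects`) are on the natural-log scale; the
#'   simulated values are exponentiated back to ng/mL.
#' @param effects numeric matrix (SNPs x biomarkers) of per-effect-allele
#'   mean differences (ng/mL, or log units for log-normal biomarkers).
#' @param ld_r2 optional symmetric matrix of target pairwise dosage r2 in
#'   \[0,1\]; `NA` or 0 off-diagonal means independent. A target of exactly 1
#'   requires equal EAFs and duplicates the column.
#' @param confounders optional data.frame `name`, `mean`, `sd` of normal
#'   confounders (they affect biomarkers, never genotype).
#' @param confounder_effects matrix (confounders x biomarkers) of per-unit
#'   effects on each biomarker.
#' @param outcome list: `prevalence` (baseline disease probability at mean
#'   biomarker levels), `logor` (named per-biomarker log-OR per unit on the
#'   analysis scale), `grade_frac`/`grade_logor` and `stage_frac`/
#'   `stage_logor` (case-only contrasts: high-vs-low Gleason grade,
#'   advanced-vs-localised stage), optional `snp_logor` (named per-SNP
#'   direct log-OR: a deliberate exclusion-restriction violation for
#'   negative-control tests).
#' @param survival list: `baseline_hazard` (events per person-year at mean
#'   biomarker levels), `loghr` (named per-biomarker log-HR per unit),
#'   `followup` (uniform censoring window, years), optional `snp_loghr`
#'   (additive per-allele direct log-HR) and `snp_loghr_het` (extra log-HR
#'   for heterozygotes, to build non-additive mortality patterns).
#' @param n_studies number of studies for [simulate_consortium()].
#' @param tau2 between-study variance of per-(study, SNP) log-OR shifts.
#' @param dosage_error beta precision for imputation-style dosage noise;
#'   0 (default) keeps hard calls in {0,1,2}.
#' @param age_mean,age_sd age distribution of the cohort (years).
#' @param n_pcs number of null principal-component covariates to attach.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n,
                       snps,
                       biomarkers,
                       effects = NULL,
                       ld_r2 = NULL,
                       confounders = NULL,
                       confounder_effects = NULL,
                       outcome = list(),
                       survival = list(),
                       n_studies = 1L,
                       tau2 = 0,
                       dosage_error = 0,
                       age_mean = 62.1,
                       age_sd = 5.0,
                       n_pcs = 10L) {
  stopifnot(is.data.frame(snps), all(c("id", "effect_allele", "other_allele", "eaf") %in% names(snps)))
  stopifnot(is.data.frame(biomarkers), all(c("name", "mean", "sd") %in% names(biomarkers)))
  if (is.null(biomarkers$log_normal)) biomarkers$log_normal <- FALSE
  if (n < 1) stop("n must be >= 1")
  if (any(snps$eaf <= 0 | snps$eaf >= 1)) stop("all EAFs must lie strictly in (0,1)")
  if (any(snps$effect_allele == snps$other_allele)) stop("effect and other allele must differ")
  if (any(biomarkers$sd <= 0)) stop("biomarker SDs must be positive")
  if (anyDuplicated(snps$id)) stop("duplicated SNP ids")
  m <- nrow(snps); B <- nrow(biomarkers)

  if (is.null(effects)) effects <- matrix(0, m, B)
  effects <- as.matrix(effects)
  if (!all(dim(effects) == c(m, B))) stop("effects must be a (SNPs x biomarkers) matrix")
  dimnames(effects) <- list(snps$id, biomarkers$name)

  if (!is.null(ld_r2)) {
    ld_r2 <- as.matrix(ld_r2)
    if (!all(dim(ld_r2) == c(m, m))) stop("ld_r2 must be m x m")
    off <- ld_r2[upper.tri(ld_r2)]
    if (any(!is.na(off) & (off < 0 | off > 1))) stop("ld_r2 targets must lie in [0,1]")
  }

  if (!is.null(confounders)) {
    stopifnot(is.data.frame(confounders), all(c("name", "mean", "sd") %in% names(confounders)))
    if (is.null(confounder_effects)) {
      confounder_effects <- matrix(0, nrow(confounders), B)
    }
    confounder_effects <- as.matrix(confounder_effects)
    if (!all(dim(confounder_effects) == c(nrow(confounders), B))) {
      stop("confounder_effects must be (confounders x biomarkers)")
    }
    dimnames(confounder_effects) <- list(confounders$name, biomarkers$name)
  }

  outcome <- utils::modifyList(list(
    prevalence = 0.5,
    logor = setNames(numeric(B), biomarkers$name),
    grade_frac = 0.48, grade_logor = setNames(numeric(B), biomarkers$name),
    stage_frac = 0.24, stage_logor = setNames(numeric(B), biomarkers$name),
    snp_logor = NULL,
    confounder_logor = NULL
  ), outcome)
  survival <- utils::modifyList(list(
    baseline_hazard = 0.03,
    loghr = setNames(numeric(B), biomarkers$name),
    followup = 15,
    snp_loghr = NULL,
    snp_loghr_het = NULL
  ), survival)
  name_biom <- function(v) {
    if (is.null(names(v)) && length(v) == B) names(v) <- biomarkers$name
    stopifnot(all(names(v) %in% biomarkers$name))
    full <- setNames(numeric(B), biomarkers$name)
    full[names(v)] <- v
    full
  }
  outcome$logor <- name_biom(outcome$logor)
  outcome$grade_logor <- name_biom(outcome$grade_logor)
  outcome$stage_logor <- name_biom(outcome$stage_logor)
  survival$loghr <- name_biom(survival$loghr)
  stopifnot(outcome$prevalence > 0, outcome$prevalence < 1,
            survival$baseline_hazard > 0, survival$followup > 0,
            tau2 >= 0, n_studies >= 1, dosage_error >= 0)

  cfg <- structure(list(
    n = as.integer(n), snps = snps, biomarkers = biomarkers, effects = effects,
    ld_r2 = ld_r2, confounders = confounders, confounder_effects = confounder_effects,
    outcome = outcome, survival = survival, n_studies = as.integer(n_studies),
    tau2 = tau2, dosage_error = dosage_error,
    age_mean = age_mean, age_sd = age_sd, n_pcs = as.integer(n_pcs)
  ), class = "sim_config")

  # genetic + confounder variance must not exceed the configured total
  gv <- genetic_variance(cfg)
  cv <- confounder_variance(cfg)
  tot <- biomarkers$sd^2
  bad <- which(gv + cv > tot + 1e-10)
  if (length(bad)) {
    stop(sprintf(
      "implied genetic+confounder variance exceeds total variance for: %s",
      paste(biomarkers$name[bad], collapse = ", ")
    ))
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d individuals/study x %d studies, %d SNPs, %d biomarkers (tau2 = %g)\n",
    x$n, x$n_studies, nrow(x$snps), nrow(x$biomarkers), x$tau2
  ))
  invisible(x)
}

# Per-biomarker genetic variance beta' Sigma_G beta, where Sigma_G has
# 2p(1-p) on the diagonal and r * sd_i * sd_j off-diagonal under target LD.
genetic_variance <- function(config) {
  p <- config$snps$eaf
  sds <- sqrt(2 * p * (1 - p))
  m <- length(p)
  R <- diag(m)
  if (!is.null(config$ld_r2)) {
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i != j && !is.na(config$ld_r2[i, j]) && config$ld_r2[i, j] > 0) {
        R[i, j] <- sqrt(config$ld_r2[i, j])
      }
    }
  }
  Sigma <- R * tcrossprod(sds)
  apply(config$effects, 2, function(b) drop(crossprod(b, Sigma %*% b)))
}

confounder_variance <- function(config) {
  if (is.null(config$confounders)) {
    return(numeric(nrow(config$biomarkers)))
  }
  drop(crossprod(config$confounder_effects^2, config$confounders$sd^2))
}

## ---- LD machinery (Gaussian copula on haplotypes) -------------------------

# P(Z1 > t1, Z2 > t2) for standard bivariate normal with correlation rho.
orthant_p <- function(t1, t2, rho) {
  if (abs(rho) >= 1) {
    rho <- sign(rho) * (1 - 1e-9)
  }
  s <- sqrt(1 - rho^2)
  f <- function(z) stats::dnorm(z) * stats::pnorm((rho * z - t2) / s)
  stats::integrate(f, t1, Inf, rel.tol = 1e-10)$value
}

# Allele-level correlation induced by latent correlation rho at freqs p1, p2.
allele_cor_from_latent <- function(p1, p2, rho) {
  t1 <- qnorm(1 - p1); t2 <- qnorm(1 - p2)
  p11 <- orthant_p(t1, t2, rho)
  (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# Latent rho achieving a target allele correlation r (= dosage correlation,
# since a dosage is the sum of two iid haplotype alleles).
latent_rho_for <- function(p1, p2, r_target) {
  if (r_target == 0) return(0)
  # Frechet upper bound on the achievable allele correlation
  r_max <- (min(p1, p2) - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  if (r_target > r_max + 1e-8) {
    stop(sprintf(
      "target LD r = %.3f (r2 = %.3f) infeasible for EAFs %.3f/%.3f; achievable bound r = %.3f (r2 = %.3f)",
      r_target, r_target^2, p1, p2, r_max, r_max^2
    ))
  }
  f <- function(rho) allele_cor_from_latent(p1, p2, rho) - r_target
  uniroot(f, c(-0.9999, 0.9999), tol = 1e-8)$root
}

# Draw an n x m dosage matrix with HWE margins at `eaf` and pairwise dosage
# r2 near `ld_r2` (within +-0.05 at large n). Exact-duplicate columns are
# used for r2 == 1 with equal EAFs.
simulate_dosages <- function(n, eaf, ld_r2 = NULL) {
  m <- length(eaf)
  dup_of <- rep(NA_integer_, m)
  if (!is.null(ld_r2)) {
    for (j in seq_len(m)) for (i in seq_len(j - 1)) {
      if (!is.na(ld_r2[i, j]) && ld_r2[i, j] >= 1 - 1e-12 && is.na(dup_of[j])) {
        if (abs(eaf[i] - eaf[j]) > 1e-12) {
          stop("target r2 = 1 requires equal EAFs (achievable bound below 1 otherwise)")
        }
        dup_of[j] <- i
      }
    }
  }
  gen <- which(is.na(dup_of))
  k <- length(gen)
  L <- diag(k)
  if (!is.null(ld_r2) && k > 1) {
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (a < b) {
        i <- gen[a]; j <- gen[b]
        r2 <- ld_r2[i, j]
        if (!is.na(r2) && r2 > 0) {
          rho <- latent_rho_for(eaf[i], eaf[j], sqrt(r2))
          L[a, b] <- L[b, a] <- rho
        }
      }
    }
  }
  ch <- tryCatch(chol(L), error = function(e) NULL)
  if (is.null(ch)) { # pairwise calibration can leave L slightly non-PD
    ev <- eigen(L, symmetric = TRUE)
    ev$values <- pmax(ev$values, 1e-8)
    L2 <- ev$vectors %*% diag(ev$values) %*% t(ev$vectors)
    d <- sqrt(diag(L2))
    ch <- chol(L2 / tcrossprod(d))
  }
  thr <- qnorm(1 - eaf[gen])
  hap <- function() {
    Z <- matrix(rnorm(n * k), n, k) %*% ch
    sweep(Z, 2, thr, `>`) * 1L
  }
  D <- matrix(0, n, m)
  D[, gen] <- hap() + hap()
  for (j in which(!is.na(dup_of))) D[, j] <- D[, dup_of[j]]
  D
}

# Imputation-style dosage noise: observed dosage ~ 2 * Beta with mean g/2
# and precision kappa; hard calls untouched when kappa == 0.
blur_dosages <- function(D, kappa) {
  if (kappa <= 0) return(D)
  mu <- pmin(pmax(D / 2, 0.005), 0.995) # tight clamp keeps the EAF unbiased

  matrix(2 * rbeta(length(D), mu * kappa, (1 - mu) * kappa), nrow(D), ncol(D))
}

## ---- cohort construction --------------------------------------------------

# One study drawn with the *current* RNG stream. `shift_*` are per-SNP
# additive log-OR perturbations (between-study heterogeneity).
simulate_study <- function(config, study_label,
                           shift_dis = NULL, shift_grade = NULL, shift_stage = NULL) {
  n <- config$n
  m <- nrow(config$snps); B <- nrow(config$biomarkers)
  zero <- setNames(numeric(m), config$snps$id)
  shift_dis <- shift_dis %||% zero
  shift_grade <- shift_grade %||% zero
  shift_stage <- shift_stage %||% zero

  G <- simulate_dosages(n, config$snps$eaf, config$ld_r2)
  colnames(G) <- config$snps$id
  D <- blur_dosages(G, config$dosage_error)

  # confounders
  C <- NULL
  if (!is.null(config$confounders)) {
    C <- sapply(seq_len(nrow(config$confounders)), function(i) {
      rnorm(n, config$confounders$mean[i], config$confounders$sd[i])
    })
    C <- matrix(C, n); colnames(C) <- config$confounders$name
  }

  # biomarkers on the analysis scale (log for log-normal)
  gv <- genetic_variance(config)
  cv <- confounder_variance(config)
  resid_sd <- sqrt(config$biomarkers$sd^2 - gv - cv)
  Y <- matrix(0, n, B); colnames(Y) <- config$biomarkers$name
  for (b in seq_len(B)) {
    mu <- config$biomarkers$mean[b]
    eta <- mu + drop(G %*% config$effects[, b]) -
      sum(config$effects[, b] * 2 * config$snps$eaf)
    if (!is.null(C)) {
      eta <- eta + drop(C %*% config$confounder_effects[, b]) -
        sum(config$confounder_effects[, b] * config$confounders$mean)
    }
    Y[, b] <- eta + rnorm(n, 0, resid_sd[b])
  }
  Yc <- sweep(Y, 2, config$biomarkers$mean) # centred, analysis scale

  oc <- config$outcome
  lin <- qlogis(oc$prevalence) + drop(Yc %*% oc$logor[colnames(Y)]) +
    drop(G %*% shift_dis)
  if (!is.null(oc$snp_logor)) {
    lin <- lin + drop(G[, names(oc$snp_logor), drop = FALSE] %*% oc$snp_logor)
  }
  if (!is.null(C) && !is.null(oc$confounder_logor)) {
    Cc <- sweep(C, 2, config$confounders$mean)
    lin <- lin + drop(Cc[, names(oc$confounder_logor), drop = FALSE] %*% oc$confounder_logor)
  }
  disease <- rbinom(n, 1, plogis(lin))
  case <- disease == 1

  grade <- stage <- rep(NA_integer_, n)   # case-only contrasts
  if (any(case)) {
    lg <- qlogis(oc$grade_frac) + drop(Yc[case, , drop = FALSE] %*% oc$grade_logor[colnames(Y)]) +
      drop(G[case, , drop = FALSE] %*% shift_grade)
    grade[case] <- rbinom(sum(case), 1, plogis(lg))
    ls <- qlogis(oc$stage_frac) + drop(Yc[case, , drop = FALSE] %*% oc$stage_logor[colnames(Y)]) +
      drop(G[case, , drop = FALSE] %*% shift_stage)
    stage[case] <- rbinom(sum(case), 1, plogis(ls))
  }

  sv <- config$survival
  time <- rep(NA_real_, n); event <- rep(NA_integer_, n)
  if (any(case)) {
    lh <- drop(Yc[case, , drop = FALSE] %*% sv$loghr[colnames(Y)])
    if (!is.null(sv$snp_loghr)) {
      lh <- lh + drop(G[case, names(sv$snp_loghr), drop = FALSE] %*% sv$snp_loghr)
    }
    if (!is.null(sv$snp_loghr_het)) {
      H <- (round(G[case, names(sv$snp_loghr_het), drop = FALSE]) == 1) * 1
      lh <- lh + drop(H %*% sv$snp_loghr_het)
    }
    tt <- rexp(sum(case)) / (sv$baseline_hazard * exp(lh))
    cc <- runif(sum(case), 0, sv$followup)
    time[case] <- pmin(tt, cc)
    event[case] <- as.integer(tt <= cc)
  }

  # back-transform log-normal biomarkers to ng/mL for storage
  Ynat <- Y
  for (b in which(config$biomarkers$log_normal)) Ynat[, b] <- exp(Y[, b])

  covars <- data.frame(age = rnorm(n, config$age_mean, config$age_sd))
  if (config$n_pcs > 0) {
    P <- matrix(rnorm(n * config$n_pcs), n)
    colnames(P) <- paste0("pc", seq_len(config$n_pcs))
    covars <- cbind(covars, P)
  }
  if (!is.null(C)) covars <- cbind(covars, as.data.frame(C))

  structure(list(
    dosage = D, biomarkers = Ynat, biomarker_info = config$biomarkers,
    covariates = covars, disease = disease, grade = grade, stage = stage,
    time = time, event = event,
    study = factor(rep(study_label, n)), snps = config$snps
  ), class = "mr_cohort")
}

#' Simulate a single-study cohort
#'
#' Draws genotypes in Hardy-Weinberg proportions at the configured
#' effect-allele frequencies (pairwise LD induced through a Gaussian copula
#' on haplotypes), biomarkers as linear functions of dosage and confounders
#' with the residual sized to match the configured total SD, case/control
#' status, case-only grade and stage contrasts, and case-only exponential
#' survival with uniform censoring. The same `config` and `seed` always
#' yield identical output.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed.
#' @param study_label study name attached to every individual.
#' @return an object of class `mr_cohort`: dosage matrix (individuals x
#'   SNPs), biomarker matrix (ng/mL), covariates, binary `disease`,
#'   case-only `grade` (1 = Gleason >= 7) and `stage` (1 = advanced),
#'   case-only `time` (years) / `event`, and a `study` factor.
#' @export
simulate_cohort <- function(config, seed = 1L, study_label = "study1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  co <- simulate_study(config, study_label)
  validate_cohort(co)
}

#' Simulate a multi-study consortium
#'
#' Concatenates `config$n_studies` studies. Between-study heterogeneity is
#' induced by per-(study, SNP) additive shifts on the genotype log-OR,
#' drawn Normal(0, `tau2`) independently for the disease, grade and stage
#' models; with `tau2 = 0` studies differ only by sampling noise. With
#' `n_studies = 1` the result is identical to [simulate_cohort()] at the
#' same seed.
#'
#' @inheritParams simulate_cohort
#' @return an `mr_cohort` with one study label per study.
#' @export
simulate_consortium <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$n_studies
  if (k < 1) stop("n_studies must be >= 1")
  if (k == 1) return(simulate_cohort(config, seed))
  set.seed(seed)
  m <- nrow(config$snps)
  sdtau <- sqrt(config$tau2)
  shifts <- replicate(3, matrix(rnorm(k * m, 0, sdtau), k, m,
                                dimnames = list(NULL, config$snps$id)),
                      simplify = FALSE)
  parts <- lapply(seq_len(k), function(s) {
    simulate_study(config, sprintf("study%02d", s),
                   shift_dis = shifts[[1]][s, ],
                   shift_grade = shifts[[2]][s, ],
                   shift_stage = shifts[[3]][s, ])
  })
  validate_cohort(bind_cohorts(parts))
}

bind_cohorts <- function(parts) {
  structure(list(
    dosage = do.call(rbind, lapply(parts, `[[`, "dosage")),
    biomarkers = do.call(rbind, lapply(parts, `[[`, "biomarkers")),
    biomarker_info = parts[[1]]$biomarker_info,
    covariates = do.call(rbind, lapply(parts, `[[`, "covariates")),
    disease = unlist(lapply(parts, `[[`, "disease")),
    grade = unlist(lapply(parts, `[[`, "grade")),
    stage = unlist(lapply(parts, `[[`, "stage")),
    time = unlist(lapply(parts, `[[`, "time")),
    event = unlist(lapply(parts, `[[`, "event")),
    study = factor(unlist(lapply(parts, function(p) as.character(p$study)))),
    snps = parts[[1]]$snps
  ), class = "mr_cohort")
}

validate_cohort <- function(co) {
  stopifnot(inherits(co, "mr_cohort"))
  if (anyNA(co$study)) stop("missing study labels")
  d <- co$dosage[!is.na(co$dosage)]
  if (any(d < 0 | d > 2)) stop("dosages outside [0,2]")
  tt <- co$time[!is.na(co$time)]
  if (any(tt <= 0)) stop("non-positive survival times")
  co
}

#' @export
print.mr_cohort <- function(x, ...) {
  cat(sprintf(
    "mr_cohort: %d individuals, %d SNPs, %d biomarkers, %d studies (%d cases / %d controls)\n",
    nrow(x$dosage), ncol(x$dosage), ncol(x$biomarkers),
    nlevels(x$study), sum(x$disease == 1), sum(x$disease == 0)
  ))
  invisible(x)
}

#' Biomarker matrix on the analysis scale
#'
#' Returns the biomarker matrix with natural-log transform applied to the
#' biomarkers flagged `log_normal` (IGFBP-2 in the default panel), i.e. the
#' scale on which regressions are run.
#'
#' @param cohort an `mr_cohort`.
#' @return numeric matrix, one column per biomarker.
#' @export
analysis_biomarkers <- function(cohort) {
  Y <- cohort$biomarkers
  for (b in which(cohort$biomarker_info$log_normal)) Y[, b] <- log(Y[, b])
  Y
}
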