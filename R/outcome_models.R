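# Per-SNP genotype-outcome association models.
#
# Logistic regression for case-control, case-only grade and case-only
# stage contrasts, with a hand-rolled cluster sandwich (score
# contributions summed within study, g/(g-1) small-sample factor) when
# study labels are supplied. Survival uses Cox partial likelihood
# (Breslow ties) from the survival package, with additive or genotypic
# coding and a scaled-Schoenfeld proportional-hazards diagnostic.

# Cluster-robust covariance for a binomial glm: B M B with B the inverse
# information and M the cross-product of cluster-summed scores.
cluster_vcov_glm <- function(fit, cluster) {
  X <- model.matrix(fit)
  r <- fit$y - fit$fitted.values
  scores <- X * r
  g <- rowsum(scores, group = as.character(cluster))
  meat <- crossprod(g)
  B <- vcov(fit)
  ng <- nrow(g)
  (ng / (ng - 1)) * B %*% meat %*% B
}

#' Per-allele logistic genotype-outcome association
#'
#' Maximum-likelihood logistic regression of a binary outcome on additive
#' dosage plus covariates. With `cluster` supplied the standard error is
#' the cluster-robust sandwich (accounting for within-study correlation);
#' otherwise the model-based SE is used. The OR is per effect allele.
#'
#' @param dosage additive dosage vector.
#' @param outcome binary 0/1 outcome; rows with `NA` are dropped (so
#'   case-only contrasts can be passed directly).
#' @param covariates optional data.frame of adjustment covariates.
#' @param cluster optional cluster labels (study) for robust SEs.
#' @param snp_id,outcome_name labels carried into the result.
#' @return object of class `outcome_assoc` with `log_effect` (log-OR per
#'   effect allele), `se`, `p`, `or`, `ci`, `n_case`, `n_control`.
#' @export
logistic_assoc <- function(dosage, outcome, covariates = NULL, cluster = NULL,
                           snp_id = "snp", outcome_name = "case-control") {
  X <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  ok <- !is.na(dosage) & !is.na(outcome)
  if (!is.null(X)) ok <- ok & complete.cases(X)
  if (!is.null(cluster)) ok <- ok & !is.na(cluster)
  d <- dosage[ok]; y <- outcome[ok]
  if (length(unique(y)) < 2) stop("outcome has a single class")
  if (sd(d) == 0) stop("degenerate (monomorphic) dosage")
  dat <- data.frame(.y = y, dosage = d)
  if (!is.null(X)) dat <- cbind(dat, X[ok, , drop = FALSE])
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(as.formula(paste(".y ~", paste(setdiff(names(dat), ".y"), collapse = " + "))),
        family = binomial(), data = dat),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      } else if (grepl("algorithm did not converge", msg)) {
        # reported as an error below via fit$converged
        invokeRestart("muffleWarning")
      }
    }
  )
  if (sep_warn || !fit$converged || abs(coef(fit)["dosage"]) > 15) {
    stop("perfect separation / non-convergence: no estimate for ", snp_id)
  }
  b <- coef(fit)["dosage"]
  V <- if (is.null(cluster)) vcov(fit) else cluster_vcov_glm(fit, cluster[ok])
  se <- sqrt(V["dosage", "dosage"])
  z <- b / se
  structure(list(
    snp = snp_id, outcome = outcome_name, coding = "additive",
    log_effect = unname(b), se = se, p = 2 * pnorm(-abs(z)),
    or = exp(unname(b)), ci = exp(unname(b) + c(-1, 1) * 1.96 * se),
    n_case = sum(y == 1), n_control = sum(y == 0),
    cluster_used = !is.null(cluster), n_clusters = if (is.null(cluster)) NA_integer_ else length(unique(cluster[ok]))
  ), class = "outcome_assoc")
}

#' Cox genotype-survival association
#'
#' Cox proportional hazards partial-likelihood fit (Breslow tie handling)
#' of survival on genotype plus covariates, with cluster-robust standard
#' errors when study labels are given. `coding = "additive"` enters dosage
#' linearly; `coding = "genotypic"` fits heterozygote and
#' effect-homozygote indicators against the other-homozygote baseline,
#' exposing non-additive (heterozygote-extreme) mortality patterns.
#'
#' @param dosage additive dosage vector (hard-called for genotypic
#'   coding).
#' @param time follow-up time (years, from diagnosis); must be positive.
#' @param event event indicator (1 = death).
#' @param covariates optional adjustment covariates.
#' @param cluster optional study labels for robust SEs.
#' @param coding `"additive"` or `"genotypic"`.
#' @param ties tie-handling method passed to [survival::coxph()].
#' @param snp_id,outcome_name labels carried into the result.
#' @return `outcome_assoc` with `log_effect` (named vector under genotypic
#'   coding), `se`, `p`, `hr`, `n_events`, and the underlying fit (for
#'   [ph_check()]).
#' @export
cox_assoc <- function(dosage, time, event, covariates = NULL, cluster = NULL,
                      coding = c("additive", "genotypic"), ties = "breslow",
                      snp_id = "snp", outcome_name = "mortality-all-cause") {
  coding <- match.arg(coding)
  X <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  ok <- !is.na(dosage) & !is.na(time) & !is.na(event)
  if (!is.null(X)) ok <- ok & complete.cases(X)
  if (!is.null(cluster)) ok <- ok & !is.na(cluster)
  d <- dosage[ok]; tt <- time[ok]; ev <- event[ok]
  if (any(tt <= 0)) stop("all survival times must be positive")
  if (sum(ev) < 1) stop("no events")
  if (sd(d) == 0) stop("degenerate dosage")
  dat <- data.frame(.time = tt, .event = ev)
  if (coding == "additive") {
    dat$dosage <- d
    terms <- "dosage"
  } else {
    g <- round(d)
    dat$het <- as.integer(g == 1)
    dat$hom_effect <- as.integer(g == 2)
    terms <- c("het", "hom_effect")[c(any(g == 1), any(g == 2))]
    if (length(terms) == 0) stop("degenerate genotype classes")
  }
  if (!is.null(X)) dat <- cbind(dat, X[ok, , drop = FALSE])
  rhs <- c(terms, if (!is.null(X)) colnames(X))
  fml <- as.formula(paste("survival::Surv(.time, .event) ~", paste(rhs, collapse = " + ")))
  fit <- if (is.null(cluster)) {
    survival::coxph(fml, data = dat, ties = ties)
  } else {
    dat$.cluster <- as.character(cluster[ok])
    survival::coxph(fml, data = dat, ties = ties, cluster = .cluster)
  }
  sm <- summary(fit)
  secol <- if (!is.null(cluster)) "robust se" else "se(coef)"
  b <- coef(fit)[terms]
  se <- sm$coefficients[terms, secol]
  z <- b / se
  structure(list(
    snp = snp_id, outcome = outcome_name, coding = coding,
    log_effect = b, se = se, p = 2 * pnorm(-abs(z)),
    hr = exp(b), ci = cbind(exp(b - 1.96 * se), exp(b + 1.96 * se)),
    n_events = sum(ev), n_case = sum(ev), n_control = sum(ev == 0),
    cluster_used = !is.null(cluster), fit = fit
  ), class = "outcome_assoc")
}

#' @export
print.outcome_assoc <- function(x, ...) {
  eff <- exp(x$log_effect)
  lab <- if (!is.null(x$fit)) "HR" else "OR"
  for (i in seq_along(eff)) {
    nm <- if (length(eff) > 1) paste0(" [", names(eff)[i], "]") else ""
    cat(sprintf("%s ~ %s (%s)%s: %s %.3f, se(log) %.3f, p = %.3g\n",
                x$outcome, x$snp, x$coding, nm, lab, eff[i], x$se[i], x$p[i]))
  }
  invisible(x)
}

#' Proportional-hazards diagnostic
#'
#' Score test on scaled Schoenfeld residuals against a monotone transform
#' of time ([survival::cox.zph()]); `p < 0.05` flags a violation of the
#' proportional hazards assumption.
#'
#' @param assoc a fitted [cox_assoc()] result.
#' @param transform time transform: `"km"` (default), `"identity"` or
#'   `"log"`.
#' @return list with `p` (genotype term; first coefficient), `p_global`,
#'   the full `table`, `n_events` and `undefined` (TRUE when there are
#'   fewer than 10 events, in which case `p` is `NA`).
#' @export
ph_check <- function(assoc, transform = c("km", "identity", "log")) {
  transform <- match.arg(transform)
  stopifnot(inherits(assoc, "outcome_assoc"), !is.null(assoc$fit))
  if (assoc$n_events < 10) {
    warning("fewer than 10 events: proportional-hazards test undefined")
    return(list(p = NA_real_, p_global = NA_real_, table = NULL,
                n_events = assoc$n_events, undefined = TRUE))
  }
  zp <- survival::cox.zph(assoc$fit, transform = transform)
  tab <- zp$table
  term <- names(assoc$log_effect)[1]
  p <- if (term %in% rownames(tab)) tab[term, "p"] else tab[1, "p"]
  list(p = unname(p), p_global = unname(tab["GLOBAL", "p"]), table = tab,
       n_events = assoc$n_events, undefined = FALSE)
}

#' Per-study association table
#'
#' Fits [logistic_assoc()] for one outcome contrast in every study of a
#' consortium cohort, returning the exact input schema of [pool()]:
#' `study, snp, outcome, coding, beta, se, p, n_case, n_control`. Studies
#' where the fit fails (separation, single class) yield `NA` estimates and
#' are dropped, with a count recorded, by the pooling step.
#'
#' @param cohort an `mr_cohort` with multiple study labels.
#' @param snp SNP id (column of the dosage matrix).
#' @param outcome `"case-control"`, `"grade"` or `"stage"` (the latter two
#'   are case-only contrasts).
#' @param covariates character vector of covariate column names.
#' @return data.frame, one row per study.
#' @export
study_assoc_table <- function(cohort, snp, outcome = c("case-control", "grade", "stage"),
                              covariates = NULL) {
  outcome <- match.arg(outcome)
  y <- switch(outcome,
    "case-control" = cohort$disease,
    "grade" = cohort$grade,   # NA outside cases: case-only contrast
    "stage" = cohort$stage
  )
  rows <- lapply(levels(cohort$study), function(s) {
    idx <- cohort$study == s
    covs <- if (is.null(covariates)) NULL else cohort$covariates[idx, covariates, drop = FALSE]
    res <- tryCatch(
      logistic_assoc(cohort$dosage[idx, snp], y[idx], covariates = covs,
                     snp_id = snp, outcome_name = outcome),
      error = function(e) NULL
    )
    if (is.null(res)) {
      data.frame(study = s, snp = snp, outcome = outcome, coding = "additive",
                 beta = NA_real_, se = NA_real_, p = NA_real_,
                 n_case = sum(y[idx] == 1, na.rm = TRUE),
                 n_control = sum(y[idx] == 0, na.rm = TRUE))
    } else {
      data.frame(study = s, snp = snp, outcome = outcome, coding = "additive",
                 beta = res$log_effect, se = res$se, p = res$p,
                 n_case = res$n_case, n_control = res$n_control)
    }
  })
  do.call(rbind, rows)
}
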