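# Independent oracles and tiny configuration builders used across tests.

# Brute-force Cox partial likelihood for a single covariate, no ties:
# enumerate risk sets at each event time and maximise numerically.
brute_force_cox <- function(x, time, event) {
  ord <- order(time)
  x <- x[ord]; time <- time[ord]; event <- event[ord]
  stopifnot(!anyDuplicated(time))
  neg_logpl <- function(beta) {
    ll <- 0
    for (i in seq_along(time)) {
      if (event[i] == 1) {
        risk <- which(time >= time[i])
        ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
      }
    }
    -ll
  }
  optimize(neg_logpl, c(-8, 8), tol = 1e-9)$minimum
}

# Woolf closed-form 2x2 log-OR and SE: cells (a, b, c, d) =
# (exposed case, exposed control, unexposed case, unexposed control).
woolf <- function(a, b, c, d) {
  list(log_or = log(a * d / (b * c)), se = sqrt(1 / a + 1 / b + 1 / c + 1 / d))
}

# Minimal single-SNP, single-biomarker world.
tiny_config <- function(n = 1000, eaf = 0.3, beta = 0, sd = 1, mean = 0,
                        log_normal = FALSE, ...) {
  sim_config(
    n = n,
    snps = data.frame(id = "s1", effect_allele = "A", other_allele = "G", eaf = eaf),
    biomarkers = data.frame(name = "bm", mean = mean, sd = sd, log_normal = log_normal),
    effects = matrix(beta, 1, 1),
    ...
  )
}

two_snp_config <- function(n = 500, eaf = c(0.3, 0.3), r2 = NA, ...) {
  ld <- diag(2)
  ld[1, 2] <- ld[2, 1] <- r2
  sim_config(
    n = n,
    snps = data.frame(id = c("s1", "s2"), effect_allele = c("A", "C"),
                      other_allele = c("G", "T"), eaf = eaf),
    ld_r2 = ld,
    biomarkers = data.frame(name = "bm", mean = 0, sd = 1, log_normal = FALSE),
    effects = matrix(0, 2, 1),
    ...
  )
}
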