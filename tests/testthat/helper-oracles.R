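# Independent brute-force oracles used across the suite. These never call
# the implementation paths they check.

# two-sided Mann-Whitney p by full enumeration of group labelings
# (tie-free data only): count labelings whose U is at least as far from
# the null mean as the observed U.
mw_enum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  mu <- n1 * (n - n1) / 2
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  labelings <- utils::combn(n, n1)
  us <- apply(labelings, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# two-sided Fisher exact p by explicit enumeration of all tables with the
# observed margins, probabilities from log-binomial coefficients.
fisher_enum_p <- function(n11, n10, n01, n00) {
  m <- n11 + n10; n <- n01 + n00; k <- n11 + n01
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  probs <- exp(logp)
  obs <- probs[support == n11]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Cox partial log-likelihood for a binary covariate, tie-free data
# (Breslow = Efron when event times are distinct); maximized on a grid by
# optimize().
cox_brute_beta <- function(times, events, x) {
  ll <- function(b) {
    s <- 0
    for (i in which(events == 1)) {
      risk <- times >= times[i]
      s <- s + b * x[i] - log(sum(exp(b * x[risk])))
    }
    s
  }
  stats::optimize(ll, c(-10, 10), maximum = TRUE, tol = 1e-9)$maximum
}

# two-group log-rank via the textbook O-E / V sum over event times
logrank_oracle <- function(t1, e1, t2, e2) {
  times <- c(t1, t2); events <- c(e1, e2)
  g <- rep(c(1, 2), c(length(t1), length(t2)))
  obs1 <- 0; exp1 <- 0; v <- 0
  for (tt in sort(unique(times[events == 1]))) {
    at_risk <- times >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(events == 1 & times == tt)
    d1 <- sum(events == 1 & times == tt & g == 1)
    obs1 <- obs1 + d1
    exp1 <- exp1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (obs1 - exp1)^2 / v
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

# partial Spearman by rank-then-residualize: regress the ranks of x and y
# on the ranks of z, correlate the residuals.
partial_spearman_oracle <- function(x, y, z) {
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  stats::cor(stats::resid(stats::lm(rx ~ rz)),
             stats::resid(stats::lm(ry ~ rz)))
}

# median-of-ratios size factors by an explicit per-sample loop
size_factor_oracle <- function(m) {
  ref <- apply(m, 1, function(r) all(r > 0))
  geo <- apply(m[ref, , drop = FALSE], 1, function(r) prod(r)^(1 / length(r)))
  vapply(seq_len(ncol(m)), function(j) {
    stats::median(m[ref, j] / geo)
  }, numeric(1))
}

# a 2-gene mutation matrix realizing the 2x2 table (n11, n10, n01, n00)
make_mut_pair <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  a <- c(rep(1L, n11 + n10), rep(0L, n01 + n00))
  b <- c(rep(1L, n11), rep(0L, n10), rep(1L, n01), rep(0L, n00))
  mutation_matrix(matrix(c(a, b), nrow = 2, byrow = TRUE,
                         dimnames = list(c("gA", "gB"), paste0("s", 1:n))))
}

# small deterministic cohort built directly from matrices (no simulator)
make_toy_cohort <- function(n_samples = 8, genes = c("PD1", "g1", "g2"),
                            seed = 1) {
  set.seed(seed)
  samples <- paste0("s", seq_len(n_samples))
  ev <- matrix(rlnorm(length(genes) * n_samples, 3, 0.5),
               nrow = length(genes), dimnames = list(genes, samples))
  mv <- matrix(rbinom(length(genes) * n_samples, 1, 0.4),
               nrow = length(genes), dimnames = list(genes, samples))
  cl <- data.frame(sample_id = samples,
                   time = rexp(n_samples, 0.1),
                   event = rbinom(n_samples, 1, 0.7))
  cohort(expression_matrix(ev), mutation_matrix(mv), clinical_table(cl))
}
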