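# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive re-derivations (direct sums, full enumeration) and never
# call the implementation paths they check.

# Harmonic mean by direct reciprocal sum.
harmonic_mean_oracle <- function(x) length(x) / sum(1 / x)

# Exact two-sided Mann-Whitney p by full enumeration of all C(n1+n2, n1)
# group labelings (no ties assumed). U is counted for the x sample.
mw_enum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_of <- function(idx) {
    xs <- pooled[idx]
    ys <- pooled[-idx]
    sum(outer(xs, ys, ">"))
  }
  u_obs <- u_of(seq_len(n1))
  center <- n1 * (n - n1) / 2
  combos <- utils::combn(n, n1)
  us <- apply(combos, 2, u_of)
  mean(abs(us - center) >= abs(u_obs - center) - 1e-9)
}

# Exact two-sided paired Wilcoxon signed-rank p by enumeration of all 2^n
# sign assignments over the nonzero differences.
wilcox_sign_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  center <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  mean(abs(vs - center) >= abs(v_obs - center) - 1e-9)
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins (sum of probabilities <= the observed one).
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  k <- a + c          # col 1 total
  n_total <- a + b + c + d
  lo <- max(0, k - (n_total - m))
  hi <- min(m, k)
  probs <- stats::dhyper(lo:hi, m, n_total - m, k)
  p_obs <- stats::dhyper(a, m, n_total - m, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hand-rolled BH step-up.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Small fully-specified cohort used across IO and analysis tests.
tiny_cohort <- function(seed = 11, n = 60) {
  simulate_cohort(cohort_config(n_patients = n, seed = seed))
}

# Null configuration: every effect off, escape VAFs exchangeable between
# B2M and HLA mutations.
null_config <- function(n = 600, seed = 1) {
  cohort_config(
    n_patients = n, seed = seed,
    msi_enrichment_or = 1,
    burden_multiplier_b2m = 1, burden_multiplier_hla = 1,
    burden_multiplier_msi = 1,
    bias_strength = 0,
    vaf_model = list(b2m_shape1 = 8, b2m_shape2 = 2,
                     hla_low_shape1 = 2, hla_low_shape2 = 8,
                     hla_high_weight = 1)
  )
}
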