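# Independent oracles used across the suite.

# fold-change straight from the normalized 4-state weight table:
# expression ~ r * (P + alpha*beta*P*R) / Z, constitutive ~ r * P / (1 + P)
fc_from_weights <- function(alpha, beta, P, R) {
  Z <- 1 + P + R + beta * P * R
  ((P + alpha * beta * P * R) / Z) / (P / (1 + P))
}

# random log-uniform draws
rlu <- function(n, lo, hi) 10^runif(n, log10(lo), log10(hi))

draw_modes <- function(n, lo = 1e-2, hi = 1e2) {
  tibble::tibble(alpha = rlu(n, lo, hi), beta = rlu(n, lo, hi))
}

# numeric location of the sign change of dFC/dbeta over a log beta grid
alpha_c_numeric <- function(P, R, alpha_range = c(1e-6, 1),
                            betas = 10^seq(-3, 3, length.out = 41)) {
  trend <- function(a) {
    f <- fold_change(a, betas, P, R)
    f[length(f)] - f[1]
  }
  uniroot(trend, alpha_range, tol = 1e-12)$root
}

# qualitative behavior of an FC_max(P) titration: returns a region label
region_from_sweep <- function(alpha, beta,
                              P_grid = 10^seq(-6, 6, length.out = 200)) {
  fc <- fc_max_thermo(alpha, beta, P_grid)
  lo <- fc[1]; hi <- fc[length(fc)]   # limits alpha*beta and alpha
  up <- all(diff(fc) >= -1e-12)
  down <- all(diff(fc) <= 1e-12)
  if (lo < 1 && hi < 1) {
    if (down) "blue" else "purple"
  } else if (lo > 1 && hi > 1) {
    if (up) "gray" else "yellow"
  } else if (lo > 1 && hi < 1) {
    "red"
  } else if (lo < 1 && hi > 1) {
    "green"
  } else {
    "boundary"
  }
}

# default finite-R response-time rate template (promoter fast vs dilution)
finite_r_rates <- function(alpha, beta, s = 100, R = 1, gamma = 1) {
  kinetic_rates(kon_p = s, koff_p = s, kon_tf = R * s, koff_tf = s,
                r = s, gamma = gamma, alpha = alpha, beta = beta)
}
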