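# Closed linear moment system for the protein copy number.
#
# Unknowns per promoter state i: pi_i, m_i = <n 1_i>, s_i = <n^2 1_i>.
# Production events add one protein simultaneously with the transitions
# carrying them (rnap -> empty at r, cobound -> tf at alpha*r); death is
# gamma per molecule. The system is block-triangular: solve pi, then m,
# then s.
moment_system <- function(rates) {
  A <- build_generator(rates)
  B <- production_matrix(rates)
  g <- rates$gamma
  pi <- promoter_ss_vec(rates)
  m <- tryCatch(
    solve(g * diag(4) - t(A), t(B) %*% pi),
    error = function(e) stop("moment system singular: ", conditionMessage(e),
                             call. = FALSE))
  s <- solve(2 * g * diag(4) - t(A), g * m + t(B) %*% (2 * m + pi))
  mean <- sum(m)
  m2 <- sum(s)
  list(pi = pi, m = drop(m), s = drop(s), mean = mean, var = m2 - mean^2)
}

#' Steady-state protein moments of the kinetic model
#'
#' Mean, variance, Fano factor and coefficient of variation of the protein
#' copy number, from the exact closed linear system for the promoter-state
#' probabilities and the state-conditioned first and second moments (no
#' simulation, no closure approximation). Production increments the count
#' simultaneously with the initiation transitions; death is `gamma` per
#' molecule.
#'
#' @param rates A [kinetic_rates()] object with `gamma > 0` and nonzero
#'   constitutive expression.
#' @return A one-row tibble: `mean`, `variance`, `fano`, `cv`.
#' @examples
#' kr <- kinetic_rates(100, 100, 0, 100, 100, 1)
#' protein_moments(kr)  # constitutive gene
#' @export
protein_moments <- function(rates) {
  stopifnot(inherits(rates, "kinetic_rates"))
  if (rates$r <= 0 || rates$kon_p <= 0) {
    stop("no production (r = 0 or kon_p = 0): moments degenerate.",
         call. = FALSE)
  }
  ms <- moment_system(rates)
  tibble::tibble(mean = ms$mean, variance = ms$var,
                 fano = ms$var / ms$mean, cv = sqrt(ms$var) / ms$mean)
}

#' Closed-form Fano factor at saturating TF
#'
#' At saturating TF the promoter reduces to the two states TF-bound and
#' co-bound and the Fano factor has the closed form
#' `1 - alpha*beta*V2 * beta*P / ((1 + alpha*beta*V2 + beta*P) *
#' (1 + alpha*beta*V2 + beta*P + beta*V4))` with `V2 = r/koff_p` and
#' `V4 = gamma/koff_p`. Sub-Poissonian (`< 1`) because each initiation
#' ejects the polymerase, anti-correlating successive productions. With
#' `alpha = beta = 1` this is the constitutive Fano factor.
#'
#' Provided as an analytic cross-check of [protein_moments()]; the moment
#' system, not this formula, is the implementation.
#'
#' @inheritParams fc_max_kinetic
#' @param V4 Ratio `gamma/koff_p` (>= 0).
#' @return Fano factor (dimensionless, in (0, 1]). Vectorized.
#' @export
fano_max_kinetic <- function(alpha, beta, P, V2, V4) {
  check_mode(alpha, beta)
  check_vec(P, "P", min = 0)
  check_vec(V2, "V2", min = 0)
  check_vec(V4, "V4", min = 0)
  abv <- alpha * beta * V2
  1 - abv * beta * P / ((1 + abv + beta * P) * (1 + abv + beta * P + beta * V4))
}

#' Fold-change in expression noise (CV) under regulation
#'
#' Ratio of the regulated CV to the constitutive CV of the same promoter
#' (`kon_tf = 0`). Satisfies the identity
#' `CV_reg / CV_0 = FC^(-1/2) * (Fano_reg / Fano_0)^(1/2)` exactly, since
#' `CV^2 = Fano / mean`.
#'
#' @param rates A [kinetic_rates()] object.
#' @return A one-row tibble: `cv_fc` (the CV ratio), `fc` (fold-change in
#'   mean), `fano_ratio`.
#' @export
cv_fold_change <- function(rates) {
  stopifnot(inherits(rates, "kinetic_rates"))
  reg <- protein_moments(rates)
  con <- protein_moments(update_rates(rates, kon_tf = 0))
  tibble::tibble(cv_fc = reg$cv / con$cv,
                 fc = reg$mean / con$mean,
                 fano_ratio = reg$fano / con$fano)
}
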