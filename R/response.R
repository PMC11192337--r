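# 8-dimensional linear ODE for (pi_i(t), m_i(t)); production feeds the
# first moments through the productive transition rates.
response_matrix <- function(rates) {
  A <- build_generator(rates)
  B <- production_matrix(rates)
  M <- matrix(0, 8, 8)
  M[1:4, 1:4] <- t(A)
  M[5:8, 5:8] <- t(A) - rates$gamma * diag(4)
  M[5:8, 1:4] <- t(B)
  M
}

# mean protein trajectory evaluator; eigendecomposition when well
# conditioned, Matrix::expm fallback
mean_evaluator <- function(M, x0) {
  eg <- tryCatch(eigen(M), error = function(e) NULL)
  use_eigen <- !is.null(eg) &&
    is.finite(rcond <- tryCatch(1 / kappa(eg$vectors), error = function(e) 0)) &&
    rcond > 1e-10
  if (use_eigen) {
    coef <- solve(eg$vectors, x0)
    w <- colSums(matrix(eg$vectors[5:8, ], nrow = 4)) * coef
    function(t) Re(sum(w * exp(eg$values * t)))
  } else {
    function(t) sum((Matrix::expm(M * t) %*% x0)[5:8])
  }
}

#' Response time of a regulated gene
#'
#' The gene expresses constitutively; at `t = 0` the TF is switched on
#' (instantly active at its full binding propensity `kon_tf`). The mean
#' expression then relaxes to the regulated steady state; the response time
#' is the first time the mean crosses halfway between the constitutive and
#' the regulated level, in units of the cell-cycle time `T_cc = log(2)/gamma`
#' (so a constitutive step change scores exactly 1). Computed by integrating
#' the exact linear ODE for the promoter-state probabilities and
#' state-conditioned first moments, with bisection at relative tolerance
#' `1e-6` on the crossing.
#'
#' @param rates A [kinetic_rates()] object; `kon_tf` is the post-switch TF
#'   binding propensity.
#' @param saturating_tf If `TRUE`, override `kon_tf` with
#'   `saturating_factor * koff_tf` (the saturating-TF limit).
#' @param saturating_factor Multiplier defining "saturating" (default `1e6`;
#'   results should be insensitive to a 10x increase).
#' @param fc_tolerance Minimum `|FC - 1|` for the response time to be
#'   defined; below it the midpoint is meaningless and an error is thrown
#'   (as `R -> 0` the regulated and constitutive states coincide).
#' @param t_max_cc Scan horizon in cell cycles (default 60).
#' @return Response time in cell cycles (scalar).
#' @examples
#' kr <- kinetic_rates(100, 100, 100, 100, 100, 1, alpha = 0.2, beta = 1)
#' response_time(kr)  # ~1 cell cycle
#' @export
response_time <- function(rates, saturating_tf = FALSE,
                          saturating_factor = 1e6,
                          fc_tolerance = 1e-6, t_max_cc = 60) {
  stopifnot(inherits(rates, "kinetic_rates"))
  if (saturating_tf) {
    rates <- update_rates(rates, kon_tf = saturating_factor * rates$koff_tf)
  }
  if (rates$kon_tf <= 0) {
    stop("kon_tf = 0: nothing is switched on at t = 0.", call. = FALSE)
  }
  con <- update_rates(rates, kon_tf = 0)
  ms0 <- moment_system(con)
  msI <- moment_system(rates)
  if (abs(msI$mean / ms0$mean - 1) < fc_tolerance) {
    stop("response time undefined: |FC - 1| < ", fc_tolerance,
         " (regulated state indistinguishable from constitutive).",
         call. = FALSE)
  }
  mid <- (ms0$mean + msI$mean) / 2
  M <- response_matrix(rates)
  x0 <- c(ms0$pi, ms0$m)
  mean_at <- mean_evaluator(M, x0)
  tcc <- log(2) / rates$gamma
  ## dense scan (log-spaced early times capture fast promoter transients,
  ## linear tail the gamma relaxation), then bisection
  ts <- unique(sort(c(0, 10^seq(log10(tcc) - 8, log10(t_max_cc * tcc),
                                length.out = 300),
                      seq(0, t_max_cc * tcc, length.out = 200))))
  f <- vapply(ts, mean_at, numeric(1)) - mid
  cross <- which(f[-1] * f[-length(f)] <= 0)
  if (!length(cross)) {
    stop("no midpoint crossing within ", t_max_cc, " cell cycles.",
         call. = FALSE)
  }
  i <- cross[1]
  root <- uniroot(function(t) mean_at(t) - mid, c(ts[i], ts[i + 1]),
                  tol = 1e-6 * tcc)$root
  root / tcc
}

#' Mean-expression trajectory after TF switch-on
#'
#' Deterministic mean protein number versus time for the switch-on
#' experiment of [response_time()], useful for plotting relaxation curves.
#'
#' @inheritParams response_time
#' @param times Vector of times (in cell cycles) at which to evaluate.
#' @return A tibble with columns `time_cc` and `mean`.
#' @export
mean_trajectory <- function(rates, times, saturating_tf = FALSE,
                            saturating_factor = 1e6) {
  stopifnot(inherits(rates, "kinetic_rates"))
  if (saturating_tf) {
    rates <- update_rates(rates, kon_tf = saturating_factor * rates$koff_tf)
  }
  con <- update_rates(rates, kon_tf = 0)
  ms0 <- moment_system(con)
  M <- response_matrix(rates)
  mean_at <- mean_evaluator(M, c(ms0$pi, ms0$m))
  tcc <- log(2) / rates$gamma
  tibble::tibble(time_cc = times,
                 mean = vapply(times * tcc, mean_at, numeric(1)))
}
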