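#' Context for a mean-field autoregulated gene
#'
#' The gene's own protein is the TF, so the TF level is not a free parameter:
#' it solves `R = <n(R)> / k_D,TF` with `<n(R)>` the mean-field expression
#' level. The mean level uses the thermodynamic occupancy (fast-promoter
#' assumption): `<n(R)> = expression_scale * (P + alpha*beta*P*R) /
#' (1 + P + R + beta*P*R)`, where `expression_scale = r/gamma` is the mean
#' copy number a fully RNAP-occupied promoter would sustain.
#'
#' @param alpha,beta Regulatory mode of the TF (> 0).
#' @param P Dimensionless promoter strength (>= 0).
#' @param expression_scale Maximal mean TF copy number `r/gamma`
#'   (molecules, > 0; default 100).
#' @param kd_tf TF-DNA dissociation scale in molecules (> 0; default 50).
#' @param gamma Dilution rate, sets the cell-cycle clock for
#'   [autoreg_response_time()] (default 1).
#' @return An `autoreg_context` object.
#' @export
autoreg_context <- function(alpha, beta, P, expression_scale = 100,
                            kd_tf = 50, gamma = 1) {
  check_mode(alpha, beta)
  check_scalar(P, "P", min = 0)
  check_scalar(expression_scale, "expression_scale", min = 0, strict = TRUE)
  check_scalar(kd_tf, "kd_tf", min = 0, strict = TRUE)
  check_scalar(gamma, "gamma", min = 0, strict = TRUE)
  structure(list(alpha = alpha, beta = beta, P = P,
                 expression_scale = expression_scale, kd_tf = kd_tf,
                 gamma = gamma),
            class = "autoreg_context")
}

# mean-field mean expression at TF level R
autoreg_mean <- function(ctx, R) {
  with(ctx, expression_scale * (P + alpha * beta * P * R) /
         (1 + P + R + beta * P * R))
}

#' Self-consistent TF level of an autoregulated gene
#'
#' Fixed point of `R = <n(R)> / k_D,TF`, found by damped iteration with a
#' bracketed root fall-back; uniqueness is checked by a sign scan of
#' `<n(R)>/k_D,TF - R` over the bracket (the map is bounded, so a bracket
#' always exists).
#'
#' @param ctx An [autoreg_context()].
#' @param damping Damping factor of the fixed-point iteration in (0, 1].
#' @param tol Relative convergence tolerance.
#' @return The fixed-point TF level `R*` (dimensionless).
#' @export
autoreg_fixed_point <- function(ctx, damping = 0.5, tol = 1e-12) {
  stopifnot(inherits(ctx, "autoreg_context"))
  g <- function(R) autoreg_mean(ctx, R) / ctx$kd_tf
  hi <- ctx$expression_scale * max(1, ctx$alpha * ctx$beta) / ctx$kd_tf + 1
  R <- g(0)
  for (i in seq_len(200)) {
    Rn <- (1 - damping) * R + damping * g(R)
    if (abs(Rn - R) <= tol * (abs(R) + tol)) {
      R <- Rn
      break
    }
    R <- Rn
  }
  if (abs(g(R) - R) > 1e-8 * (1 + R)) {
    ## damped iteration did not settle; bracketed root
    h <- function(R) g(R) - R
    if (h(0) < 0 || h(hi) > 0) {
      stop("no fixed point in bracket [0, ", signif(hi, 4),
           "]: h(0) = ", signif(h(0), 4), ", h(hi) = ", signif(h(hi), 4),
           call. = FALSE)
    }
    R <- uniroot(h, c(0, hi), tol = 1e-12)$root
  }
  ## uniqueness on the bracket
  grid <- seq(0, hi, length.out = 201)
  sgn <- sign(g(grid) - grid)
  flips <- sum(diff(sgn[sgn != 0]) != 0)
  if (flips > 1) {
    warning("multiple sign changes of the self-consistency map detected; ",
            "returning the fixed point reached from R = 0.", call. = FALSE)
  }
  R
}

#' Fold-change of an autoregulated gene
#'
#' Mean-field fold-change: expression at the self-consistent TF level
#' divided by the constitutive level `expression_scale * P/(1 + P)`.
#' As `P -> 0` the gene makes too little TF to regulate itself and the
#' fold-change tends to 1 for every `(alpha, beta)`.
#'
#' @inheritParams autoreg_fixed_point
#' @return Fold-change (dimensionless).
#' @examples
#' autoreg_fold_change(autoreg_context(0.5, 10, P = 1e-4))  # ~1
#' @export
autoreg_fold_change <- function(ctx, damping = 0.5) {
  stopifnot(inherits(ctx, "autoreg_context"))
  if (ctx$P == 0) return(1)
  n0 <- ctx$expression_scale * ctx$P / (1 + ctx$P)
  autoreg_mean(ctx, autoreg_fixed_point(ctx, damping = damping)) / n0
}

#' Numeric critical acceleration for an autoregulated gene
#'
#' The `alpha` at which the autoregulatory fold-change-versus-beta curve
#' switches from monotone decreasing to monotone increasing, located by the
#' sign change of `FC(beta_max) - FC(beta_min)` over a log-spaced beta grid
#' and bisection in `alpha`. With the feedback severed (`pin_R` set), the
#' same scan reduces to the closed form `P/(1 + P + R)` of
#' [alpha_critical()].
#'
#' @param P Promoter strength (> 0).
#' @param expression_scale,kd_tf,gamma As in [autoreg_context()].
#' @param beta_range Log10 range of the beta scan (default `c(-2, 2)`).
#' @param n_beta Points in the beta grid (default 25).
#' @param alpha_range Bisection bounds for `alpha` (default `c(1e-6, 1)`).
#' @param pin_R If non-`NULL`, sever the feedback and hold the TF level at
#'   this fixed `R` (diagnostic mode).
#' @return The critical acceleration `alpha_c`.
#' @export
autoreg_alpha_critical <- function(P, expression_scale = 100, kd_tf = 50,
                                   gamma = 1, beta_range = c(-2, 2),
                                   n_beta = 25, alpha_range = c(1e-6, 1),
                                   pin_R = NULL) {
  check_scalar(P, "P", min = 0, strict = TRUE)
  betas <- 10^seq(beta_range[1], beta_range[2], length.out = n_beta)
  fc_of <- function(a, b) {
    if (is.null(pin_R)) {
      autoreg_fold_change(autoreg_context(a, b, P, expression_scale, kd_tf,
                                          gamma))
    } else {
      fold_change(a, b, P, pin_R)
    }
  }
  trend <- function(a) {
    f <- vapply(betas, function(b) fc_of(a, b), numeric(1))
    f[length(f)] - f[1]
  }
  lo <- trend(alpha_range[1]); hi <- trend(alpha_range[2])
  if (lo * hi > 0) {
    stop("no monotonicity switch in alpha range [", alpha_range[1], ", ",
         alpha_range[2], "]: trend endpoints ", signif(lo, 3), ", ",
         signif(hi, 3), call. = FALSE)
  }
  uniroot(trend, alpha_range, tol = 1e-10)$root
}

#' Response time of an autoregulated gene
#'
#' Deterministic mean-field relaxation: starting from the constitutive level
#' the protein obeys `dn/dt = gamma * (expression_scale * phi(n/k_D,TF) - n)`
#' with `phi` the regulated occupancy; the response time is the first
#' midpoint crossing between the constitutive and the self-consistent
#' steady-state level, in cell cycles. Integrated with classic RK4 and a
#' step of `1e-3` cell cycles, with linear interpolation at the crossing.
#'
#' @inheritParams autoreg_fixed_point
#' @param fc_tolerance Minimum `|FC - 1|` for the time to be defined.
#' @param t_max_cc Integration horizon in cell cycles.
#' @return Response time in cell cycles.
#' @export
autoreg_response_time <- function(ctx, fc_tolerance = 1e-6, t_max_cc = 50) {
  stopifnot(inherits(ctx, "autoreg_context"))
  fc <- autoreg_fold_change(ctx)
  if (abs(fc - 1) < fc_tolerance) {
    stop("response time undefined: |FC - 1| < ", fc_tolerance, call. = FALSE)
  }
  n0 <- ctx$expression_scale * ctx$P / (1 + ctx$P)
  ninf <- autoreg_mean(ctx, autoreg_fixed_point(ctx))
  mid <- (n0 + ninf) / 2
  g <- ctx$gamma
  f <- function(n) g * (autoreg_mean(ctx, n / ctx$kd_tf) - n)
  tcc <- log(2) / g
  h <- 1e-3 * tcc
  n <- n0
  t <- 0
  for (i in seq_len(ceiling(t_max_cc * tcc / h))) {
    k1 <- f(n); k2 <- f(n + h / 2 * k1); k3 <- f(n + h / 2 * k2)
    k4 <- f(n + h * k3)
    nn <- n + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if ((n - mid) * (nn - mid) <= 0 && i > 1) {
      return((t + h * (mid - n) / (nn - n)) / tcc)
    }
    n <- nn
    t <- t + h
  }
  stop("no midpoint crossing within ", t_max_cc, " cell cycles.",
       call. = FALSE)
}

#' Autoregulatory fold-change across promoter strengths
#'
#' Sweeps `P` and returns the mean-field fold-change curve, the autoreg
#' analogue of an `FC_max(P)` titration. Useful for reproducing the
#' region-map behavior (all curves approach 1 as `P -> 0`).
#'
#' @param modes A data frame with columns `alpha` and `beta` (one row per
#'   TF mode).
#' @param P Vector of promoter strengths.
#' @inheritParams autoreg_context
#' @return A tibble with columns `alpha`, `beta`, `P`, `fc`.
#' @export
autoreg_fc_curve <- function(modes, P, expression_scale = 100, kd_tf = 50,
                             gamma = 1) {
  stopifnot(is.data.frame(modes), all(c("alpha", "beta") %in% names(modes)))
  tidyr::crossing(dplyr::as_tibble(modes[c("alpha", "beta")]), P = P) |>
    dplyr::mutate(fc = purrr::pmap_dbl(
      list(.data$alpha, .data$beta, .data$P),
      function(a, b, p) {
        autoreg_fold_change(autoreg_context(a, b, p, expression_scale,
                                            kd_tf, gamma))
      }))
}
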