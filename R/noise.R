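# fast internal CV: moment system without object/tibble overhead
cv_fast <- function(kon_p, koff_p, kon_tf, koff_tf, r, gamma, alpha, beta) {
  kp <- koff_p / beta
  kt <- koff_tf / beta
  A <- matrix(c(-(kon_p + kon_tf), kon_p, kon_tf, 0,
                koff_p + r, -(koff_p + r + kon_tf), 0, kon_tf,
                koff_tf, 0, -(koff_tf + kon_p), kon_p,
                0, kt, kp + alpha * r, -(kt + kp + alpha * r)),
              4, 4, byrow = TRUE)
  pi <- qr.solve(rbind(t(A), rep(1, 4)), c(0, 0, 0, 0, 1))
  ## production inflow: into empty from rnap (r), into tf from cobound
  inflow <- c(r * pi[2], 0, alpha * r * pi[4], 0)
  m <- solve(gamma * diag(4) - t(A), inflow)
  inflow2 <- c(r * (2 * m[2] + pi[2]), 0, alpha * r * (2 * m[4] + pi[4]), 0)
  s <- solve(2 * gamma * diag(4) - t(A), gamma * m + inflow2)
  mean <- sum(m)
  v <- sum(s) - mean^2
  c(cv = sqrt(v) / mean, mean = mean)
}

#' Default kinetic template for noise scans
#'
#' Rates used by [cv_profile()] and [noise_phase_diagram()] unless
#' overridden: `koff_p = r = 100 * gamma` (so `V2 = 1`, `V4 = 0.01`),
#' `koff_tf = 10 * gamma`, `kon_p = P * koff_p`. Time unit is `1/gamma`.
#'
#' @param P Dimensionless promoter strength.
#' @param alpha,beta Regulatory mode.
#' @param gamma Dilution rate (default 1).
#' @param koff_p,r,koff_tf Optional overrides.
#' @return A [kinetic_rates()] object with `kon_tf = 0` (set by the scan).
#' @export
noise_template <- function(P, alpha = 1, beta = 1, gamma = 1,
                           koff_p = 100 * gamma, r = 100 * gamma,
                           koff_tf = 10 * gamma) {
  kinetic_rates(kon_p = P * koff_p, koff_p = koff_p, kon_tf = 0,
                koff_tf = koff_tf, r = r, gamma = gamma,
                alpha = alpha, beta = beta)
}

#' Fold-change-in-CV profile across TF concentration
#'
#' Computes the ratio of the regulated to the constitutive CV of protein
#' copy number on a log-spaced grid of TF binding rates `kon_tf`, the
#' x-axis along which noise phenotypes are read off. The grid must span at
#' least 6 decades; if the top-decade endpoint is not within 1% of the
#' saturating-TF limit, the grid is extended upward automatically (the
#' profile must plateau for classification to mean anything).
#'
#' @param rates A [kinetic_rates()] template (its `kon_tf` is ignored);
#'   see [noise_template()].
#' @param kon_tf_grid Optional explicit grid (log-spaced, length >= 8).
#'   Default: 64 points over 8 decades centred on `koff_tf`.
#' @param n_points,n_decades Grid size and span used when `kon_tf_grid` is
#'   not given.
#' @param max_extra_decades Cap on automatic upward extension.
#' @return A tibble (class `noise_profile`) with columns `kon_tf`, `cv_fc`;
#'   attributes carry the template, the saturating limit and the
#'   fold-change at saturation.
#' @export
cv_profile <- function(rates, kon_tf_grid = NULL, n_points = 64,
                       n_decades = 8, max_extra_decades = 6) {
  stopifnot(inherits(rates, "kinetic_rates"))
  if (is.null(kon_tf_grid)) {
    kon_tf_grid <- 10^seq(log10(rates$koff_tf) - n_decades / 2,
                          log10(rates$koff_tf) + n_decades / 2,
                          length.out = n_points)
  }
  if (length(kon_tf_grid) < 8) {
    stop("kon_tf grid must have at least 8 points.", call. = FALSE)
  }
  if (diff(range(log10(kon_tf_grid))) < 6) {
    stop("kon_tf grid must span at least 6 decades.", call. = FALSE)
  }
  if (is.unsorted(kon_tf_grid, strictly = TRUE)) {
    stop("kon_tf grid must be strictly increasing.", call. = FALSE)
  }
  cv_at <- function(kt) {
    cv_fast(rates$kon_p, rates$koff_p, kt, rates$koff_tf, rates$r,
            rates$gamma, rates$alpha, rates$beta)
  }
  cv0 <- cv_at(0)
  sat <- cv_at(1e9 * rates$koff_tf)
  per_decade <- length(kon_tf_grid) / diff(range(log10(kon_tf_grid)))
  vals <- vapply(kon_tf_grid, function(k) cv_at(k)[["cv"]], numeric(1))
  extra <- 0
  while (abs(vals[length(vals)] / sat[["cv"]] - 1) > 0.01 &&
         extra < max_extra_decades) {
    top <- log10(kon_tf_grid[length(kon_tf_grid)])
    add <- 10^seq(top + 1 / per_decade, top + 1, length.out = ceiling(per_decade))
    kon_tf_grid <- c(kon_tf_grid, add)
    vals <- c(vals, vapply(add, function(k) cv_at(k)[["cv"]], numeric(1)))
    extra <- extra + 1
  }
  out <- tibble::tibble(kon_tf = kon_tf_grid, cv_fc = vals / cv0[["cv"]])
  attr(out, "template") <- rates
  attr(out, "cv_fc_sat") <- sat[["cv"]] / cv0[["cv"]]
  attr(out, "fc_sat") <- sat[["mean"]] / cv0[["mean"]]
  class(out) <- c("noise_profile", class(out))
  out
}

#' Classify the shape of a noise profile
#'
#' Reads the sign pattern of the first differences of `cv_fc` along the
#' TF-concentration grid, ignoring differences below `tolerance` (relative
#' to the profile's deviation from 1 -- the moments are deterministic, so
#' the tolerance guards only floating-point noise):
#'
#' * `monotonic`: no interior sign change (flat profiles included)
#' * `internal_max`: one rise-then-fall change
#' * `max_and_min`: a maximum followed by a minimum
#' * `unclassified`: any other pattern (flagged, never silently binned)
#'
#' @param profile A `noise_profile` from [cv_profile()], or a numeric
#'   vector of `cv_fc` values on an increasing grid.
#' @param tolerance Relative tolerance for a "real" difference
#'   (default `1e-6`).
#' @return A single string.
#' @export
classify_noise_profile <- function(profile, tolerance = 1e-6) {
  y <- if (is.data.frame(profile)) profile$cv_fc else as.numeric(profile)
  scale <- max(abs(y - 1), 1)
  d <- diff(y)
  d <- d[abs(d) > tolerance * scale]
  if (!length(d)) return("monotonic")
  pattern <- rle(sign(d))$values
  if (length(pattern) == 1) return("monotonic")
  if (identical(pattern, c(1, -1))) return("internal_max")
  if (identical(pattern, c(1, -1, 1))) return("max_and_min")
  "unclassified"
}

#' Noise-phenotype phase diagram over (alpha, beta)
#'
#' Classifies the fold-change-in-CV profile for every TF mode on a log grid,
#' at fixed promoter strength. Weak promoters give entirely monotonic
#' diagrams; strong promoters split the repressor wedge into monotonic,
#' max-and-min and internal-maximum bands.
#'
#' @param P Promoter strength.
#' @param alpha_grid,beta_grid Log-spaced mode grids (defaults: 41 points
#'   over `[1e-3, 1e3]`).
#' @param gamma,koff_p,r,koff_tf Template rates, see [noise_template()].
#' @param n_points,n_decades Per-profile TF grid, see [cv_profile()].
#' @param tolerance Classification tolerance.
#' @return A tibble with columns `alpha`, `beta`, `class`.
#' @export
noise_phase_diagram <- function(P,
                                alpha_grid = 10^seq(-3, 3, length.out = 41),
                                beta_grid = 10^seq(-3, 3, length.out = 41),
                                gamma = 1, koff_p = 100 * gamma,
                                r = 100 * gamma, koff_tf = 10 * gamma,
                                n_points = 64, n_decades = 8,
                                tolerance = 1e-6) {
  grid <- tidyr::crossing(alpha = alpha_grid, beta = beta_grid)
  grid$class <- purrr::pmap_chr(grid, function(alpha, beta) {
    prof <- cv_profile(noise_template(P, alpha, beta, gamma, koff_p, r,
                                      koff_tf),
                       n_points = n_points, n_decades = n_decades)
    classify_noise_profile(prof, tolerance)
  })
  grid
}

#' @rdname cv_profile
#' @param object A `noise_profile`.
#' @param ... Ignored.
#' @export
autoplot.noise_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$kon_tf, y = .data$cv_fc)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "TF binding rate kon_TF (1/time)",
                  y = "fold-change in CV",
                  subtitle = paste("shape:", classify_noise_profile(object)))
}
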