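#' Fold-change curves over TF concentration or promoter strength
#'
#' Tidy sweep of the thermodynamic fold-change for a set of TF modes: one
#' row per (mode, x) combination, ready for plotting. Sweep either the TF
#' concentration `R` at fixed `P`, or the promoter strength `P` at
#' saturating TF (`FC_max` titration).
#'
#' @param modes A data frame with columns `alpha`, `beta`.
#' @param R,P Numeric sweep vector (supply exactly one as a vector; the
#'   other fixed scalar). `R = Inf` rows give `FC_max`.
#' @return A tibble `alpha`, `beta`, `P`, `R`, `fc`.
#' @examples
#' fc_curve(data.frame(alpha = 0.5, beta = 10), R = 10^seq(-2, 3), P = 0.1)
#' @export
fc_curve <- function(modes, R, P) {
  stopifnot(is.data.frame(modes), all(c("alpha", "beta") %in% names(modes)))
  tidyr::crossing(dplyr::as_tibble(modes[c("alpha", "beta")]),
                  tidyr::crossing(P = P, R = R)) |>
    dplyr::mutate(fc = fold_change(.data$alpha, .data$beta, .data$P, .data$R))
}

#' Regulatory phase space over (alpha, beta)
#'
#' Grid of `FC_max` values and region labels, for the thermodynamic model at
#' promoter strength `P` or the kinetic model at `(P, V2)`. Contour levels
#' are left to the plotting layer.
#'
#' @param alpha_grid,beta_grid Log-spaced grids.
#' @param model `"thermo"` (default) or `"kinetic"`.
#' @param P Promoter strength.
#' @param V2 Initiation/unbinding ratio (kinetic model).
#' @param tolerance Boundary tolerance for [classify_region()].
#' @return A tibble `alpha`, `beta`, `fc_max`, `region`, `behavior`.
#' @export
phase_space <- function(alpha_grid = 10^seq(-2, 2, length.out = 41),
                        beta_grid = 10^seq(-2, 2, length.out = 41),
                        model = c("thermo", "kinetic"), P = 0.01, V2 = 0,
                        tolerance = 1e-9) {
  model <- match.arg(model)
  grid <- tidyr::crossing(alpha = alpha_grid, beta = beta_grid)
  fc <- if (model == "thermo") {
    fc_max_thermo(grid$alpha, grid$beta, P)
  } else {
    fc_max_kinetic(grid$alpha, grid$beta, P, V2)
  }
  dplyr::bind_cols(classify_region(grid$alpha, grid$beta, tolerance),
                   fc_max = fc)
}

#' Response-time surface over (alpha, beta)
#'
#' Deterministic response time for every mode on a grid, at a shared rate
#' template. Cells whose fold-change is within `fc_guard` of 1 are returned
#' as `NA` (the midpoint is meaningless there; the fold-change column lets
#' you see which).
#'
#' @param alpha_grid,beta_grid Mode grids.
#' @param rates A [kinetic_rates()] template; its `alpha`, `beta` are
#'   replaced cell by cell.
#' @param saturating_tf Passed to [response_time()].
#' @param fc_guard Exclusion half-width around FC = 1 (default 0.05).
#' @return A tibble `alpha`, `beta`, `fc`, `response_time_cc`.
#' @export
response_time_grid <- function(alpha_grid, beta_grid, rates,
                               saturating_tf = FALSE, fc_guard = 0.05) {
  stopifnot(inherits(rates, "kinetic_rates"))
  grid <- tidyr::crossing(alpha = alpha_grid, beta = beta_grid)
  res <- purrr::pmap(grid, function(alpha, beta) {
    r <- update_rates(rates, alpha = alpha, beta = beta)
    fc <- if (saturating_tf) {
      fc_max_kinetic(alpha, beta, r$kon_p / r$koff_p, r$r / r$koff_p)
    } else {
      fold_change_kinetic(r)
    }
    rt <- if (abs(fc - 1) <= fc_guard) NA_real_ else {
      response_time(r, saturating_tf = saturating_tf)
    }
    c(fc = fc, rt = rt)
  })
  grid |>
    dplyr::mutate(fc = purrr::map_dbl(res, "fc"),
                  response_time_cc = purrr::map_dbl(res, "rt"))
}

#' Plot a regulatory phase space
#'
#' `FC_max` contours (log scale) with the region map of [phase_space()].
#'
#' @param space A tibble from [phase_space()].
#' @return A ggplot.
#' @export
plot_phase_space <- function(space) {
  ggplot2::ggplot(space, ggplot2::aes(x = .data$alpha, y = .data$beta)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$region), alpha = 0.6) +
    ggplot2::geom_contour(ggplot2::aes(z = log10(.data$fc_max)),
                          breaks = 0, colour = "black") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_fill_manual(values = c(
      blue = "#7f9fd4", red = "#d47f7f", green = "#8fd47f",
      gray = "#bdbdbd", purple = "#b58fd4", yellow = "#e3d673",
      boundary = "black")) +
    ggplot2::labs(x = "acceleration alpha", y = "stabilization beta")
}
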