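#' Configuration for an exact stochastic simulation
#'
#' @param rates A [kinetic_rates()] object. For autoregulatory topologies
#'   `kon_tf` is the binding propensity *per free molecule* of the binding
#'   species (monomer or dimer), and the gene's own protein is the TF.
#' @param topology `"simple"` (TF pool external, fixed propensity),
#'   `"autoreg_monomer"`, or `"autoreg_dimer"`.
#' @param k_dim,k_mon Dimerization and monomerization rates (1/time);
#'   required iff `topology = "autoreg_dimer"`. The association propensity is
#'   `k_dim * n * (n - 1) / 2`.
#' @param horizon Simulated time span (> 0).
#' @param n_trajectories Number of independent trajectories (>= 1).
#' @param seed Integer seed; identical seed and config give bit-identical
#'   trajectories.
#' @param init_state Initial promoter state (`"empty"`, `"rnap"`, `"tf"`,
#'   `"cobound"`).
#' @param n0,d0 Initial free monomer and dimer counts.
#' @param dilute_bound If `TRUE`, DNA-bound TF is also lost at rate `gamma`
#'   (default `FALSE`: bound TF is sequestered and protected from dilution).
#' @param cap Population cap; exceeding it aborts with a diagnostic.
#' @param max_events Per-trajectory event cap.
#' @return A `sim_config` object.
#' @export
sim_config <- function(rates, topology = c("simple", "autoreg_monomer",
                                           "autoreg_dimer"),
                       k_dim = NULL, k_mon = NULL,
                       horizon, n_trajectories = 1, seed,
                       init_state = "empty", n0 = 0, d0 = 0,
                       dilute_bound = FALSE, cap = 1e6, max_events = 2e7) {
  stopifnot(inherits(rates, "kinetic_rates"))
  topology <- match.arg(topology)
  check_scalar(horizon, "horizon", min = 0, strict = TRUE)
  stopifnot(n_trajectories >= 1, length(seed) == 1, is.finite(seed))
  if (topology == "autoreg_dimer") {
    if (is.null(k_dim) || is.null(k_mon)) {
      stop("autoreg_dimer requires k_dim and k_mon.", call. = FALSE)
    }
  } else if (!is.null(k_dim) || !is.null(k_mon)) {
    stop("k_dim/k_mon only apply to the autoreg_dimer topology.",
         call. = FALSE)
  }
  init_state <- match.arg(init_state, c("empty", "rnap", "tf", "cobound"))
  structure(list(rates = rates, topology = topology,
                 k_dim = k_dim %||% 0, k_mon = k_mon %||% 0,
                 horizon = horizon, n_trajectories = as.integer(n_trajectories),
                 seed = as.integer(seed), init_state = init_state,
                 n0 = n0, d0 = d0, dilute_bound = dilute_bound,
                 cap = cap, max_events = as.integer(max_events)),
            class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

state_names <- c("empty", "rnap", "tf", "cobound")

run_one <- function(config, state0 = NULL, n0 = NULL, d0 = NULL,
                    horizon = NULL, kon_tf = NULL) {
  r <- config$rates
  out <- ssa_run_cpp(
    r$kon_p, r$koff_p, kon_tf %||% r$kon_tf, r$koff_tf, r$r, r$gamma,
    r$alpha, r$beta, r$beta_scope == "rnap_only",
    match(config$topology, c("simple", "autoreg_monomer", "autoreg_dimer")) - 1L,
    config$k_dim, config$k_mon,
    horizon %||% config$horizon,
    (state0 %||% (match(config$init_state, state_names) - 1L)),
    n0 %||% config$n0, d0 %||% config$d0,
    config$dilute_bound, config$cap, config$max_events)
  traj <- tibble::tibble(time = out$time,
                         state = state_names[out$state + 1L],
                         protein = out$protein, dimer = out$dimer)
  attr(traj, "horizon") <- out$horizon
  class(traj) <- c("ssa_trajectory", class(traj))
  traj
}

#' Simulate the full stochastic system
#'
#' Exact Gillespie simulation of the 4-state promoter with protein birth and
#' death, for simple regulation or autoregulation (monomer- or dimer-binding
#' TF). Piecewise-constant trajectories record every event. Uses R's RNG, so
#' the configuration seed gives bit-identical output.
#'
#' @param config A [sim_config()] object.
#' @return A list of trajectory tibbles (`time`, `state`, `protein`,
#'   `dimer`), classed `ssa_ensemble`, with the config as attribute.
#' @export
simulate_ssa <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  out <- lapply(seq_len(config$n_trajectories), function(i) run_one(config))
  structure(out, class = "ssa_ensemble", config = config)
}

# value of a piecewise-constant trajectory column at given times
traj_at <- function(traj, times, column = "protein") {
  idx <- findInterval(times, traj$time)
  idx[idx < 1L] <- 1L
  traj[[column]][idx]
}

# time-weighted average of f(column) over the window [from, to]
time_average <- function(traj, from, to = attr(traj, "horizon"),
                         f = identity, column = "protein") {
  t <- c(traj$time, attr(traj, "horizon"))
  lo <- pmax(t[-length(t)], from)
  hi <- pmin(t[-1], to)
  keep <- which(hi > lo)
  if (!length(keep)) return(NA_real_)
  sum(f(traj[[column]][keep]) * (hi[keep] - lo[keep])) / (to - from)
}

#' Moment estimates from simulated trajectories
#'
#' Ergodic (time-averaged) estimates of the steady-state protein mean,
#' variance, Fano factor and CV, pooled across trajectories, with
#' Monte-Carlo standard errors by batch means (batches are whole
#' trajectories when there are >= `n_batches` of them, otherwise contiguous
#' time blocks of the single trajectory).
#'
#' @param trajectories An `ssa_ensemble` from [simulate_ssa()].
#' @param burn_in Time discarded from the start of each trajectory; must be
#'   shorter than the horizon.
#' @param n_batches Number of batches for the SEs (default 20).
#' @return A one-row tibble: `mean`, `variance`, `fano`, `cv` and their
#'   standard errors `mean_se`, `variance_se`, `fano_se`, `cv_se`.
#' @export
estimate_moments <- function(trajectories, burn_in = 0, n_batches = 20) {
  stopifnot(inherits(trajectories, "ssa_ensemble"))
  config <- attr(trajectories, "config")
  if (burn_in >= config$horizon) {
    stop("burn_in must be smaller than the horizon.", call. = FALSE)
  }
  stats_of <- function(m1, m2) {
    v <- m2 - m1^2
    c(mean = m1, variance = v, fano = v / m1, cv = sqrt(pmax(v, 0)) / m1)
  }
  if (length(trajectories) >= n_batches) {
    per <- vapply(trajectories, function(tr) {
      c(time_average(tr, burn_in),
        time_average(tr, burn_in, f = function(x) x^2))
    }, numeric(2))
    groups <- cut(seq_along(trajectories), n_batches, labels = FALSE)
  } else {
    tr <- trajectories[[1L]]
    edges <- seq(burn_in, config$horizon, length.out = n_batches + 1L)
    per <- vapply(seq_len(n_batches), function(b) {
      c(time_average(tr, edges[b], edges[b + 1L]),
        time_average(tr, edges[b], edges[b + 1L], f = function(x) x^2))
    }, numeric(2))
    groups <- seq_len(n_batches)
  }
  if (anyNA(per)) {
    stop("insufficient post-burn-in data in at least one batch.",
         call. = FALSE)
  }
  batch <- vapply(split(seq_len(ncol(per)), groups), function(ix) {
    stats_of(mean(per[1, ix]), mean(per[2, ix]))
  }, numeric(4))
  overall <- stats_of(mean(per[1, ]), mean(per[2, ]))
  if (overall[["variance"]] <= 0) {
    stop("zero-variance trajectories: moment estimation degenerate.",
         call. = FALSE)
  }
  se <- apply(batch, 1, sd) / sqrt(ncol(batch))
  tibble::tibble(mean = overall[["mean"]], variance = overall[["variance"]],
                 fano = overall[["fano"]], cv = overall[["cv"]],
                 mean_se = se[["mean"]], variance_se = se[["variance"]],
                 fano_se = se[["fano"]], cv_se = se[["cv"]])
}

#' Promoter-state occupancy from simulated trajectories
#'
#' Time-fraction spent in each of the four promoter states, with batch-mean
#' standard errors; the stochastic counterpart of
#' [promoter_steady_state()].
#'
#' @inheritParams estimate_moments
#' @return A tibble with columns `state`, `probability`, `se`.
#' @export
estimate_occupancy <- function(trajectories, burn_in = 0, n_batches = 20) {
  stopifnot(inherits(trajectories, "ssa_ensemble"))
  occ_traj <- function(tr, from, to) {
    vapply(state_names, function(s) {
      time_average(tr, from, to, f = function(x) as.numeric(x == s),
                   column = "state")
    }, numeric(1))
  }
  config <- attr(trajectories, "config")
  if (length(trajectories) >= n_batches) {
    per <- vapply(trajectories, occ_traj, numeric(4),
                  from = burn_in, to = config$horizon)
  } else {
    tr <- trajectories[[1L]]
    edges <- seq(burn_in, config$horizon, length.out = n_batches + 1L)
    per <- vapply(seq_len(n_batches), function(b) {
      occ_traj(tr, edges[b], edges[b + 1L])
    }, numeric(4))
  }
  tibble::tibble(state = state_names,
                 probability = rowMeans(per),
                 se = apply(per, 1, sd) / sqrt(ncol(per)))
}

#' Response time estimated from stochastic simulation
#'
#' Each replicate is first relaxed to the constitutive steady state
#' (`kon_tf = 0`) for `burn_in_cc` cell cycles; the TF is then switched on
#' and the trajectory recorded. The ensemble-mean trajectory is evaluated on
#' a time grid, and the response time is its first crossing of the midpoint
#' between the constitutive and regulated mean levels (by linear
#' interpolation). The SE comes from batch means over replicates.
#'
#' @param config A [sim_config()] object; `horizon` is the post-switch span.
#' @param n_replicates Number of replicates (default 200).
#' @param burn_in_cc Constitutive relaxation time before the switch, in cell
#'   cycles (default 10).
#' @param n_grid Time-grid resolution for the ensemble mean.
#' @param n_batches Batches for the SE (default 20).
#' @param tail_frac Fraction of the horizon tail used to estimate the
#'   regulated mean level.
#' @return A one-row tibble: `response_time_cc`, `se`, `fc_hat` (the
#'   SSA-estimated fold-change).
#' @export
estimate_response_time <- function(config, n_replicates = 200,
                                   burn_in_cc = 10, n_grid = 400,
                                   n_batches = 20, tail_frac = 0.25) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tcc <- log(2) / config$rates$gamma
  grid <- seq(0, config$horizon, length.out = n_grid)
  paths <- matrix(NA_real_, n_replicates, n_grid)
  for (i in seq_len(n_replicates)) {
    pre <- run_one(config, horizon = burn_in_cc * tcc, kon_tf = 0)
    k <- nrow(pre)
    post <- run_one(config,
                    state0 = match(pre$state[k], state_names) - 1L,
                    n0 = pre$protein[k], d0 = pre$dimer[k])
    paths[i, ] <- traj_at(post, grid)
  }
  cross_of <- function(mean_path) {
    m0 <- mean_path[1]
    minf <- mean(mean_path[grid >= (1 - tail_frac) * config$horizon])
    if (abs(minf - m0) < 1e-12) return(c(NA_real_, NA_real_))
    mid <- (m0 + minf) / 2
    f <- mean_path - mid
    i <- which(f[-1] * f[-length(f)] <= 0)[1]
    if (is.na(i)) return(c(NA_real_, minf / m0))
    frac <- f[i] / (f[i] - f[i + 1])
    c((grid[i] + frac * (grid[i + 1] - grid[i])) / tcc, minf / m0)
  }
  overall <- cross_of(colMeans(paths))
  if (is.na(overall[1])) {
    stop("response time undefined: ensemble mean does not cross the ",
         "midpoint (fold-change too close to 1?).", call. = FALSE)
  }
  groups <- cut(seq_len(n_replicates), n_batches, labels = FALSE)
  per_batch <- vapply(split(seq_len(n_replicates), groups), function(ix) {
    cross_of(colMeans(paths[ix, , drop = FALSE]))[1]
  }, numeric(1))
  tibble::tibble(response_time_cc = overall[1],
                 se = sd(per_batch, na.rm = TRUE) /
                   sqrt(sum(!is.na(per_batch))),
                 fc_hat = overall[2])
}
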