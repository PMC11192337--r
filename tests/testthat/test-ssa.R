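test_that("seeded simulations are bit-identical and config is validated", {
  kr <- kinetic_rates(5, 10, 3, 7, 20, 1, alpha = 0.5, beta = 4)
  cfg <- sim_config(kr, horizon = 20, n_trajectories = 2, seed = 99)
  a <- simulate_ssa(cfg)
  b <- simulate_ssa(cfg)
  expect_identical(lapply(a, as.data.frame), lapply(b, as.data.frame))

  expect_error(sim_config(kr, topology = "autoreg_dimer", horizon = 1,
                          seed = 1), "k_dim")
  expect_error(sim_config(kr, k_dim = 1, k_mon = 1, horizon = 1, seed = 1),
               "autoreg_dimer")
  expect_error(sim_config(kr, horizon = -1, seed = 1), "horizon")
})

test_that("pure death decays exponentially", {
  kr <- kinetic_rates(kon_p = 0, koff_p = 1, kon_tf = 0, koff_tf = 1,
                      r = 0, gamma = 1)
  cfg <- sim_config(kr, horizon = 3, n_trajectories = 400, seed = 3,
                    n0 = 5)
  trajs <- simulate_ssa(cfg)
  at1 <- vapply(trajs, function(tr) {
    tr$protein[findInterval(1, tr$time)]
  }, numeric(1))
  se <- sd(at1) / sqrt(length(at1))
  expect_lt(abs(mean(at1) - 5 * exp(-1)), 3 * se)
})

test_that("locked promoter gives Poisson protein statistics", {
  ## near-instant polymerase rebinding makes production effectively
  ## constant-rate: stationary law is Poisson, Fano = 1
  kr <- kinetic_rates(1e4, 1, 0, 1, 5, 1)
  cfg <- sim_config(kr, horizon = 500, seed = 17)
  m <- estimate_moments(simulate_ssa(cfg), burn_in = 20)
  expect_lt(abs(m$fano - 1), 3 * m$fano_se)
})

test_that("occupancy and moments match the analytic solutions within 3 SE", {
  set.seed(61)
  for (i in 1:3) {
    kr <- kinetic_rates(kon_p = rlu(1, 1, 20), koff_p = rlu(1, 2, 20),
                        kon_tf = rlu(1, 1, 20), koff_tf = rlu(1, 2, 20),
                        r = rlu(1, 5, 50), gamma = 1,
                        alpha = rlu(1, 0.1, 10), beta = rlu(1, 0.1, 10))
    cfg <- sim_config(kr, horizon = 600, seed = 100 + i)
    trajs <- simulate_ssa(cfg)
    occ <- estimate_occupancy(trajs, burn_in = 30)
    exact <- promoter_steady_state(kr)$probability
    expect_true(all(abs(occ$probability - exact) <=
                      3 * pmax(occ$se, 1e-4)),
                label = sprintf("occupancy config %d", i))
    m <- estimate_moments(trajs, burn_in = 30)
    ex <- protein_moments(kr)
    expect_lt(abs(m$mean - ex$mean), 3 * m$mean_se)
    expect_lt(abs(m$cv - ex$cv), 3 * max(m$cv_se, 1e-4))
  }
})

test_that("degenerate moment estimation inputs error", {
  kr <- kinetic_rates(5, 10, 0, 7, 20, 1)
  cfg <- sim_config(kr, horizon = 50, seed = 5)
  trajs <- simulate_ssa(cfg)
  expect_error(estimate_moments(trajs, burn_in = 50), "burn_in")
  ## zero-variance: no production at all
  kr0 <- kinetic_rates(5, 10, 0, 7, 0, 1)
  t0 <- simulate_ssa(sim_config(kr0, horizon = 50, seed = 6))
  expect_error(estimate_moments(t0, burn_in = 1), "zero-variance")
})

test_that("SSA response times agree with the ODE and show the slow corner", {
  ## constitutive-scale response: saturating TF, fast promoter
  kr <- kinetic_rates(1000, 1000, 1e6 * 1000, 1000, 1000, 1,
                      alpha = 5, beta = 1)
  est <- estimate_response_time(
    sim_config(kr, horizon = 6, seed = 41), n_replicates = 150)
  expect_lt(abs(est$response_time_cc - 1), 3 * est$se)

  ## ODE agreement on finite-R configs; mean counts ~25 keep the
  ## ensemble-mean crossing estimator well conditioned
  for (ab in list(c(0.2, 5), c(20, 0.1))) {
    krf <- kinetic_rates(100, 100, 10, 10, 100, 1,
                         alpha = ab[1], beta = ab[2])
    est <- estimate_response_time(
      sim_config(krf, horizon = 12, seed = 43), n_replicates = 200)
    expect_lt(abs(est$response_time_cc - response_time(krf)),
              3 * est$se)
  }

  ## strong stabilization + deceleration responds slower than constitutive
  kr_slow <- kinetic_rates(100, 100, 10, 10, 100, 1,
                           alpha = 0.01, beta = 100)
  est_slow <- estimate_response_time(
    sim_config(kr_slow, horizon = 12, seed = 43), n_replicates = 200)
  expect_gt(est_slow$response_time_cc - 3 * est_slow$se, 1.0)
  expect_lt(abs(est_slow$response_time_cc - response_time(kr_slow)),
            3 * est_slow$se)
})

test_that("autoregulation bookkeeping: bound TF is sequestered", {
  kr <- kinetic_rates(10, 20, 1, 2, 60, 1, alpha = 0.5, beta = 10)
  cfg <- sim_config(kr, topology = "autoreg_monomer", horizon = 100,
                    seed = 13)
  trajs <- simulate_ssa(cfg)
  tr <- trajs[[1]]
  ## when the promoter binds TF the free count drops by one
  i <- which(tr$state[-1] %in% c("tf", "cobound") &
               tr$state[-nrow(tr)] %in% c("empty", "rnap"))
  expect_true(all(tr$protein[i + 1] == tr$protein[i] - 1))
})

test_that("dimer-TF autoregulation preserves the S3-style regulatory switch", {
  ## fast promoter binding (V2 = 0.1) so stabilization can recruit
  ## polymerase; expression scale 60 gives enough dimers to self-regulate
  fc_ssa <- function(P, alpha, beta, k_dim, k_mon, seed) {
    kr <- kinetic_rates(P * 600, 600, 1, 1, 60, 1,
                        alpha = alpha, beta = beta)
    cfg <- sim_config(kr, topology = "autoreg_dimer", k_dim = k_dim,
                      k_mon = k_mon, horizon = 400, n_trajectories = 5,
                      seed = seed)
    reg <- estimate_moments(simulate_ssa(cfg), burn_in = 40, n_batches = 5)
    cfg0 <- sim_config(update_rates(kr, kon_tf = 0),
                       topology = "autoreg_dimer", k_dim = k_dim,
                       k_mon = k_mon, horizon = 400, n_trajectories = 5,
                       seed = seed + 1)
    con <- estimate_moments(simulate_ssa(cfg0), burn_in = 40, n_batches = 5)
    c(fc = unname(reg$mean / con$mean),
      se = unname(reg$mean_se / con$mean))
  }
  for (rates in list(c(0.1, 1), c(1, 0.1))) {   # slow and fast dimerization
    ## red region (alpha < 1, alpha*beta > 1): activator -> repressor
    lo <- fc_ssa(0.5, 0.5, 10, rates[1], rates[2], seed = 19)
    hi <- fc_ssa(10, 0.5, 10, rates[1], rates[2], seed = 23)
    expect_gt(lo["fc"] - 3 * lo["se"], 1)
    expect_lt(hi["fc"] + 3 * hi["se"], 1)
    ## green region (alpha > 1, alpha*beta < 1): repressor -> activator
    lo <- fc_ssa(2, 2, 0.1, rates[1], rates[2], seed = 29)
    hi <- fc_ssa(30, 2, 0.1, rates[1], rates[2], seed = 31)
    expect_lt(lo["fc"] + 3 * lo["se"], 1)
    expect_gt(hi["fc"] - 3 * hi["se"], 1)
  }
})

test_that("population and event caps abort with diagnostics", {
  kr <- kinetic_rates(1e3, 1, 0, 1, 1e3, 1e-6)
  expect_error(
    simulate_ssa(sim_config(kr, horizon = 1e5, seed = 1, cap = 50)),
    "cap")
})
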