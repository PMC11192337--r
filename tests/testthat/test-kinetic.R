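kr0 <- kinetic_rates(kon_p = 2, koff_p = 3, kon_tf = 1.5, koff_tf = 2.5,
                     r = 0.7, gamma = 0.1, alpha = 0.5, beta = 4)

test_that("the generator has the prescribed structure", {
  A <- build_generator(kr0)
  expect_equal(rowSums(A), rep(0, 4), ignore_attr = TRUE)
  expect_equal(A["empty", "rnap"], 2)
  expect_equal(A["rnap", "empty"], 3 + 0.7)         # koff_p + r
  expect_equal(A["cobound", "rnap"], 2.5 / 4)       # koff_tf / beta
  expect_equal(A["cobound", "tf"], 3 / 4 + 0.5 * 0.7)  # koff_p/beta + alpha*r

  ## beta = 1: co-bound off-rates equal the singly-bound ones
  A1 <- build_generator(update_rates(kr0, beta = 1))
  expect_equal(A1["cobound", "rnap"], 2.5)            # = koff_tf
  expect_equal(A1["cobound", "tf"], 3 + 0.5 * 0.7)    # = koff_p + alpha*r
})

test_that("beta_scope = rnap_only leaves the TF off-rate untouched", {
  A <- build_generator(update_rates(kr0, beta_scope = "rnap_only"))
  expect_equal(A["cobound", "rnap"], 2.5)       # koff_tf, undivided
  expect_equal(A["cobound", "tf"], 3 / 4 + 0.35)
})

test_that("r = 0 stationary distribution is the equilibrium weight table", {
  set.seed(31)
  for (i in 1:10) {
    kr <- kinetic_rates(kon_p = rlu(1, 0.1, 10), koff_p = rlu(1, 0.1, 10),
                        kon_tf = rlu(1, 0.1, 10), koff_tf = rlu(1, 0.1, 10),
                        r = 0, gamma = 1,
                        alpha = rlu(1, 0.1, 10), beta = rlu(1, 0.1, 10))
    P <- kr$kon_p / kr$koff_p; R <- kr$kon_tf / kr$koff_tf
    expect_equal(promoter_steady_state(kr)$probability,
                 state_weights(kr$alpha, kr$beta, P, R)$probability,
                 tolerance = 1e-10)
  }
})

test_that("reduced chains are handled", {
  pss <- promoter_steady_state(update_rates(kr0, kon_tf = 0))
  expect_equal(pss$probability[3:4], c(0, 0))
  expect_equal(sum(pss$probability), 1)
  pss2 <- promoter_steady_state(update_rates(kr0, kon_p = 0))
  expect_equal(pss2$probability[c(2, 4)], c(0, 0))
})

test_that("kinetic fold-change reduces to the thermodynamic model as V2 -> 0", {
  expect_equal(fold_change_kinetic(update_rates(kr0, alpha = 1, beta = 1)), 1)
  set.seed(41)
  for (i in 1:50) {
    ## V2 = 1e-6 at moderate mode strengths (the correction scales with
    ## alpha*beta*V2, so extreme draws need a smaller V2; see below)
    kr <- kinetic_rates(kon_p = rlu(1, 1e-2, 1e2), koff_p = 1,
                        kon_tf = rlu(1, 1e-2, 1e2), koff_tf = rlu(1, 0.1, 10),
                        r = 1e-6, gamma = 1,
                        alpha = rlu(1, 1e-1, 1e1), beta = rlu(1, 1e-1, 1e1))
    expect_equal(fold_change_kinetic(kr),
                 fold_change(kr$alpha, kr$beta, kr$kon_p / kr$koff_p,
                             kr$kon_tf / kr$koff_tf),
                 tolerance = 1e-4)
  }
  expect_error(fold_change_kinetic(update_rates(kr0, r = 0)), "constitutive")
})

test_that("saturating kinetic fold-change matches the Eq-3 closed form", {
  set.seed(43)
  for (i in 1:10) {
    kr <- kinetic_rates(kon_p = rlu(1, 0.1, 10), koff_p = 1,
                        kon_tf = 1e8, koff_tf = 1, r = rlu(1, 0.1, 10),
                        gamma = 1, alpha = rlu(1, 0.1, 10),
                        beta = rlu(1, 0.1, 10))
    expect_equal(fold_change_kinetic(kr),
                 fc_max_kinetic(kr$alpha, kr$beta, kr$kon_p, kr$r),
                 tolerance = 1e-6)
  }
})

test_that("fc_max_kinetic limits and flatness on the on-rate boundary", {
  expect_equal(fc_max_kinetic(1, 1, 2, 3), 1)
  set.seed(47)
  m <- draw_modes(1000)
  P <- rlu(1000, 1e-3, 1e3)
  expect_equal(fc_max_kinetic(m$alpha, m$beta, P, 0),
               fc_max_thermo(m$alpha, m$beta, P), tolerance = 1e-14)
  ## on-rate boundary beta: FC_max independent of P (the boundary only
  ## exists while 1 + V2*(1 - alpha) > 0)
  for (av in list(c(0.3, 1), c(0.5, 1), c(2, 0.5))) {
    b <- tuning_boundary_beta(av[1], "on_rate", V2 = av[2])
    fc <- fc_max_kinetic(av[1], b, c(0.01, 1, 100), av[2])
    expect_equal(max(fc) - min(fc), 0, tolerance = 1e-12)
  }
})

test_that("Table-1 tuning boundaries", {
  expect_equal(tuning_boundary_beta(1, "on_rate", V2 = 5), 1)
  expect_equal(tuning_boundary_beta(1, "off_rate", N_P = 2, r = 7), 1)
  expect_equal(tuning_boundary_beta(0.5, "on_rate", V2 = 0), 1)
  expect_equal(tuning_boundary_beta(0.5, "on_rate", V2 = 1), 2 / 3)
  expect_error(tuning_boundary_beta(3, "on_rate", V2 = 1), "no boundary")

  ## off-rate tuning: FC_max flat as koff_p is titrated at the boundary beta
  a <- 0.4; kon_p <- 2; r <- 3
  b <- tuning_boundary_beta(a, "off_rate", N_P = kon_p, r = r)
  expect_equal(b, (kon_p + r) / (kon_p + a * r))
  fc <- vapply(c(0.1, 1, 10, 100), function(koff) {
    fc_max_kinetic(a, b, kon_p / koff, r / koff)
  }, numeric(1))
  expect_equal(max(fc) - min(fc), 0, tolerance = 1e-12)
  ## off the boundary it is not flat
  fc2 <- vapply(c(0.1, 1, 10, 100), function(koff) {
    fc_max_kinetic(a, 2 * b, kon_p / koff, r / koff)
  }, numeric(1))
  expect_gt(max(fc2) - min(fc2), 1e-3)
})
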