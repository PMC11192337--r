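test_that("state weights normalize and reproduce the known limits", {
  w <- state_weights(1, 1, 0, 0)
  expect_equal(w$probability, c(1, 0, 0, 0))

  w <- state_weights(7, 1, 1, 1)  # beta = 1, P = R = 1: all equal
  expect_equal(w$probability, rep(0.25, 4))

  w <- state_weights(0.5, 2, 0.3, 0.7)
  expect_equal(sum(w$probability), 1)
  expect_true(all(w$probability >= 0))

  expect_error(state_weights(1, 1, 1, Inf), "saturating")
})

test_that("stabilization multiplies weak-promoter RNAP occupancy", {
  ## with saturating TF the promoter is confined to {tf, cobound}; RNAP
  ## occupancy conditional on TF bound is beta*P/(1 + beta*P), vs the
  ## unconditional P/(1 + P): a 10x boost at beta = 10 on a weak promoter
  beta <- 10; P <- 1e-6; R <- 1e9
  w <- state_weights(1, beta, P, R)
  p_cond <- w$probability[4] / (w$probability[3] + w$probability[4])
  expect_equal(p_cond / (P / (1 + P)), 10, tolerance = 1e-4)
})

test_that("fold-change matches the 4-state weight oracle and Eq-1 form", {
  expect_equal(fold_change(1, 1, 2, 5), 1)
  expect_equal(fold_change(3, 0.2, 1, 0), 1)
  ## weak promoter, saturating TF: FC -> alpha*beta
  expect_equal(fold_change(0.5, 10, 1e-6, Inf), 5, tolerance = 1e-4)
  expect_gt(fold_change(0.5, 10, 1e-4, Inf), 1)  # net activation

  set.seed(101)
  n <- 1e4
  a <- rlu(n, 1e-2, 1e2); b <- rlu(n, 1e-2, 1e2)
  P <- rlu(n, 1e-3, 1e3); R <- rlu(n, 1e-3, 1e3)
  fc <- fold_change(a, b, P, R)
  expect_equal(fc, fc_from_weights(a, b, P, R), tolerance = 1e-12)
  ## and equals (1 + chi*FCmax)/(1 + chi)
  ch <- chi(a, b, P, R)
  expect_equal(fc, (1 + ch * fc_max_thermo(a, b, P)) / (1 + ch),
               tolerance = 1e-12)
})

test_that("fold-change is monotone in R between 1 and FC_max", {
  set.seed(7)
  for (i in 1:20) {
    a <- rlu(1, 1e-2, 1e2); b <- rlu(1, 1e-2, 1e2); P <- rlu(1, 1e-3, 1e3)
    R <- 10^seq(-4, 6, length.out = 100)
    fc <- fold_change(a, b, P, R)
    expect_true(all(diff(fc) > 0) || all(diff(fc) < 0) ||
                  abs(fc_max_thermo(a, b, P) - 1) < 1e-10)
    expect_true(all(fc >= min(1, fc_max_thermo(a, b, P)) - 1e-9))
    expect_true(all(fc <= max(1, fc_max_thermo(a, b, P)) + 1e-9))
  }
})

test_that("FC_max limits and the switching strength", {
  expect_equal(fc_max_thermo(1, 1, 2.3), 1)
  expect_equal(fc_max_thermo(0.5, 10, 1e-9), 5, tolerance = 1e-6)
  expect_equal(fc_max_thermo(0.5, 10, 1e6), 0.5, tolerance = 1e-5)
  expect_equal(fc_max_thermo(0.5, 4, 0.5), 1)

  expect_equal(switch_promoter_strength(0.5, 4), 0.5)
  expect_equal(switch_promoter_strength(2, 0.4), 0.5)
  expect_error(switch_promoter_strength(1, 5), "no sign switch")
  expect_error(switch_promoter_strength(2, 3), "no sign switch")
  ## root oracle: FC_max(P_s) = 1 wherever P_s is defined
  set.seed(11)
  for (i in 1:20) {
    a <- rlu(1, 1e-2, 1); b <- rlu(1, 1 / a + 0.1, 1e3)  # red region
    Ps <- switch_promoter_strength(a, b)
    expect_gt(Ps, 0)
    expect_equal(fc_max_thermo(a, b, Ps), 1, tolerance = 1e-10)
  }
})

test_that("chi matches its closed form", {
  expect_equal(chi(1, 1, 0.37, 2), 2)
  expect_equal(chi(2, 5, 1, 0), 0)
  expect_equal(chi(1, 10, 1, 1), 5.5)
  expect_error(chi(1, 1, 1, Inf), "infinite")
})

test_that("alpha_critical formula agrees with the dFC/dbeta sign change", {
  expect_equal(alpha_critical(1, 0), 0.5)
  expect_equal(alpha_critical(0.2, 0.2), 1 / 7)
  expect_lt(alpha_critical(1, 1e9), 1e-8)
  expect_warning(out <- alpha_critical(0, 1), "degenerate")
  expect_equal(out, 0)

  for (pr in list(c(0.01, 0.2), c(1, 1), c(0.5, 3))) {
    expect_equal(alpha_c_numeric(pr[1], pr[2]), alpha_critical(pr[1], pr[2]),
                 tolerance = 1e-6)
  }
})

test_that("six-region classification matches FC_max(P) sweep behavior", {
  expect_equal(as.character(classify_region(0.5, 4)$region), "red")
  expect_equal(as.character(classify_region(2, 3)$region), "yellow")
  expect_equal(as.character(classify_region(1, 1)$region), "boundary")
  expect_equal(as.character(classify_region(2, 0.1)$region), "green")
  expect_equal(as.character(classify_region(0.5, 1.5)$region), "blue")
  expect_equal(as.character(classify_region(0.2, 0.5)$region), "purple")
  expect_equal(as.character(classify_region(3, 1/3)$region), "boundary")

  set.seed(21)
  modes <- draw_modes(150)
  lab <- classify_region(modes$alpha, modes$beta)
  for (i in seq_len(nrow(modes))) {
    if (lab$region[i] == "boundary") next
    expect_equal(as.character(lab$region[i]),
                 region_from_sweep(modes$alpha[i], modes$beta[i]),
                 label = sprintf("alpha=%g beta=%g", modes$alpha[i],
                                 modes$beta[i]))
  }
})

test_that("degenerate and invalid inputs are policed", {
  expect_error(fold_change(-1, 1, 1, 1), "alpha")
  expect_error(fold_change(1, 1, -1, 1), "P")
  expect_error(fc_max_thermo(1, Inf, 1), "finite")
  ## P = 0 and R = 0 are exact limits, not errors
  expect_equal(fold_change(2, 2, 0, 5), (1 + 4 * 5) / (1 + 5))
  expect_equal(fold_change(0.5, 3, 0, 2), (1 + 1.5 * 2) / (1 + 2))
})
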