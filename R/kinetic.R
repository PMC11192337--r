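#' Rate set for the 4-state kinetic promoter model
#'
#' Bundles the rates of the full promoter + protein birth/death system.
#' Binding propensities `kon_p` and `kon_tf` are already proportional to the
#' polymerase and TF copy numbers; dissociation rates are per complex.
#' Productive initiation removes the polymerase: RNAP-bound -> empty at rate
#' `r`, co-bound -> TF-bound at rate `alpha * r`, each emitting one protein
#' (mRNA dynamics are folded into `r`). Stabilization `beta` divides both the
#' TF and RNAP off-rates from the co-bound state; set
#' `beta_scope = "rnap_only"` to restrict it to the RNAP off-rate for
#' sensitivity checks.
#'
#' Derived dimensionless groups: `P = kon_p/koff_p`, `R = kon_tf/koff_tf`,
#' `V2 = r/koff_p`, `V4 = gamma/koff_p`; the cell-cycle time is
#' `T_cc = log(2)/gamma`.
#'
#' @param kon_p,koff_p RNAP binding propensity and unbinding rate (1/time).
#' @param kon_tf,koff_tf TF binding propensity and unbinding rate (1/time).
#' @param r Initiation (production) rate from the RNAP-bound state (1/time).
#' @param gamma Protein dilution/degradation rate (1/time, > 0).
#' @param alpha,beta Regulatory mode of the TF (dimensionless, > 0).
#' @param beta_scope `"both"` (default) or `"rnap_only"`.
#' @return An object of class `kinetic_rates`.
#' @examples
#' kr <- kinetic_rates(kon_p = 100, koff_p = 100, kon_tf = 100, koff_tf = 100,
#'                     r = 100, gamma = 1, alpha = 0.5, beta = 4)
#' @export
kinetic_rates <- function(kon_p, koff_p, kon_tf, koff_tf, r, gamma,
                          alpha = 1, beta = 1,
                          beta_scope = c("both", "rnap_only")) {
  beta_scope <- match.arg(beta_scope)
  for (nm in c("kon_p", "kon_tf", "r")) {
    check_scalar(get(nm), nm, min = 0)
  }
  for (nm in c("koff_p", "koff_tf", "gamma")) {
    check_scalar(get(nm), nm, min = 0, strict = TRUE)
  }
  check_mode(alpha, beta)
  structure(
    list(kon_p = kon_p, koff_p = koff_p, kon_tf = kon_tf, koff_tf = koff_tf,
         r = r, gamma = gamma, alpha = alpha, beta = beta,
         beta_scope = beta_scope),
    class = "kinetic_rates")
}

#' @export
print.kinetic_rates <- function(x, ...) {
  cat("<kinetic_rates>\n")
  cat(sprintf("  RNAP: kon %g, koff %g; TF: kon %g, koff %g\n",
              x$kon_p, x$koff_p, x$kon_tf, x$koff_tf))
  cat(sprintf("  r %g, gamma %g; alpha %g, beta %g (%s)\n",
              x$r, x$gamma, x$alpha, x$beta, x$beta_scope))
  cat(sprintf("  P = %g, R = %g, V2 = %g, V4 = %g, T_cc = %g\n",
              x$kon_p / x$koff_p, x$kon_tf / x$koff_tf, x$r / x$koff_p,
              x$gamma / x$koff_p, log(2) / x$gamma))
  invisible(x)
}

#' Modify fields of a kinetic rate set
#'
#' @param object A [kinetic_rates()] object. (The argument is named `object`
#'   so that short field names like `r` are never partially matched to it.)
#' @param ... Named fields to replace (e.g. `kon_tf = 0`, `alpha = 2`).
#' @return A new `kinetic_rates` object.
#' @export
update_rates <- function(object, ...) {
  stopifnot(inherits(object, "kinetic_rates"))
  new <- utils::modifyList(unclass(object), list(...))
  do.call(kinetic_rates, new)
}

# off-rates out of the co-bound state, honoring beta_scope
cobound_off <- function(rates) {
  list(p = rates$koff_p / rates$beta,
       tf = if (rates$beta_scope == "rnap_only") rates$koff_tf
            else rates$koff_tf / rates$beta)
}

#' Transition-rate generator of the 4 promoter states
#'
#' Returns the 4x4 generator `A` with `A[i, j]` the rate from state `i` to
#' state `j` (states: `empty`, `rnap`, `tf`, `cobound`) and diagonal equal to
#' minus the row exit rates, so rows sum to zero. The `empty <- rnap` entry
#' contains `koff_p + r` (the `r` channel is a productive initiation) and the
#' `tf <- cobound` entry contains `koff_p/beta + alpha*r`.
#'
#' @param rates A [kinetic_rates()] object.
#' @return A 4x4 numeric matrix with dimnames.
#' @export
build_generator <- function(rates) {
  stopifnot(inherits(rates, "kinetic_rates"))
  off <- cobound_off(rates)
  A <- matrix(0, 4, 4,
              dimnames = rep(list(c("empty", "rnap", "tf", "cobound")), 2))
  A["empty", "rnap"] <- rates$kon_p
  A["rnap", "empty"] <- rates$koff_p + rates$r
  A["empty", "tf"] <- rates$kon_tf
  A["tf", "empty"] <- rates$koff_tf
  A["rnap", "cobound"] <- rates$kon_tf
  A["cobound", "rnap"] <- off$tf
  A["tf", "cobound"] <- rates$kon_p
  A["cobound", "tf"] <- off$p + rates$alpha * rates$r
  diag(A) <- -rowSums(A)
  A
}

# productive (protein-emitting) part of each transition
production_matrix <- function(rates) {
  B <- matrix(0, 4, 4,
              dimnames = rep(list(c("empty", "rnap", "tf", "cobound")), 2))
  B["rnap", "empty"] <- rates$r
  B["cobound", "tf"] <- rates$alpha * rates$r
  B
}

# stationary distribution of the promoter chain (internal, plain vector)
promoter_ss_vec <- function(rates) {
  A <- build_generator(rates)
  M <- rbind(t(A), rep(1, 4))
  pi <- tryCatch(qr.solve(M, c(0, 0, 0, 0, 1)),
                 error = function(e) stop("singular promoter chain: ",
                                          conditionMessage(e), call. = FALSE))
  if (any(pi < -1e-9)) {
    stop("promoter steady state has negative entries; chain may be reducible.",
         call. = FALSE)
  }
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

#' Steady-state occupancy of the four promoter states
#'
#' Null vector of the generator of [build_generator()], normalized to a
#' probability distribution. With `r = 0` the chain satisfies detailed
#' balance and this reproduces the equilibrium weights of [state_weights()].
#'
#' @param rates A [kinetic_rates()] object.
#' @return A tibble with columns `state` and `probability`.
#' @export
promoter_steady_state <- function(rates) {
  pi <- promoter_ss_vec(rates)
  tibble::tibble(state = c("empty", "rnap", "tf", "cobound"),
                 probability = unname(pi))
}

#' Kinetic-model fold-change at finite TF concentration
#'
#' Production rate with the TF present, `r*pi_rnap + alpha*r*pi_cobound`,
#' divided by the constitutive production of the same promoter with
#' `kon_tf = 0`. Reduces to the thermodynamic [fold_change()] as
#' `V2 = r/koff_p -> 0`.
#'
#' @param rates A [kinetic_rates()] object.
#' @return Fold-change (dimensionless).
#' @export
fold_change_kinetic <- function(rates) {
  stopifnot(inherits(rates, "kinetic_rates"))
  if (rates$r <= 0 || rates$kon_p <= 0) {
    stop("zero constitutive expression (r = 0 or kon_p = 0): fold-change ",
         "undefined.", call. = FALSE)
  }
  pi <- promoter_ss_vec(rates)
  pi0 <- promoter_ss_vec(update_rates(rates, kon_tf = 0))
  unname((rates$r * pi[2] + rates$alpha * rates$r * pi[4]) /
           (rates$r * pi0[2]))
}

#' Saturating fold-change of the full kinetic model
#'
#' `FC_max = alpha*beta*(1 + P + V2) / (1 + beta*P + alpha*beta*V2)` where
#' `V2 = r/koff_p`. At `V2 = 0` this is exactly the thermodynamic
#' [fc_max_thermo()]; the correction appears when initiation is not slow
#' compared to polymerase unbinding.
#'
#' @inheritParams state_weights
#' @param V2 Ratio of initiation rate to RNAP unbinding rate (>= 0).
#' @return `FC_max` (dimensionless). Vectorized.
#' @export
fc_max_kinetic <- function(alpha, beta, P, V2) {
  check_mode(alpha, beta)
  check_vec(P, "P", min = 0)
  check_vec(V2, "V2", min = 0)
  alpha * beta * (1 + P + V2) / (1 + beta * P + alpha * beta * V2)
}

#' Phase-space boundary beta in the kinetic model
#'
#' In the kinetic model the `beta = 1` line of the thermodynamic phase space
#' moves, and where it lies depends on how promoter strength is titrated.
#' Tuning the RNAP *off*-rate gives `beta = (N_P + r) / (N_P + alpha*r)`;
#' tuning the *on*-rate gives `beta = 1 / (1 + V2*(1 - alpha))`. On the
#' returned line `FC_max` is insensitive to promoter strength; `alpha = 1`
#' gives `beta = 1` in both modes.
#'
#' @param alpha Acceleration (> 0, scalar or vector).
#' @param tuning `"off_rate"` or `"on_rate"`.
#' @param N_P RNAP binding propensity `kon_p` (needed for `"off_rate"`).
#' @param r Initiation rate (needed for `"off_rate"`).
#' @param V2 `r/koff_p` (needed for `"on_rate"`).
#' @return The boundary `beta` (vectorized over `alpha`).
#' @examples
#' tuning_boundary_beta(0.5, "on_rate", V2 = 1)  # 2/3
#' @export
tuning_boundary_beta <- function(alpha, tuning = c("off_rate", "on_rate"),
                                 N_P = NULL, r = NULL, V2 = NULL) {
  tuning <- match.arg(tuning)
  check_vec(alpha, "alpha", min = 0, strict = TRUE)
  if (tuning == "off_rate") {
    if (is.null(N_P) || is.null(r)) {
      stop("off_rate tuning needs N_P and r.", call. = FALSE)
    }
    check_vec(N_P, "N_P", min = 0); check_vec(r, "r", min = 0)
    (N_P + r) / (N_P + alpha * r)
  } else {
    if (is.null(V2)) stop("on_rate tuning needs V2.", call. = FALSE)
    check_vec(V2, "V2", min = 0)
    den <- 1 + V2 * (1 - alpha)
    if (any(den <= 0)) {
      stop("no boundary: 1 + V2*(1 - alpha) <= 0 (strongly accelerating TF).",
           call. = FALSE)
    }
    1 / den
  }
}
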