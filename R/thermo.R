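#' Equilibrium state weights of the four promoter states
#'
#' Statistical weights of the promoter being empty, RNAP-bound, TF-bound or
#' co-bound are `{1, P, R, beta*P*R}`; normalizing gives the equilibrium
#' occupancy of each state. Expression is proportional to the RNAP-bound
#' weight plus `alpha*beta` times the co-bound weight, which is what makes
#' the fold-change of [fold_change()] come out of this table.
#'
#' @param alpha Acceleration: multiplicative factor on the initiation rate
#'   when TF and RNAP are co-bound (`alpha > 1` accelerates). Must be > 0.
#' @param beta Stabilization: multiplicative factor by which co-binding
#'   reduces TF and RNAP dissociation (`beta > 1` stabilizes). Must be > 0.
#' @param P Dimensionless promoter strength, `N_P / k_D,P` (>= 0).
#' @param R Dimensionless TF concentration, `N_TF / k_D,TF` (>= 0, finite).
#'   Saturating TF (`R = Inf`) has no normalizable state table; use the
#'   limit formula [fc_max_thermo()] instead.
#' @return A tibble with columns `state` (`empty`, `rnap`, `tf`, `cobound`)
#'   and `probability`, summing to 1.
#' @seealso [fold_change()], [fc_max_thermo()]
#' @examples
#' state_weights(alpha = 1, beta = 1, P = 1, R = 1)   # all 1/4
#' @export
state_weights <- function(alpha, beta, P, R) {
  check_mode(alpha, beta)
  check_scalar(P, "P", min = 0)
  check_scalar(R, "R", min = 0)
  if (is.infinite(R)) {
    stop("R is saturating (infinite); the state table degenerates. ",
         "Use fc_max_thermo() for the saturating limit.", call. = FALSE)
  }
  w <- c(empty = 1, rnap = P, tf = R, cobound = beta * P * R)
  tibble::tibble(state = names(w), probability = unname(w) / sum(w))
}

#' Thermodynamic fold-change of a regulated promoter
#'
#' Ratio of expression with the TF present at level `R` to constitutive
#' expression, from the equilibrium 4-state model:
#' `FC = (1 + chi * FC_max) / (1 + chi)`, equivalently
#' `(1 + alpha*beta*R) * (1 + P) / (1 + P + R + beta*P*R)`.
#' `FC` moves monotonically from 1 at `R = 0` to `FC_max` as `R -> Inf`;
#' `R = Inf` is accepted and returns [fc_max_thermo()] exactly.
#'
#' @inheritParams state_weights
#' @param R Dimensionless TF concentration; may be `Inf` (saturating).
#' @return Fold-change (dimensionless, >= 0). Vectorized over all arguments.
#' @examples
#' fold_change(alpha = 0.5, beta = 10, P = 1e-6, R = Inf)  # ~ alpha * beta
#' fold_change(alpha = 2, beta = 3, P = 1, R = 0)          # 1: no TF
#' @export
fold_change <- function(alpha, beta, P, R) {
  check_mode(alpha, beta)
  check_vec(P, "P", min = 0)
  check_vec(R, "R", min = 0)
  n <- max(length(alpha), length(beta), length(P), length(R))
  alpha <- rep_len(alpha, n); beta <- rep_len(beta, n)
  P <- rep_len(P, n); R <- rep_len(R, n)
  fc <- (1 + alpha * beta * R) * (1 + P) / (1 + P + R + beta * P * R)
  sat <- is.infinite(R)
  if (any(sat)) fc[sat] <- fc_max_thermo(alpha[sat], beta[sat], P[sat])
  fc
}

#' Saturating fold-change FC_max of the thermodynamic model
#'
#' `FC_max = alpha * beta * (1 + P) / (1 + beta * P)`: the fold-change in the
#' limit of saturating TF. As `P -> 0` it tends to `alpha * beta` (the two
#' modes multiply); as `P -> Inf` it tends to `alpha` alone, because a strong
#' promoter gains nothing from stabilization.
#'
#' @inheritParams state_weights
#' @return `FC_max` (dimensionless). Vectorized.
#' @examples
#' fc_max_thermo(0.5, 10, 1e-9)  # ~5 = alpha * beta
#' fc_max_thermo(0.5, 10, 1e6)   # ~0.5 = alpha
#' @export
fc_max_thermo <- function(alpha, beta, P) {
  check_mode(alpha, beta)
  check_vec(P, "P", min = 0)
  alpha * beta * (1 + P) / (1 + beta * P)
}

#' Effective TF concentration chi
#'
#' `chi = R * (1 + beta * P) / (1 + P)`: the TF concentration rescaled by the
#' stabilization-dependent gain in TF occupancy when RNAP can co-bind.
#' `FC = (1 + chi * FC_max) / (1 + chi)`.
#'
#' @inheritParams state_weights
#' @return `chi` (dimensionless, >= 0). Vectorized. Errors for `R = Inf`.
#' @export
chi <- function(alpha, beta, P, R) {
  check_mode(alpha, beta)
  check_vec(P, "P", min = 0)
  check_vec(R, "R", min = 0)
  if (any(is.infinite(R))) {
    stop("chi is infinite at saturating R; use fc_max_thermo() for limits.",
         call. = FALSE)
  }
  R * (1 + beta * P) / (1 + P)
}

#' Critical acceleration alpha_c
#'
#' Below `alpha_c = P / (1 + P + R)` increasing stabilization beta *lowers*
#' the fold-change at finite TF concentration; above it, stabilization raises
#' fold-change. `alpha_c < 1` always: the inversion only ever happens for
#' decelerating TFs. As `R -> Inf`, `alpha_c -> 0`, which is why the effect
#' is invisible in `FC_max`.
#'
#' @param P Dimensionless promoter strength (> 0; `P = 0` returns 0 with a
#'   warning, the degenerate no-promoter limit).
#' @param R Dimensionless TF concentration (finite, >= 0).
#' @return `alpha_c` in `[0, 1)`. Vectorized.
#' @examples
#' alpha_critical(P = 1, R = 0)      # 0.5
#' alpha_critical(P = 0.2, R = 0.2)  # 1/7
#' @export
alpha_critical <- function(P, R) {
  check_vec(P, "P", min = 0)
  check_vec(R, "R", min = 0)
  if (any(is.infinite(R))) return(rep_len(0, max(length(P), length(R))))
  if (any(P == 0)) {
    warning("P = 0: alpha_c is degenerate (no promoter); returning 0.",
            call. = FALSE)
  }
  P / (1 + P + R)
}

#' Promoter strength at which regulation switches sign
#'
#' For incoherent TFs in the red region (`alpha < 1`, `alpha*beta > 1`) or
#' green region (`alpha > 1`, `alpha*beta < 1`) the saturating fold-change
#' crosses 1 at `P_s = (alpha*beta - 1) / (beta - alpha*beta)`: the promoter
#' strength at which the TF turns from activator into repressor (red) or vice
#' versa (green).
#'
#' @inheritParams state_weights
#' @return `P_s > 0`, satisfying `fc_max_thermo(alpha, beta, P_s) == 1`.
#' @examples
#' switch_promoter_strength(0.5, 4)  # 0.5
#' @export
switch_promoter_strength <- function(alpha, beta) {
  check_mode(alpha, beta)
  if (length(alpha) != 1L || length(beta) != 1L) {
    stop("switch_promoter_strength() takes scalar alpha, beta.", call. = FALSE)
  }
  ab <- alpha * beta
  if (abs(alpha - 1) < 1e-12 || abs(ab - 1) < 1e-12) {
    stop("no sign switch: P_s is undefined on the alpha = 1 or alpha*beta = 1 ",
         "boundary.", call. = FALSE)
  }
  red <- alpha < 1 && ab > 1
  green <- alpha > 1 && ab < 1
  if (!red && !green) {
    stop("no sign switch: FC_max does not cross 1 for alpha = ", alpha,
         ", beta = ", beta, " (need the red or green region).", call. = FALSE)
  }
  (ab - 1) / (beta - ab)
}

#' Classify a TF's regulatory region in (alpha, beta) space
#'
#' The lines `alpha = 1`, `beta = 1` and `alpha*beta = 1` partition the plane
#' into six regions, each with a characteristic response of `FC_max` to
#' titration of promoter strength:
#'
#' * `blue`   (`alpha*beta < 1`, `beta > 1`): low repression to high repression
#' * `red`    (`alpha*beta > 1`, `alpha < 1`): activation to repression
#' * `green`  (`alpha*beta < 1`, `alpha > 1`): repression to activation
#' * `gray`   (`alpha*beta > 1`, `beta < 1`): low activation to high activation
#' * `purple` (`alpha < 1`, `beta < 1`): high repression to low repression
#' * `yellow` (`alpha > 1`, `beta > 1`): high activation to low activation
#'
#' Points within `tolerance` (relative, in log space) of any dividing line
#' are labelled `boundary` so classification is deterministic and
#' side-stable under floating-point jitter.
#'
#' @inheritParams state_weights
#' @param tolerance Relative tolerance in `log(alpha)`, `log(beta)`,
#'   `log(alpha*beta)` for boundary detection (default `1e-9`).
#' @return A tibble with columns `alpha`, `beta`, `region` (factor) and
#'   `behavior` (how `FC_max` responds as `P` increases).
#' @examples
#' classify_region(0.5, 4)$region   # red
#' classify_region(2, 3)$region    # yellow
#' @export
classify_region <- function(alpha, beta, tolerance = 1e-9) {
  check_mode(alpha, beta)
  stopifnot(tolerance >= 0)
  n <- max(length(alpha), length(beta))
  alpha <- rep_len(alpha, n); beta <- rep_len(beta, n)
  la <- log(alpha); lb <- log(beta); lab <- la + lb
  on_line <- abs(la) <= tolerance | abs(lb) <= tolerance | abs(lab) <= tolerance
  region <- dplyr::case_when(
    on_line ~ "boundary",
    lab < 0 & lb > 0 ~ "blue",
    lab > 0 & la < 0 ~ "red",
    lab < 0 & la > 0 ~ "green",
    lab > 0 & lb < 0 ~ "gray",
    la < 0 & lb < 0 ~ "purple",
    TRUE ~ "yellow"
  )
  tibble::tibble(
    alpha = alpha, beta = beta,
    region = factor(region, levels = names(region_behaviors())),
    behavior = unname(region_behaviors()[region])
  )
}

#' Behavior strings for the six regulatory regions
#'
#' @return Named character vector mapping region label to the qualitative
#'   response of `FC_max` as promoter strength increases.
#' @export
region_behaviors <- function() {
  c(blue = "low repression to high repression",
    red = "activation to repression as P increases",
    green = "repression to activation as P increases",
    gray = "low activation to high activation",
    purple = "high repression to low repression",
    yellow = "high activation to low activation",
    boundary = "on a dividing line (alpha = 1, beta = 1 or alpha*beta = 1)")
}

## ---- argument checks ----

check_mode <- function(alpha, beta) {
  check_vec(alpha, "alpha", min = 0, strict = TRUE)
  check_vec(beta, "beta", min = 0, strict = TRUE)
  if (any(is.infinite(alpha)) || any(is.infinite(beta))) {
    stop("alpha and beta must be finite.", call. = FALSE)
  }
  invisible(NULL)
}

check_vec <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x)) {
    stop(name, " must be numeric and non-missing.", call. = FALSE)
  }
  bad <- if (strict) any(x <= min) else any(x < min)
  if (bad) {
    stop(name, " must be ", if (strict) "> " else ">= ", min, ".",
         call. = FALSE)
  }
  invisible(NULL)
}

check_scalar <- function(x, name, min = -Inf, strict = FALSE) {
  if (length(x) != 1L) stop(name, " must be a single value.", call. = FALSE)
  check_vec(x, name, min = min, strict = strict)
}
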