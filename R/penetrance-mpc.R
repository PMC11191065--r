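# Recurrent-event (MPC) penetrance. Primary-cancer onsets follow a
# nonhomogeneous Poisson process with Weibull baseline, individual gamma
# frailty and a prior-primary indicator D(t) that switches on after the first
# onset. The gamma frailty is conjugate: after observing n_prev events by
# t_prev the frailty posterior is Gamma(1/theta + n_prev, 1/theta +
# Lambda(0, t_prev)), giving closed-form next-primary penetrance.

mpc_linpred <- function(params, G, S, D) {
  exp(params$gamma_G * G + params$gamma_S * S + params$gamma_GxS * G * S +
        params$gamma_D * D + params$gamma_GxD * G * D)
}

# Lambda(a, b | X, Z = 1) with D(u) switching at t1 (NA = never)
mpc_cum_intensity <- function(a, b, G, S, params, t1 = NA_real_) {
  w <- function(t) (t / params$scale)^params$shape
  e0 <- mpc_linpred(params, G, S, 0)
  e1 <- mpc_linpred(params, G, S, 1)
  seg <- function(lo, hi, e) ifelse(hi > lo, (w(hi) - w(lo)) * e, 0)
  if (is.na(t1)) {
    seg(a, b, e0)
  } else {
    seg(pmin(a, t1), pmin(b, t1), e0) + seg(pmax(a, t1), pmax(b, t1), e1)
  }
}

#' Next-primary (MPC) penetrance
#'
#' Probability of developing the next primary cancer by age `t_next` given
#' `n_prev` primaries by age `t_prev` (first onset at `t1`, by default
#' `t_prev`). With cumulative intensity \eqn{\Lambda} and frailty variance
#' \eqn{\theta}:
#' \deqn{q = 1 - \left(\frac{1/\theta + \Lambda(0, t_{prev})}
#'   {1/\theta + \Lambda(0, t_{next})}\right)^{1/\theta + n_{prev}},}
#' where \eqn{\Lambda(0,\cdot)} uses D = 0 before the first onset and D = 1
#' after. At \eqn{\theta = 0} this reduces to the frailty-free Poisson form
#' \eqn{1 - e^{-\Lambda(t_{prev}, t_{next})}}. Supported up to the second
#' primary (`n_prev` in 0, 1).
#'
#' @param t_next Prediction age(s), years (>= `t_prev`).
#' @param t_prev Conditioning age (event history observed on `[0, t_prev)`).
#' @param n_prev Number of prior primaries (0 or 1).
#' @param G,S Carrier and sex (1 = female) indicators.
#' @param params An [mpc_params()] object.
#' @param t1 Age at first primary (defaults to `t_prev` when `n_prev = 1`).
#' @return Numeric vector of probabilities, 0 at `t_next = t_prev`,
#'   nondecreasing in `t_next`.
#' @export
mpc_penetrance <- function(t_next, t_prev = 0, n_prev = 0, G = 0, S = 0,
                           params = mpc_params(), t1 = NULL) {
  if (!n_prev %in% c(0, 1)) abort("n_prev must be 0 or 1 (supported up to second primary)")
  if (any(t_next < t_prev - 1e-12)) abort("t_next must be >= t_prev")
  if (params$theta < 0) abort("theta must be nonnegative")
  t1 <- if (n_prev == 0) NA_real_ else (t1 %||% t_prev)
  L_prev <- mpc_cum_intensity(0, t_prev, G, S, params, t1)
  L_next <- mpc_cum_intensity(0, t_next, G, S, params, t1)
  theta <- params$theta
  if (theta == 0) {
    1 - exp(-(L_next - L_prev))
  } else {
    a <- 1 / theta + n_prev
    1 - ((1 / theta + L_prev) / (1 / theta + L_next))^a
  }
}

#' Next-primary risk curve under the MPC model
#'
#' @inheritParams mpc_penetrance
#' @param ages Age grid (default integer years from `ceiling(t_prev)` to 100).
#' @return An `lfs_risk_curve` tibble (`age`, `outcome = "next_primary"`,
#'   `prob`).
#' @export
mpc_risk_curve <- function(t_prev = 0, n_prev = 0, G = 0, S = 0,
                           params = mpc_params(),
                           ages = seq(ceiling(t_prev), 100), t1 = NULL) {
  q <- mpc_penetrance(pmax(ages, t_prev), t_prev, n_prev, G, S, params, t1)
  new_risk_curve(tibble(age = ages, outcome = "next_primary", prob = q),
                 model = "MPC")
}

# Frailty-marginal joint likelihood factor E[Z^n exp(-Z s)] for
# Z ~ Gamma(1/theta, 1/theta):
#   Gamma(1/theta + n) / Gamma(1/theta) * (1/theta)^(1/theta)
#     / (1/theta + s)^(1/theta + n)
# log scale; theta = 0 degenerates to exp(-s) (Z == 1).
log_frailty_moment <- function(n, s, theta) {
  if (theta == 0) return(-s)
  a <- 1 / theta
  lgamma(a + n) - lgamma(a) + a * log(a) - (a + n) * log(a + s)
}
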