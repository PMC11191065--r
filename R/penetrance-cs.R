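# Cause-specific competing-risk penetrance under gamma frailty.
#
# Conditional on frailty Z = 1 the cumulative cause-k hazard is Weibull-PH,
#   Lambda_k(t|X) = (t/rho_k)^kappa_k * exp(beta_k . (G, S, G*S)),
# with the breast term forced to 0 for males. Marginalising a gamma(1/theta,
# 1/theta) frailty gives the crude incidence ("CS penetrance")
#   q_k(t|X) = int_0^t lambda_k(u|X) (1 + theta * Lambda.(u|X))^-(1/theta + 1) du
# and marginal all-cause survival (1 + theta * Lambda.(t|X))^-(1/theta), which
# together conserve probability: sum_k q_k(t) + S(t) = 1.

cs_linpred <- function(params, G, S) {
  e <- exp(params$beta_G * G + params$beta_S * S + params$beta_GxS * G * S)
  if (S == 0) e[["breast"]] <- 0  # structural zero, not a covariate effect
  e
}

# per-outcome Lambda_k(t | X, Z = 1) for vector t; returns length(t) x 4 matrix
cs_cumhaz_matrix <- function(t, e, params) {
  out <- vapply(CS_OUTCOMES, function(k) {
    (t / params$scale[[k]])^params$shape[[k]] * e[[k]]
  }, numeric(length(t)))
  matrix(out, nrow = length(t), ncol = 4, dimnames = list(NULL, CS_OUTCOMES))
}

# per-outcome hazard lambda_k(t | X, Z = 1)
cs_hazard_matrix <- function(t, e, params) {
  out <- vapply(CS_OUTCOMES, function(k) {
    kk <- params$shape[[k]]; rr <- params$scale[[k]]
    (kk / rr) * (t / rr)^(kk - 1) * e[[k]]
  }, numeric(length(t)))
  matrix(out, nrow = length(t), ncol = 4, dimnames = list(NULL, CS_OUTCOMES))
}

#' Cumulative cause-specific hazards (conditional on frailty = 1)
#'
#' @param t Age in years (scalar or vector, >= 0).
#' @param G Carrier indicator (0/1).
#' @param S Sex indicator (1 = female).
#' @param params A [cs_params()] object.
#' @return A tibble with `t`, one column per outcome, and `total`.
#' @export
cs_cumulative_hazard <- function(t, G, S, params = cs_params()) {
  if (any(t < 0)) abort("t must be nonnegative")
  e <- cs_linpred(params, G, S)
  L <- cs_cumhaz_matrix(t, e, params)
  out <- as_tibble(as.data.frame(L))
  out <- tibble(t = t) %>% dplyr::bind_cols(out)
  out$total <- rowSums(L)
  out
}

# frailty-marginal density weight: E[Z exp(-Z s)] = (1 + theta s)^-(1/theta + 1)
frailty_density_weight <- function(s, theta) {
  if (theta == 0) exp(-s) else (1 + theta * s)^(-(1 / theta + 1))
}

#' Marginal all-cause survival under the CS model
#'
#' @inheritParams cs_cumulative_hazard
#' @return Numeric vector of \eqn{(1+\theta\Lambda_\cdot(t))^{-1/\theta}}.
#' @export
cs_survival <- function(t, G, S, params = cs_params()) {
  e <- cs_linpred(params, G, S)
  tot <- rowSums(cs_cumhaz_matrix(t, e, params))
  if (params$theta == 0) exp(-tot) else (1 + params$theta * tot)^(-1 / params$theta)
}

#' Cause-specific penetrance (crude incidence)
#'
#' Probability of developing outcome `k` before all competing outcomes by age
#' `t`, marginal over the gamma frailty; computed by adaptive quadrature of the
#' subdensity (absolute tolerance 1e-9).
#'
#' @inheritParams cs_cumulative_hazard
#' @param outcomes Subset of outcomes to return.
#' @return A tibble `t`, `outcome`, `q` (long); `sum(q) + cs_survival(t) = 1`
#'   at each age.
#' @export
cs_penetrance <- function(t, G, S, params = cs_params(),
                          outcomes = CS_OUTCOMES) {
  if (any(t < 0)) abort("t must be nonnegative")
  if (params$theta < 0) abort("theta must be nonnegative")
  e <- cs_linpred(params, G, S)
  theta <- params$theta
  grid <- sort(unique(t))
  res <- map(outcomes, function(k) {
    if (e[[k]] == 0) return(tibble(t = grid, outcome = k, q = 0))
    integrand <- function(u) {
      tot <- rowSums(cs_cumhaz_matrix(u, e, params))
      cs_hazard_matrix(u, e, params)[, k] * frailty_density_weight(tot, theta)
    }
    qs <- numeric(length(grid))
    lo <- 0; acc <- 0
    for (i in seq_along(grid)) {
      if (grid[i] > lo) {
        acc <- acc + integrate(integrand, lo, grid[i],
                               abs.tol = 1e-11, rel.tol = 1e-10,
                               subdivisions = 400L)$value
        lo <- grid[i]
      }
      qs[i] <- acc
    }
    tibble(t = grid, outcome = k, q = qs)
  })
  out <- bind_rows(res)
  out[match(paste(rep(t, each = length(outcomes)), outcomes),
            paste(out$t, out$outcome)), ] %>%
    `rownames<-`(NULL)
}

#' First-primary risk curve under the CS model
#'
#' Per-outcome crude incidences on an integer age grid, optionally conditioned
#' on being event-free at age `from`:
#' \eqn{(q_k(t) - q_k(a)) / S(a)}.
#'
#' @inheritParams cs_cumulative_hazard
#' @param ages Age grid (default 0:100).
#' @param from Conditioning age (event-free at `from`; default 0).
#' @return An `lfs_risk_curve` tibble: `age`, `outcome`, `prob`.
#' @export
cs_risk_curve <- function(G, S, params = cs_params(), ages = 0:100, from = 0) {
  if (any(ages < from)) abort("ages must be >= the conditioning age")
  qs <- cs_penetrance(unique(c(from, ages)), G, S, params)
  surv0 <- cs_survival(from, G, S, params)
  out <- bind_rows(map(CS_OUTCOMES, function(k) {
    qk <- qs[qs$outcome == k, ]
    tibble(age = ages,
           outcome = k,
           prob = (qk$q[match(ages, qk$t)] -
                     qk$q[match(from, qk$t)]) / surv0)
  }))
  new_risk_curve(out, model = "CS")
}

new_risk_curve <- function(df, model) {
  structure(as_tibble(df), model = model,
            class = c("lfs_risk_curve", class(as_tibble(df))))
}

#' @export
autoplot.lfs_risk_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$age, y = .data$prob,
                               colour = .data$outcome)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Age (years)", y = "Cumulative probability",
                  colour = "Outcome",
                  title = paste0(attr(object, "model"), " risk curve")) +
    ggplot2::theme_minimal()
}
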