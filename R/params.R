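CS_OUTCOMES <- c("sarcoma", "breast", "other", "death")

#' Cause-specific (CS) competing-risk model parameters
#'
#' The CS model places a Weibull proportional-hazards cause-specific hazard on
#' each of the four competing outcomes (sarcoma, breast, all other cancers,
#' death), sharing a multiplicative gamma frailty with mean 1 and variance
#' `theta`:
#' \deqn{\lambda_k(t \mid X, Z) = Z\,\frac{\kappa_k}{\rho_k}
#'   \left(\frac{t}{\rho_k}\right)^{\kappa_k - 1}
#'   e^{\beta_{kG} G + \beta_{kS} S + \beta_{kGS} G S}.}
#' `G` is carrier status (1 = TP53 deleterious-variant carrier), `S` is sex
#' (1 = female); the breast hazard is identically 0 for males.
#'
#' The shipped defaults are plausible placeholders for testing and simulation
#' (carrier log hazard ratios of order 3); they are not fitted estimates.
#'
#' @param shape,scale Named numeric vectors over the four outcomes (Weibull
#'   shape kappa > 0 and scale rho > 0, scale in years).
#' @param beta_G,beta_S,beta_GxS Named log-hazard-ratio vectors.
#' @param theta Frailty variance (>= 0; 0 = no frailty).
#' @return A `cs_params` object.
#' @export
cs_params <- function(
    shape = c(sarcoma = 1.1, breast = 3.0, other = 2.5, death = 4.5),
    scale = c(sarcoma = 2500, breast = 180, other = 150, death = 110),
    beta_G = c(sarcoma = 3.4, breast = 2.8, other = 2.5, death = 0.5),
    beta_S = c(sarcoma = -0.2, breast = 0, other = -0.1, death = -0.2),
    beta_GxS = c(sarcoma = 0.1, breast = 0, other = 0.3, death = 0),
    theta = 0.5) {
  for (v in list(shape, scale, beta_G, beta_S, beta_GxS)) {
    stopifnot(setequal(names(v), CS_OUTCOMES))
  }
  stopifnot(all(shape > 0), all(scale > 0), theta >= 0)
  structure(
    list(shape = shape[CS_OUTCOMES], scale = scale[CS_OUTCOMES],
         beta_G = beta_G[CS_OUTCOMES], beta_S = beta_S[CS_OUTCOMES],
         beta_GxS = beta_GxS[CS_OUTCOMES], theta = theta),
    class = "cs_params"
  )
}

#' Multiple-primary-cancer (MPC) recurrent-event model parameters
#'
#' The MPC model treats primary-cancer onsets as a nonhomogeneous Poisson
#' process with a Weibull baseline intensity, individual gamma frailty
#' (mean 1, variance `theta`) and time-dependent covariates
#' \deqn{\lambda(t \mid X, Z) = Z\,\frac{\kappa}{\rho}
#'   \left(\frac{t}{\rho}\right)^{\kappa - 1}
#'   e^{\gamma_G G + \gamma_S S + \gamma_{GS} G S + \gamma_D D(t)
#'      + \gamma_{GD} G D(t)},}
#' where `D(t)` indicates a prior primary cancer before `t`. Penetrance is
#' supported up to the second primary.
#'
#' Defaults are testing placeholders, not fitted estimates.
#'
#' @param shape,scale Weibull baseline shape/scale (scale in years).
#' @param gamma_G,gamma_S,gamma_GxS,gamma_D,gamma_GxD Log-intensity-ratio
#'   coefficients.
#' @param theta Frailty variance (>= 0).
#' @return An `mpc_params` object.
#' @export
mpc_params <- function(shape = 2.2, scale = 130, gamma_G = 2.6, gamma_S = 0.3,
                       gamma_GxS = 0.2, gamma_D = 0.8, gamma_GxD = 0.2,
                       theta = 0.3) {
  stopifnot(shape > 0, scale > 0, theta >= 0)
  structure(
    list(shape = shape, scale = scale, gamma_G = gamma_G, gamma_S = gamma_S,
         gamma_GxS = gamma_GxS, gamma_D = gamma_D, gamma_GxD = gamma_GxD,
         theta = theta),
    class = "mpc_params"
  )
}

#' @export
print.cs_params <- function(x, ...) {
  cat("<cs_params> Weibull cause-specific hazards, gamma frailty theta =",
      x$theta, "\n")
  print(tibble(outcome = CS_OUTCOMES, shape = unname(x$shape),
               scale = unname(x$scale), beta_G = unname(x$beta_G),
               beta_S = unname(x$beta_S), beta_GxS = unname(x$beta_GxS)))
  invisible(x)
}

#' @export
print.mpc_params <- function(x, ...) {
  cat("<mpc_params> Weibull NHPP intensity, gamma frailty theta =", x$theta,
      "\n  shape", x$shape, " scale", x$scale,
      "\n  gamma: G", x$gamma_G, " S", x$gamma_S, " GxS", x$gamma_GxS,
      " D", x$gamma_D, " GxD", x$gamma_GxD, "\n")
  invisible(x)
}

#' Read / write model parameters as flat key-value text
#'
#' Format: one `key = value` per line, `#` comments allowed. CS keys are
#' `cs.<outcome>.<field>` with outcome in sarcoma/breast/other/death and field
#' in shape/scale/beta_G/beta_S/beta_GxS, plus `cs.theta`. MPC keys are
#' `mpc.shape`, `mpc.scale`, `mpc.gamma_G`, `mpc.gamma_S`, `mpc.gamma_GxS`,
#' `mpc.gamma_D`, `mpc.gamma_GxD`, `mpc.theta`. Missing keys keep defaults.
#'
#' @param path File path.
#' @return `read_model_params()`: list with elements `cs` (`cs_params`) and
#'   `mpc` (`mpc_params`).
#' @export
read_model_params <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(map_chr(kv, 1))
  vals <- as.numeric(trimws(map_chr(kv, 2)))
  get <- function(key, default) {
    i <- match(key, keys)
    if (is.na(i)) default else vals[i]
  }
  cs_def <- cs_params()
  vec <- function(field) {
    setNames(map_dbl(CS_OUTCOMES, function(k) {
      get(paste0("cs.", k, ".", field), cs_def[[field]][[k]])
    }), CS_OUTCOMES)
  }
  cs <- cs_params(shape = vec("shape"), scale = vec("scale"),
                  beta_G = vec("beta_G"), beta_S = vec("beta_S"),
                  beta_GxS = vec("beta_GxS"),
                  theta = get("cs.theta", cs_def$theta))
  mp <- mpc_params()
  mpc <- mpc_params(
    shape = get("mpc.shape", mp$shape), scale = get("mpc.scale", mp$scale),
    gamma_G = get("mpc.gamma_G", mp$gamma_G),
    gamma_S = get("mpc.gamma_S", mp$gamma_S),
    gamma_GxS = get("mpc.gamma_GxS", mp$gamma_GxS),
    gamma_D = get("mpc.gamma_D", mp$gamma_D),
    gamma_GxD = get("mpc.gamma_GxD", mp$gamma_GxD),
    theta = get("mpc.theta", mp$theta)
  )
  list(cs = cs, mpc = mpc)
}

#' @rdname read_model_params
#' @param cs,mpc Parameter objects to serialise.
#' @export
write_model_params <- function(path, cs = cs_params(), mpc = mpc_params()) {
  lines <- c(
    unlist(map(CS_OUTCOMES, function(k) {
      map_chr(c("shape", "scale", "beta_G", "beta_S", "beta_GxS"), function(fd) {
        paste0("cs.", k, ".", fd, " = ", format(cs[[fd]][[k]], digits = 15))
      })
    })),
    paste0("cs.theta = ", format(cs$theta, digits = 15)),
    map_chr(c("shape", "scale", "gamma_G", "gamma_S", "gamma_GxS",
              "gamma_D", "gamma_GxD", "theta"), function(fd) {
      paste0("mpc.", fd, " = ", format(mpc[[fd]], digits = 15))
    })
  )
  writeLines(lines, path)
  invisible(path)
}
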