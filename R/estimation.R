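# Likelihood-based parameter estimation on family data. The family-wise
# marginal likelihood is computed by peeling with the observed test results
# as genotype clamps; an optional ascertainment correction conditions on the
# proband's data (their confirmed carrier genotype together with their
# observed affection status) — a simplified proband-conditioning scheme.
# Estimation is by quasi-Newton maximum likelihood with box constraints;
# standard errors come from the observed information at the optimum.

#' Family log marginal likelihood
#'
#' `log peel_likelihood` of one family under the given penetrance parameters,
#' with every available test result used as a genotype clamp. With
#' `correction = TRUE` the log probability of the ascertainment event — the
#' proband clamped as a carrier with their observed phenotype — is
#' subtracted; a zero ascertainment probability yields `-Inf`.
#'
#' @param ped An `lfs_pedigree` holding one family.
#' @param params [cs_params()] or [mpc_params()].
#' @param model `"cs"` or `"mpc"`.
#' @param f Allele frequency.
#' @param correction Apply the proband-conditioning ascertainment correction?
#' @return Log marginal likelihood (scalar; `-Inf` on contradictions).
#' @export
family_loglik <- function(ped, params, model = c("cs", "mpc"), f = 0.0006,
                          correction = FALSE) {
  model <- match.arg(model)
  ped <- one_family(as_tibble(ped))
  tabs <- phenotype_tables(ped, params, model)
  clamps <- scenario_clamps(ped, "all_tests")
  ll <- log_peel_likelihood(ped, tabs, clamps, f)
  if (correction) {
    pro <- ped$id[ped$proband][1]
    if (is.na(pro)) abort("ascertainment correction requires a proband")
    pro_tabs <- setNames(list(tabs[[pro]]), pro)
    ll_asc <- log_peel_likelihood(ped, pro_tabs,
                                  setNames(list("carrier"), pro), f)
    if (!is.finite(ll_asc)) {
      warn(paste0("family ", ped$family_id[1],
                  ": zero ascertainment probability"))
      return(-Inf)
    }
    ll <- ll - ll_asc
  }
  ll
}

# --- parameter packing -------------------------------------------------------

cs_par_names <- function() {
  c(paste0(rep(CS_OUTCOMES, each = 5), ".",
           rep(c("shape", "scale", "beta_G", "beta_S", "beta_GxS"), 4)),
    "theta")
}

cs_pack <- function(params) {
  v <- unlist(map(CS_OUTCOMES, function(k) {
    c(params$shape[[k]], params$scale[[k]], params$beta_G[[k]],
      params$beta_S[[k]], params$beta_GxS[[k]])
  }))
  setNames(c(v, params$theta), cs_par_names())
}

cs_unpack <- function(v) {
  g <- function(fd) setNames(v[paste0(CS_OUTCOMES, ".", fd)], CS_OUTCOMES)
  cs_params(shape = g("shape"), scale = g("scale"), beta_G = g("beta_G"),
            beta_S = g("beta_S"), beta_GxS = g("beta_GxS"),
            theta = unname(v["theta"]))
}

mpc_par_names <- function() {
  c("shape", "scale", "gamma_G", "gamma_S", "gamma_GxS", "gamma_D",
    "gamma_GxD", "theta")
}

mpc_pack <- function(params) {
  setNames(unlist(params[mpc_par_names()]), mpc_par_names())
}

mpc_unpack <- function(v) {
  do.call(mpc_params, as.list(v[mpc_par_names()]))
}

# fast vectorised CS log-likelihood for fully-genotyped cohorts: with every
# genotype clamped, the Mendelian prior factorises out of the hazard
# likelihood, so the kernel is a sum of closed-form per-individual terms
prep_cs_data <- function(cohort) {
  cohort <- as_tibble(cohort)
  rows <- map(seq_len(nrow(cohort)), function(i) {
    ob <- pheno_obs(cohort[i, ])
    S <- as.integer(cohort$sex[i] == "female")
    G <- as.integer(cohort$test[i] == "carrier")
    if (ob$n_total > 0) {
      if (is.na(ob$first_age)) return(NULL)
      tibble(G = G, S = S, type = ob$first_type, age = ob$first_age)
    } else if (ob$dead && !is.na(ob$age_death)) {
      tibble(G = G, S = S, type = "death", age = ob$age_death)
    } else if (!is.na(ob$cens) && ob$cens > 0) {
      tibble(G = G, S = S, type = "censored", age = ob$cens)
    } else {
      NULL
    }
  })
  bind_rows(rows)
}

cs_loglik_vec <- function(data, params) {
  theta <- params$theta
  ll <- 0
  for (G in 0:1) for (S in 0:1) {
    d <- data[data$G == G & data$S == S, ]
    if (nrow(d) == 0) next
    e <- cs_linpred(params, G, S)
    tot <- rowSums(cs_cumhaz_matrix(d$age, e, params))
    ev <- d$type != "censored"
    if (theta == 0) {
      ll <- ll - sum(tot[!ev]) - sum(tot[ev])
    } else {
      ll <- ll - sum(log1p(theta * tot[!ev])) / theta -
        sum((1 / theta + 1) * log1p(theta * tot[ev]))
    }
    if (any(ev)) {
      haz <- cs_hazard_matrix(d$age[ev], e, params)
      hk <- haz[cbind(seq_len(sum(ev)), match(d$type[ev], CS_OUTCOMES))]
      if (any(hk <= 0)) return(-Inf)
      ll <- ll + sum(log(hk))
    }
  }
  ll
}

#' Maximum-likelihood fit of the penetrance models on family data
#'
#' Quasi-Newton (L-BFGS-B) maximisation of the summed family log-likelihoods
#' over a chosen free-parameter subset, with box constraints keeping shapes,
#' scales and the frailty variance in their domains. For fully-genotyped
#' cohorts under the CS model without ascertainment correction, a vectorised
#' closed-form kernel is used (the Mendelian genotype prior is a constant and
#' is added once); otherwise each evaluation peels every family.
#'
#' @param cohort An `lfs_pedigree` cohort (>= 2 families).
#' @param model `"cs"` or `"mpc"`.
#' @param free Names of free parameters (see `cs_params()` fields flattened
#'   as `outcome.field`, plus `theta`; MPC uses its own field names). Default:
#'   the CS carrier log-hazard-ratios for the three cancer outcomes.
#' @param init Parameter object to start from (also supplies fixed values).
#' @param f Allele frequency.
#' @param correction Proband-conditioning ascertainment correction.
#' @param n_starts Number of optimisation starts (jittered from `init`).
#' @param seed Seed for the start jitter.
#' @return An `lfs_fit`: tibble of estimates with observed-information
#'   standard errors, `converged`, `loglik`.
#' @export
fit_mle <- function(cohort, model = c("cs", "mpc"),
                    free = c("sarcoma.beta_G", "breast.beta_G",
                             "other.beta_G"),
                    init = NULL, f = 0.0006, correction = FALSE,
                    n_starts = 1, seed = 1) {
  model <- match.arg(model)
  cohort <- as_tibble(cohort)
  if (length(unique(cohort$family_id)) < 2) abort("need at least 2 families")
  init <- init %||% (if (model == "cs") cs_params() else mpc_params())
  full <- if (model == "cs") cs_pack(init) else mpc_pack(init)
  stopifnot(all(free %in% names(full)))
  pos <- grepl("shape|scale", free)
  th <- free == "theta"
  lower <- ifelse(pos, 1e-3, ifelse(th, 1e-6, -20))
  upper <- ifelse(pos, 1e4, ifelse(th, 50, 20))

  all_tested <- all(cohort$test != "untested")
  if (model == "cs" && all_tested && !correction) {
    dat <- prep_cs_data(cohort)
    # constant Mendelian prior term, computed once by peeling with all-ones
    # tables so the reported log-likelihood equals sum(family_loglik)
    prior_const <- sum(map_dbl(split_families(cohort), function(p) {
      log_peel_likelihood(p, list(), scenario_clamps(p, "all_tests"), f)
    }))
    objective <- function(v) {
      full[free] <- v
      ll <- cs_loglik_vec(dat, cs_unpack(full))
      if (!is.finite(ll)) return(1e10)
      -(ll + prior_const)
    }
  } else {
    fams <- split_families(cohort)
    objective <- function(v) {
      full[free] <- v
      p <- if (model == "cs") cs_unpack(full) else mpc_unpack(full)
      ll <- sum(map_dbl(fams, function(fm) {
        family_loglik(fm, p, model, f, correction)
      }))
      if (!is.finite(ll)) return(1e10) else -ll
    }
  }

  set.seed(seed)
  starts <- map(seq_len(n_starts), function(s) {
    v <- full[free]
    if (s > 1) v <- v * runif(length(v), 0.7, 1.3) + runif(length(v), -0.3, 0.3)
    pmin(pmax(v, lower), upper)
  })
  fits <- map(starts, function(v0) {
    optim(v0, objective, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = 500))
  })
  best <- fits[[which.min(map_dbl(fits, "value"))]]
  H <- tryCatch(stats::optimHess(best$par, objective), error = function(e) NULL)
  se <- rep(NA_real_, length(free))
  if (!is.null(H)) {
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov)) {
      d <- diag(cov)
      se <- ifelse(d > 0, sqrt(d), NA_real_)
    }
  }
  full[free] <- best$par
  structure(
    list(
      estimates = tibble(term = free, estimate = unname(best$par), se = se),
      params = if (model == "cs") cs_unpack(full) else mpc_unpack(full),
      model = model, converged = best$convergence == 0,
      loglik = -best$value,
      n_families = length(unique(cohort$family_id)),
      starts = map_dbl(fits, function(ft) -ft$value)
    ),
    class = "lfs_fit"
  )
}

#' @export
print.lfs_fit <- function(x, ...) {
  cat("<lfs_fit> ", toupper(x$model), " model, ", x$n_families, " families, ",
      "logLik ", sprintf("%.2f", x$loglik),
      if (x$converged) " (converged)\n" else " (NOT converged)\n", sep = "")
  print(x$estimates)
  invisible(x)
}

#' @export
tidy.lfs_fit <- function(x, ...) {
  x$estimates %>%
    mutate(conf.low = .data$estimate - 1.96 * .data$se,
           conf.high = .data$estimate + 1.96 * .data$se)
}

#' @export
glance.lfs_fit <- function(x, ...) {
  tibble(model = x$model, logLik = x$loglik, converged = x$converged,
         n_families = x$n_families, n_params = nrow(x$estimates))
}
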