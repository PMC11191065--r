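# Per-genotype phenotype likelihoods: the probability (density) of an
# individual's observed cancer history and censoring given genotype and sex,
# under either the MPC or the CS model. These are the entries that the peeling
# engine multiplies into the family likelihood. Dominance makes the entries
# for 1 and 2 copies identical. The construction follows the Mendelian
# (BayesMendel-style) framework: events with known ages contribute marginal
# event densities, the gap to censoring contributes the marginal probability
# of no further event, and any component whose age is unknown contributes 1
# (structure-only information).

# observation summary used by both models
pheno_obs <- function(ind) {
  cc <- ind$cancers[[1]]
  ages <- cc$age_dx
  known <- sort(ages[!is.na(ages)])
  n_total <- nrow(cc)
  cens <- if (ind$vital == "dead" && !is.na(ind$age_death)) {
    ind$age_death
  } else {
    ind$age_last_contact
  }
  first_type <- if (n_total > 0) cc$type[which.min(cc$primary_index)] else NA_character_
  first_age <- if (n_total > 0) cc$age_dx[which.min(cc$primary_index)] else NA_real_
  list(n_total = n_total, known = known, cens = cens,
       first_type = first_type, first_age = first_age,
       dead = ind$vital == "dead", age_death = ind$age_death)
}

#' Phenotype likelihood vector over genotypes
#'
#' Evaluates the likelihood of one individual's observed phenotype (cancer
#' events, vital status, censoring age) for genotypes 0, 1 and 2 copies of the
#' deleterious allele (entries for 1 and 2 copies equal, by dominance).
#'
#' Under the MPC model the contribution is
#' \eqn{\prod_j \lambda_0(t_j) e^{\gamma X(t_j)} \cdot E[Z^n e^{-Z \Lambda(0,c)}]}
#' with the prior-primary indicator switching after the first onset. Under the
#' CS model only the first event enters (cause-specific density at its age, or
#' the marginal survival for unaffected individuals; a death without prior
#' cancer is the competing "death" outcome). Events with unknown diagnosis age
#' contribute 1 and truncate the no-further-event window at the last known
#' age; an individual with no usable ages at all gets the all-ones vector.
#'
#' @param ind A one-row `lfs_pedigree` slice.
#' @param params [mpc_params()] or [cs_params()].
#' @param model `"mpc"` (default) or `"cs"`.
#' @return Numeric length-3 vector (genotype 0, 1, 2), nonnegative.
#' @export
phenotype_likelihood <- function(ind, params = mpc_params(),
                                 model = c("mpc", "cs")) {
  model <- match.arg(model)
  ob <- pheno_obs(ind)
  if (length(ob$known) > 0 && !is.na(ob$cens) &&
      ob$cens < max(ob$known) - 1e-9) {
    abort(paste0("individual ", ind$id,
                 ": censoring age earlier than last known onset age"))
  }
  S <- as.integer(ind$sex == "female")
  lik <- function(G) {
    if (model == "mpc") mpc_pheno_lik(ob, G, S, params)
    else cs_pheno_lik(ob, G, S, params)
  }
  l0 <- as.numeric(lik(0)); l1 <- as.numeric(lik(1))
  c(l0, l1, l1)
}

mpc_pheno_lik <- function(ob, G, S, params) {
  known <- head(ob$known, 2)  # penetrance supported to the second primary
  n <- length(known)
  # end of the verified event-free window
  w_end <- if (ob$n_total > n || is.na(ob$cens)) {
    if (n == 0) NA_real_ else max(known)
  } else {
    ob$cens
  }
  if (n == 0 && is.na(w_end)) return(1)
  t1 <- if (n >= 1) known[1] else NA_real_
  log_dens <- 0
  if (n >= 1) {
    for (j in seq_len(n)) {
      D <- as.integer(j > 1)
      kk <- params$shape; rr <- params$scale
      log_dens <- log_dens +
        log((kk / rr) * (known[j] / rr)^(kk - 1)) +
        log(mpc_linpred(params, G, S, D))
    }
  }
  s <- mpc_cum_intensity(0, w_end, G, S, params, t1)
  exp(log_dens + log_frailty_moment(n, s, params$theta))
}

cs_pheno_lik <- function(ob, G, S, params) {
  e <- cs_linpred(params, G, S)
  theta <- params$theta
  if (ob$n_total > 0) {
    # first event is the competing-risk outcome; later history is outside CS
    if (is.na(ob$first_age)) return(1)
    t1 <- ob$first_age
    tot <- rowSums(cs_cumhaz_matrix(t1, e, params))
    haz <- cs_hazard_matrix(t1, e, params)[, ob$first_type]
    return(haz * frailty_density_weight(tot, theta))
  }
  if (ob$dead && !is.na(ob$age_death)) {
    td <- ob$age_death
    tot <- rowSums(cs_cumhaz_matrix(td, e, params))
    return(cs_hazard_matrix(td, e, params)[, "death"] *
             frailty_density_weight(tot, theta))
  }
  if (is.na(ob$cens) || ob$cens <= 0) return(1)
  tot <- rowSums(cs_cumhaz_matrix(ob$cens, e, params))
  if (theta == 0) exp(-tot) else (1 + theta * tot)^(-1 / theta)
}

# likelihood tables for a whole family: named list id -> numeric(3)
phenotype_tables <- function(ped, params = mpc_params(), model = "mpc") {
  ped <- as_tibble(ped)
  tabs <- map(seq_len(nrow(ped)), function(i) {
    phenotype_likelihood(ped[i, ], params, model)
  })
  setNames(tabs, ped$id)
}
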