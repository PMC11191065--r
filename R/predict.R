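#' Predict carrier probability for a counselee
#'
#' Thin orchestration of [carrier_posterior()] over a prediction request.
#'
#' @param ped An `lfs_pedigree` holding one family.
#' @param counselee Id of the counselee.
#' @param scenario Test-usage scenario (see [carrier_posterior()]).
#' @param params,model,f,de_novo Passed to [carrier_posterior()].
#' @return One-row tibble `id`, `prob`, `scenario`.
#' @export
predict_carrier <- function(ped, counselee, scenario = "all_tests",
                            params = mpc_params(), model = "mpc",
                            f = 0.0006, de_novo = 0) {
  carrier_posterior(ped, counselee, scenario, params, model, f, de_novo)
}

#' Predict first-primary cancer risks (CS model)
#'
#' Genotype-weighted cause-specific risk curve for a cancer-free counselee:
#' \deqn{q_k(t) = p\, q_k^{cs}(t \mid G{=}1) + (1-p)\, q_k^{cs}(t \mid G{=}0)}
#' with `p` the counselee's carrier posterior; conditioning on being
#' event-free at the current age is applied per genotype before weighting.
#'
#' @inheritParams predict_carrier
#' @param cs [cs_params()] penetrance parameters.
#' @param ages Age grid for the curve.
#' @param from Current (event-free) age; ages below it are rejected.
#' @return An `lfs_risk_curve` tibble with attribute `carrier_prob`.
#' @export
predict_first_primary <- function(ped, counselee, scenario = "all_tests",
                                  cs = cs_params(), params = mpc_params(),
                                  model = "mpc", f = 0.0006,
                                  ages = NULL, from = NULL) {
  ped <- one_family(as_tibble(ped))
  row <- ped[ped$id == counselee, ]
  if (nrow(row$cancers[[1]]) > 0) {
    abort("counselee must be cancer-free for first-primary prediction")
  }
  from <- from %||% (if (!is.na(row$age_last_contact)) row$age_last_contact else 0)
  ages <- ages %||% seq(ceiling(from), 100)
  if (any(ages < from)) abort("prediction ages must be >= current age")
  p <- predict_carrier(ped, counselee, scenario, params, model, f)$prob
  S <- as.integer(row$sex == "female")
  c1 <- cs_risk_curve(1, S, cs, ages = ages, from = from)
  c0 <- cs_risk_curve(0, S, cs, ages = ages, from = from)
  out <- c1
  out$prob <- p * c1$prob + (1 - p) * c0$prob
  attr(out, "carrier_prob") <- p
  attr(out, "model") <- "CS (genotype-weighted)"
  out
}

#' Predict second-primary risk (MPC model)
#'
#' For a counselee with exactly one known primary at age `t1`, the
#' genotype-weighted next-primary penetrance
#' \eqn{p\,q^{mpc}(t \mid t_1, G{=}1) + (1-p)\,q^{mpc}(t \mid t_1, G{=}0)},
#' where the carrier posterior `p` is computed with the first cancer included
#' in the phenotype likelihood.
#'
#' @inheritParams predict_carrier
#' @param ages Age grid (default integer ages from the first onset to 100).
#' @return An `lfs_risk_curve` tibble with attribute `carrier_prob`.
#' @export
predict_second_primary <- function(ped, counselee, scenario = "all_tests",
                                   params = mpc_params(), f = 0.0006,
                                   ages = NULL) {
  ped <- one_family(as_tibble(ped))
  row <- ped[ped$id == counselee, ]
  cc <- row$cancers[[1]]
  if (nrow(cc) < 1) abort("counselee has no recorded primary cancer")
  t1 <- cc$age_dx[cc$primary_index == 1]
  if (length(t1) == 0 || is.na(t1)) {
    abort("first-primary diagnosis age unknown: counselee is excluded")
  }
  ages <- ages %||% seq(ceiling(t1), 100)
  p <- predict_carrier(ped, counselee, scenario, params, "mpc", f)$prob
  S <- as.integer(row$sex == "female")
  q1 <- mpc_penetrance(pmax(ages, t1), t1, 1, 1, S, params)
  q0 <- mpc_penetrance(pmax(ages, t1), t1, 1, 0, S, params)
  out <- new_risk_curve(
    tibble(age = ages, outcome = "next_primary", prob = p * q1 + (1 - p) * q0),
    model = "MPC (genotype-weighted)"
  )
  attr(out, "carrier_prob") <- p
  out
}
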