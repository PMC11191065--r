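# Exact pedigree likelihood by genotype peeling (Elston-Stewart). The
# pedigree's genotype distribution is a factor graph: Hardy-Weinberg priors on
# founders, Mendelian transmission factors p(child | father, mother), and
# per-individual phenotype/clamp factors. Sum-product variable elimination
# with a greedy min-width order computes the marginal likelihood (and any
# single-individual genotype marginal) exactly; on loop-free pedigrees the
# elimination cliques are the nuclear families, so cost is linear in the
# number of nuclear families, and marriage loops only enlarge the local
# cliques, never break exactness. Intermediate factors are max-rescaled with
# an accumulated log scale to avoid underflow on large families.

state_grid <- local({
  cache <- list()
  function(k) {
    key <- as.character(k)
    if (is.null(cache[[key]])) {
      m <- 3L^k
      G <- matrix(0L, nrow = m, ncol = k)
      for (j in seq_len(k)) {
        G[, j] <- rep(rep(0:2, each = 3L^(j - 1L)), length.out = m)
      }
      cache[[key]] <<- G
    }
    cache[[key]]
  }
})

# factor: list(vars = character ids, vals = numeric of length 3^k,
# var j varying fastest for j = 1)
f_index <- function(G, cols) {
  if (length(cols) == 0) return(rep(1L, nrow(G)))
  1L + as.integer(G[, cols, drop = FALSE] %*% 3L^(seq_along(cols) - 1L))
}

f_join <- function(f1, f2) {
  vars <- union(f1$vars, f2$vars)
  G <- state_grid(length(vars))
  vals <- f1$vals[f_index(G, match(f1$vars, vars))] *
    f2$vals[f_index(G, match(f2$vars, vars))]
  list(vars = vars, vals = vals)
}

f_marginalize <- function(f, var) {
  keep <- setdiff(f$vars, var)
  if (length(keep) == 0) return(list(vars = character(), vals = sum(f$vals)))
  G <- state_grid(length(f$vars))
  idx <- f_index(G, match(keep, f$vars))
  vals <- numeric(3L^length(keep))
  acc <- rowsum(f$vals, idx)
  vals[as.integer(rownames(acc))] <- acc[, 1]
  list(vars = keep, vals = vals)
}

# core engine: returns list(loglik, marginal) where marginal (if target given)
# is the unnormalised genotype marginal of target on the natural scale of
# exp(loglik_contributions), i.e. sum(marginal) * exp(log_scale) = likelihood.
peel_engine <- function(ped, tables, clamps = list(), f = 0.0006,
                        de_novo = 0, target = NULL) {
  ped <- as_tibble(ped)
  ids <- ped$id
  hw <- hw_prior(f)
  tr <- transmission_array(de_novo)
  factors <- list()
  for (i in seq_len(nrow(ped))) {
    id <- ids[i]
    if (is.na(ped$father_id[i])) {
      factors[[length(factors) + 1]] <- list(vars = id, vals = hw)
    } else {
      fa <- ped$father_id[i]; mo <- ped$mother_id[i]
      factors[[length(factors) + 1]] <-
        list(vars = c(fa, mo, id), vals = as.numeric(tr))
    }
    pen <- tables[[id]] %||% c(1, 1, 1)
    if (!is.null(clamps[[id]])) pen <- pen * clamp_indicator(clamps[[id]])
    if (!all(pen == 1)) {
      factors[[length(factors) + 1]] <- list(vars = id, vals = pen)
    }
  }
  log_scale <- 0
  elim <- setdiff(ids, target)
  while (length(elim) > 0) {
    # greedy min-width: eliminate the variable whose neighbourhood is smallest
    widths <- map_dbl(elim, function(v) {
      length(Reduce(union, map(keep(factors, ~ v %in% .x$vars), "vars")))
    })
    v <- elim[which.min(widths)]
    elim <- setdiff(elim, v)
    inv <- map_lgl(factors, ~ v %in% .x$vars)
    joined <- Reduce(f_join, factors[inv])
    red <- f_marginalize(joined, v)
    m <- max(red$vals)
    if (m <= 0) return(list(loglik = -Inf, marginal = rep(0, 3)))
    red$vals <- red$vals / m
    log_scale <- log_scale + log(m)
    factors <- c(factors[!inv], list(red))
  }
  final <- Reduce(f_join, factors)
  if (is.null(target)) {
    tot <- sum(final$vals)  # scalar factor product
    list(loglik = log_scale + log(tot), marginal = NULL)
  } else {
    stopifnot(identical(final$vars, target))
    tot <- sum(final$vals)
    list(loglik = if (tot > 0) log_scale + log(tot) else -Inf,
         marginal = final$vals)
  }
}

#' Family-wise marginal likelihood by peeling
#'
#' Sums \eqn{\prod_i \mathrm{prior}_i(g) \prod_i \mathrm{table}_i(g_i)} over
#' all genotype configurations by Elston-Stewart peeling; equals the
#' brute-force [enumerate_genotype_configs()] sum exactly, in time linear in
#' the number of nuclear families for loop-free pedigrees.
#'
#' @param ped An `lfs_pedigree` holding one family.
#' @param tables Named list id -> length-3 phenotype likelihood vector
#'   (missing ids get all-ones), e.g. from [phenotype_likelihood()].
#' @param clamps Named list id -> genotype (0/1/2) or `"carrier"` /
#'   `"wildtype"`. Inconsistent clamps give likelihood 0, not an error.
#' @param f Allele frequency.
#' @param de_novo De novo mutation rate per gamete.
#' @return The marginal likelihood (numeric scalar).
#' @export
peel_likelihood <- function(ped, tables = list(), clamps = list(),
                            f = 0.0006, de_novo = 0) {
  res <- peel_engine(one_family(as_tibble(ped)), tables, clamps, f, de_novo)
  exp(res$loglik)
}

log_peel_likelihood <- function(ped, tables = list(), clamps = list(),
                                f = 0.0006, de_novo = 0) {
  peel_engine(one_family(as_tibble(ped)), tables, clamps, f, de_novo)$loglik
}

scenario_clamps <- function(ped, scenario) {
  ped <- as_tibble(ped)
  use <- switch(scenario,
    tests_ignored = rep(FALSE, nrow(ped)),
    proband_clamped = ped$proband & ped$test != "untested",
    all_tests = ped$test != "untested",
    abort(paste0("unknown scenario: ", scenario))
  )
  cl <- as.list(ped$test[use])
  setNames(cl, ped$id[use])
}

#' Posterior carrier probability from family history
#'
#' Computes \eqn{P(G \ge 1 \mid \mathrm{family\ data})} for one family member
#' by exact peeling: the genotype marginal of the target given every member's
#' phenotype likelihood and whichever test results the scenario turns into
#' genotype clamps.
#'
#' Scenarios: `"tests_ignored"` (no test result used, mimicking pre-test
#' counseling), `"proband_clamped"` (only the proband's confirmed genotype is
#' used), `"all_tests"` (every available test result used; a tested target
#' then gets posterior exactly 1 or 0).
#'
#' @param ped An `lfs_pedigree` holding one family.
#' @param target Id of the counselee.
#' @param scenario One of `"tests_ignored"`, `"proband_clamped"`,
#'   `"all_tests"`.
#' @param params Penetrance parameters for the phenotype likelihood.
#' @param model `"mpc"` (default, the recommended carrier-inference model) or
#'   `"cs"`.
#' @param f Allele frequency; `de_novo` de novo rate.
#' @param de_novo De novo mutation rate per gamete.
#' @param tables Optional precomputed phenotype tables (overrides `params` /
#'   `model`).
#' @return A one-row tibble: `id`, `prob`, `scenario`.
#' @export
carrier_posterior <- function(ped, target, scenario = "all_tests",
                              params = mpc_params(), model = "mpc",
                              f = 0.0006, de_novo = 0, tables = NULL) {
  ped <- one_family(as_tibble(ped))
  if (!target %in% ped$id) abort(paste0("target '", target, "' not in family"))
  if (is.null(tables)) tables <- phenotype_tables(ped, params, model)
  clamps <- scenario_clamps(ped, scenario)
  res <- peel_engine(ped, tables, clamps, f, de_novo, target = target)
  tot <- sum(res$marginal)
  if (!is.finite(res$loglik) || tot <= 0) {
    abort(paste0("zero-probability conditioning for target '", target,
                 "': clamps contradict the pedigree"))
  }
  tibble(id = target, prob = (res$marginal[2] + res$marginal[3]) / tot,
         scenario = scenario)
}
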