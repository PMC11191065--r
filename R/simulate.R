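# Synthetic family-cohort generator: the stand-in for clinically ascertained
# LFS family data. Families are built over a configurable number of
# generations with Mendelian transmission of a rare dominant allele and one
# seeded carrier lineage (so ascertainment through a carrier proband is
# feasible); cancer histories are drawn from the same CS/MPC models the
# package predicts with; ascertainment retains families with a tested,
# affected carrier proband; and the clinical-counseling missingness profile
# blanks ages at the observed category rates.

#' Cohort generator configuration
#'
#' @param n_families Number of families to generate (before ascertainment).
#' @param f Deleterious-allele founder frequency.
#' @param generations Pedigree depth (default 3).
#' @param offspring_mean Mean of the truncated-Poisson offspring law
#'   (Poisson(`offspring_mean`) conditioned on 1..`offspring_max`).
#' @param offspring_max Upper truncation for offspring counts.
#' @param partner_prob Probability a non-final-generation member partners (a
#'   married-in founder) and reproduces.
#' @param cs,mpc Penetrance parameters driving the phenotype simulation.
#' @param censor_bounds List of `c(lo, hi)` current-age bounds per generation
#'   (uniform draw); generations beyond the list reuse the last entry.
#' @param missingness `"complete"` or `"ccb"`, or a 4-vector of category
#'   probabilities (complete, missing age-at-last-contact only, missing
#'   diagnosis-age only, missing both). `"ccb"` uses the clinical rates
#'   (0.53, 0.41, 0.04, 0.02).
#' @param test_prob Probability a nonproband relative was tested.
#' @param seed_carrier Seed one founding-couple member as a heterozygous
#'   carrier (default `TRUE`; makes carrier-proband ascertainment feasible at
#'   realistic allele frequencies). With `FALSE` all founders draw from
#'   Hardy-Weinberg, so the Mendelian prior used in inference matches the
#'   generative law exactly.
#' @param seed Integer seed; mandatory for any persisted cohort.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_families = 50, f = 0.0006, generations = 3,
                          offspring_mean = 2.5, offspring_max = 8,
                          partner_prob = 0.7,
                          cs = cs_params(), mpc = mpc_params(),
                          censor_bounds = list(c(55, 90), c(30, 65), c(5, 40)),
                          missingness = "complete", test_prob = 0.15,
                          seed_carrier = TRUE, seed = 1L) {
  prof <- missingness_profile(missingness)
  structure(
    list(n_families = n_families, f = f, generations = generations,
         offspring_mean = offspring_mean, offspring_max = offspring_max,
         partner_prob = partner_prob, cs = cs, mpc = mpc,
         censor_bounds = censor_bounds, missingness = prof,
         test_prob = test_prob, seed_carrier = isTRUE(seed_carrier),
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

missingness_profile <- function(x) {
  if (is.character(x)) {
    x <- switch(x,
      complete = c(1, 0, 0, 0),
      ccb = c(0.53, 0.41, 0.04, 0.02),
      abort(paste0("unknown missingness profile: ", x))
    )
  }
  stopifnot(length(x) == 4, all(x >= 0), abs(sum(x) - 1) < 1e-9)
  setNames(x, c("complete", "alc", "dx", "both"))
}

rtpois <- function(n, lambda, max) {
  # Poisson(lambda) conditioned on 1..max
  out <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      k <- rpois(1, lambda)
      if (k >= 1 && k <= max) { out[i] <- k; break }
    }
  }
  out
}

#' Simulate pedigree structure with genotypes
#'
#' Builds multigeneration families: a founding couple (one member seeded as a
#' heterozygous carrier so a carrier lineage exists), truncated-Poisson
#' offspring, married-in founder spouses drawn from Hardy-Weinberg(`f`), and
#' Mendelian transmission to children. Phenotype columns are present but
#' empty; the latent truth is kept in a `genotype` column and a `generation`
#' column records depth.
#'
#' @param config A [cohort_config()].
#' @param seed Optional seed override.
#' @return An `lfs_pedigree` cohort (families `fam1`, `fam2`, ...).
#' @export
simulate_structure <- function(config = cohort_config(), seed = NULL) {
  set.seed(seed %||% config$seed)
  hw <- hw_prior(config$f)
  fams <- map(seq_len(config$n_families), function(fi) {
    rows <- list()
    nid <- 0L
    new_ind <- function(sex, gen, fa = NA_character_, mo = NA_character_,
                        genotype = NA_integer_) {
      nid <<- nid + 1L
      id <- as.character(nid)
      if (is.na(genotype)) {
        genotype <- if (is.na(fa)) {
          sample(0:2, 1, prob = hw)
        } else {
          gf <- rows[[fa]]$genotype; gm <- rows[[mo]]$genotype
          p <- transmission_array(0)[gf + 1, gm + 1, ]
          sample(0:2, 1, prob = p)
        }
      }
      rows[[id]] <<- list(id = id, father_id = fa, mother_id = mo, sex = sex,
                          generation = gen, genotype = genotype)
      id
    }
    seed_side <- if (config$seed_carrier %||% TRUE) {
      if (runif(1) < 0.5) "male" else "female"
    } else {
      "none"
    }
    fa0 <- new_ind("male", 1L, genotype = if (seed_side == "male") 1L else NA)
    mo0 <- new_ind("female", 1L,
                   genotype = if (seed_side == "female") 1L else NA)
    couples <- list(list(fa = fa0, mo = mo0, gen = 1L))
    while (length(couples) > 0) {
      cp <- couples[[1]]; couples <- couples[-1]
      if (cp$gen >= config$generations) next
      nkid <- rtpois(1, config$offspring_mean, config$offspring_max)
      for (k in seq_len(nkid)) {
        sex <- sample(c("male", "female"), 1)
        kid <- new_ind(sex, cp$gen + 1L, fa = cp$fa, mo = cp$mo)
        if (cp$gen + 1L < config$generations &&
            runif(1) < config$partner_prob) {
          spouse_sex <- if (sex == "male") "female" else "male"
          sp <- new_ind(spouse_sex, cp$gen + 1L)
          couples[[length(couples) + 1]] <-
            if (sex == "male") list(fa = kid, mo = sp, gen = cp$gen + 1L)
            else list(fa = sp, mo = kid, gen = cp$gen + 1L)
        }
      }
    }
    df <- bind_rows(map(rows, as_tibble))
    df$family_id <- paste0("fam", fi)
    df
  })
  ped <- bind_rows(fams)
  ped$proband <- FALSE
  ped$test <- "untested"
  ped$vital <- "unknown"
  ped$age_last_contact <- NA_real_
  ped$age_death <- NA_real_
  ped$cancers <- rep(list(empty_cancers()), nrow(ped))
  as_lfs_pedigree(ped[, c("family_id", "id", "father_id", "mother_id", "sex",
                          "proband", "test", "vital", "age_last_contact",
                          "age_death", "cancers", "generation", "genotype")])
}

# inverse-transform draw of the first CS event; returns list(time, type) or
# NULL when no event occurs before `horizon`
draw_cs_first_event <- function(G, S, z, cs, horizon) {
  e <- cs_linpred(cs, G, S)
  target <- rexp(1) / z
  tot <- function(t) rowSums(cs_cumhaz_matrix(t, e, cs))
  if (tot(horizon) < target) return(NULL)
  t_ev <- uniroot(function(t) tot(t) - target, c(1e-9, horizon),
                  tol = 1e-10)$root
  haz <- cs_hazard_matrix(t_ev, e, cs)[1, ]
  type <- sample(CS_OUTCOMES, 1, prob = haz)
  list(time = t_ev, type = type)
}

# second-primary gap from the MPC conditional law given one primary at t1
draw_mpc_second <- function(G, S, t1, mpc, horizon) {
  e1 <- mpc_linpred(mpc, G, S, 1)
  L0 <- mpc_cum_intensity(0, t1, G, S, mpc)  # D = 0 before first onset
  theta <- mpc$theta
  if (theta == 0) {
    need <- rexp(1)
  } else {
    a <- 1 / theta + 1
    A <- 1 / theta + L0
    need <- A * (runif(1)^(-1 / a) - 1)
  }
  w1 <- (t1 / mpc$scale)^mpc$shape
  t2 <- mpc$scale * (w1 + need / e1)^(1 / mpc$shape)
  if (t2 < horizon) t2 else NULL
}

#' Simulate cancer phenotypes on a genotyped pedigree
#'
#' Per individual: a current age is drawn from the generation-specific
#' censoring law; an individual gamma frailty is drawn; the first event (one
#' of the three cancer groups or death) comes from the CS cause-specific
#' hazards by inverse transform on the total hazard, with the type drawn from
#' the hazard ratios at the event time; a death first-event truncates
#' follow-up; after a first cancer, a second primary (recorded without a
#' specific type, as `"other"`) is drawn from the MPC next-primary conditional
#' law (frailty updated by the observed history); right-censoring at the
#' current age throughout.
#'
#' @param ped Output of [simulate_structure()] (needs `genotype`,
#'   `generation`).
#' @param config A [cohort_config()] (penetrance parameters + censoring law).
#' @param seed Optional seed override.
#' @param hazard_scale Multiplier on all hazards (0 gives an all-censored
#'   cohort).
#' @return The pedigree with `cancers`, `vital`, `age_last_contact`,
#'   `age_death` filled in.
#' @export
simulate_phenotypes <- function(ped, config = cohort_config(), seed = NULL,
                                hazard_scale = 1) {
  if (!is.null(seed)) set.seed(seed)
  ped <- as_tibble(ped)
  cs <- config$cs; mpc <- config$mpc
  nb <- length(config$censor_bounds)
  for (i in seq_len(nrow(ped))) {
    gen <- min(ped$generation[i], nb)
    b <- config$censor_bounds[[gen]]
    cur <- runif(1, b[1], b[2])
    G <- as.integer(ped$genotype[i] >= 1)
    S <- as.integer(ped$sex[i] == "female")
    z <- if (cs$theta > 0) rgamma(1, 1 / cs$theta, 1 / cs$theta) else 1
    z <- z * hazard_scale
    ev <- if (z > 0) draw_cs_first_event(G, S, z, cs, cur) else NULL
    if (is.null(ev)) {
      ped$vital[i] <- "alive"
      ped$age_last_contact[i] <- cur
      next
    }
    if (ev$type == "death") {
      ped$vital[i] <- "dead"
      ped$age_death[i] <- ev$time
      ped$age_last_contact[i] <- ev$time
      next
    }
    cc <- tibble(type = ev$type, subtype = NA_character_,
                 age_dx = ev$time, primary_index = 1L)
    if (hazard_scale > 0) {
      t2 <- draw_mpc_second(G, S, ev$time, mpc, cur)
      if (!is.null(t2)) {
        cc <- bind_rows(cc, tibble(type = "other", subtype = NA_character_,
                                   age_dx = t2, primary_index = 2L))
      }
    }
    ped$cancers[[i]] <- cc
    ped$vital[i] <- "alive"
    ped$age_last_contact[i] <- cur
  }
  ped
}

#' Ascertain families through a tested carrier proband
#'
#' Assigns test results (probands always tested; nonprobands independently
#' with probability `test_prob`), then retains families containing at least
#' one eligible proband — a carrier (1+ copies) with at least one cancer —
#' and flags one such member, chosen at random, as the proband.
#'
#' @param cohort A phenotype-simulated cohort with `genotype`.
#' @param config A [cohort_config()].
#' @param seed Optional seed override.
#' @param rule `"carrier_affected"` (default) or `"none"` (identity: no
#'   selection, no proband change).
#' @return The ascertained cohort subset.
#' @export
ascertain <- function(cohort, config = cohort_config(), seed = NULL,
                      rule = c("carrier_affected", "none")) {
  rule <- match.arg(rule)
  if (rule == "none") return(cohort)
  if (!is.null(seed)) set.seed(seed)
  cohort <- as_tibble(cohort)
  kept <- map(split_families(cohort), function(p) {
    eligible <- p$genotype >= 1 & map_dbl(p$cancers, nrow) > 0
    if (!any(eligible)) return(NULL)
    w <- which(eligible)
    pro <- if (length(w) == 1) w else sample(w, 1)
    p$proband <- FALSE
    p$proband[pro] <- TRUE
    tested <- runif(nrow(p)) < config$test_prob
    tested[pro] <- TRUE
    p$test <- ifelse(tested, ifelse(p$genotype >= 1, "carrier", "wildtype"),
                     "untested")
    p
  })
  out <- bind_rows(kept)
  if (nrow(out) == 0) return(out)
  class(out) <- c("lfs_pedigree", class(as_tibble(out)))
  out
}

#' Apply the clinical-counseling missingness profile
#'
#' Each nonproband individual is independently assigned one of four
#' categories — complete, missing age at last contact only, missing diagnosis
#' age only, missing both — and the corresponding ages are blanked (age at
#' last contact together with age at death, since both encode the end of
#' follow-up; diagnosis ages of all recorded cancers). Probands are never
#' blanked. The assigned category is recorded in a `miss_category` column so
#' the profile is recoverable.
#'
#' @param cohort A cohort pedigree.
#' @param profile `"ccb"`, `"complete"` or a 4-vector (see [cohort_config()]).
#' @param seed Optional seed.
#' @return The cohort with ages blanked and `miss_category` added.
#' @export
apply_missingness <- function(cohort, profile = "ccb", seed = NULL) {
  prof <- missingness_profile(profile)
  if (!is.null(seed)) set.seed(seed)
  cohort <- as_tibble(cohort)
  cat_lv <- names(prof)
  draw <- sample(cat_lv, nrow(cohort), replace = TRUE, prob = prof)
  draw[cohort$proband] <- "complete"
  cohort$miss_category <- draw
  blank_alc <- draw %in% c("alc", "both")
  blank_dx <- draw %in% c("dx", "both")
  cohort$age_last_contact[blank_alc] <- NA_real_
  cohort$age_death[blank_alc] <- NA_real_
  cohort$cancers <- map2(cohort$cancers, blank_dx, function(cc, bl) {
    if (bl && nrow(cc) > 0) cc$age_dx <- NA_real_
    cc
  })
  class(cohort) <- c("lfs_pedigree", class(as_tibble(cohort)))
  cohort
}

#' Simulate a full cohort (structure, phenotypes, ascertainment, missingness)
#'
#' @param config A [cohort_config()].
#' @return An ascertained `lfs_pedigree` cohort with the configured
#'   missingness applied.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  ped <- simulate_structure(config, seed = config$seed)
  ped <- simulate_phenotypes(ped, config)
  ped <- ascertain(ped, config)
  if (nrow(ped) == 0) return(ped)
  apply_missingness(ped, config$missingness)
}

#' Write a cohort with a reproducibility manifest
#'
#' Writes the cohort in both pedigree dialects plus a JSON manifest recording
#' the generating configuration and seed, so a run is reproducible from its
#' manifest alone.
#'
#' @param cohort The cohort pedigree.
#' @param dir Output directory (created if needed).
#' @param config The generating [cohort_config()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(cohort, file.path(dir, "cohort.ped"), "ped")
  write_pedigree(cohort, file.path(dir, "cohort.csv"), "csv")
  manifest <- unclass(config)
  manifest$cs <- unclass(manifest$cs)
  manifest$mpc <- unclass(manifest$mpc)
  jsonlite::write_json(
    list(config = manifest, seed = config$seed,
         n_families = length(unique(cohort$family_id)),
         n_individuals = nrow(cohort)),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
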