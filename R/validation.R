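# The validation study as a reusable pipeline: exclusion filters, subject
# grouping, ROC/AUC, observed/expected calibration, family-bootstrap CIs, and
# the mutation-prediction and cancer-risk validation runs.

censor_age <- function(ped) {
  ifelse(!is.na(ped$age_death), ped$age_death, ped$age_last_contact)
}

#' Apply the validation exclusion rules
#'
#' A family member is excluded from the validation subject set when they have
#' (1) an unknown diagnosis age for the first or second primary cancer, or
#' (2) an unknown age at last contact while never having had cancer. Excluded
#' members stay in their pedigrees (they still inform peeling); they only
#' carry no label.
#'
#' @param cohort An `lfs_pedigree` cohort.
#' @return A list: `subjects` (tibble `family_id`, `id`, `group`, `t1_age`,
#'   `t2_age`, `n_primaries`, `sex`, `test`, `proband`, `first_type`,
#'   `outcome`) and `excluded` (`family_id`, `id`, `reason`).
#' @export
apply_exclusions <- function(cohort) {
  cohort <- as_tibble(cohort)
  n_prim <- map_dbl(cohort$cancers, nrow)
  cens <- censor_age(cohort)
  sub <- list(); exc <- list()
  for (i in seq_len(nrow(cohort))) {
    cc <- cohort$cancers[[i]]
    if (nrow(cc) == 0) {
      if (is.na(cens[i])) {
        exc[[length(exc) + 1]] <- tibble(
          family_id = cohort$family_id[i], id = cohort$id[i],
          reason = "unknown age at last contact")
        next
      }
      first_type <- if (cohort$vital[i] == "dead") "death" else NA_character_
      sub[[length(sub) + 1]] <- tibble(
        family_id = cohort$family_id[i], id = cohort$id[i],
        group = 1L, t1_age = cens[i], t2_age = NA_real_,
        n_primaries = 0L, sex = cohort$sex[i], test = cohort$test[i],
        proband = cohort$proband[i], first_type = first_type)
      next
    }
    dx12 <- cc$age_dx[cc$primary_index <= 2]
    if (any(is.na(dx12))) {
      exc[[length(exc) + 1]] <- tibble(
        family_id = cohort$family_id[i], id = cohort$id[i],
        reason = "unknown age at cancer diagnosis")
      next
    }
    grp <- if (nrow(cc) >= 2) 3L else 2L
    t1 <- cc$age_dx[cc$primary_index == 1]
    t2 <- if (grp == 3L) cc$age_dx[cc$primary_index == 2] else cens[i]
    sub[[length(sub) + 1]] <- tibble(
      family_id = cohort$family_id[i], id = cohort$id[i],
      group = grp, t1_age = t1, t2_age = t2,
      n_primaries = as.integer(nrow(cc)), sex = cohort$sex[i],
      test = cohort$test[i], proband = cohort$proband[i],
      first_type = cc$type[cc$primary_index == 1])
  }
  list(
    subjects = if (length(sub)) bind_rows(sub) else tibble(
      family_id = character(), id = character(), group = integer(),
      t1_age = numeric(), t2_age = numeric(), n_primaries = integer(),
      sex = character(), test = character(), proband = logical(),
      first_type = character()),
    excluded = if (length(exc)) bind_rows(exc) else tibble(
      family_id = character(), id = character(), reason = character())
  )
}

#' Group validation subjects and attach evaluation ages
#'
#' Group 1: no cancer (task-1 evaluation age = age at last contact); group 2:
#' single primary (task-1 age = first diagnosis age, task-2 age = age at last
#' contact); group 3: multiple primaries (task-1 age = first, task-2 age =
#' second diagnosis age).
#'
#' @param subjects The `subjects` tibble from [apply_exclusions()].
#' @return The tibble with `group`, `t1_age`, `t2_age` (already attached by
#'   [apply_exclusions()]); exposed as its own step for clarity.
#' @export
build_groups <- function(subjects) {
  subjects %>% arrange(.data$family_id, .data$group, .data$id)
}

#' Midrank ROC curve and AUC
#'
#' AUC by the Mann-Whitney midrank formula (ties contribute 1/2), with the
#' staircase ROC over all distinct score cutoffs.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcomes (0/1).
#' @return A list: `auc`, `roc` (tibble `cutoff`, `fpr`, `tpr` including the
#'   (0,0) and (1,1) endpoints), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("AUC undefined: both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cuts <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(cuts, function(c) sum(scores >= c & labels == 1), numeric(1))
  fp <- vapply(cuts, function(c) sum(scores >= c & labels == 0), numeric(1))
  roc <- tibble(cutoff = c(Inf, cuts), fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  list(auc = auc, roc = roc, n_pos = n1, n_neg = n0)
}

#' Observed/expected calibration ratio
#'
#' @param labels Binary outcomes.
#' @param predicted Predicted event probabilities in `[0, 1]`.
#' @return `sum(labels) / sum(predicted)`; 1 indicates calibration.
#' @export
oe_ratio <- function(labels, predicted) {
  stopifnot(all(predicted >= -1e-12), all(predicted <= 1 + 1e-12))
  if (sum(predicted) <= 0) abort("zero expected count: O/E undefined")
  sum(labels) / sum(predicted)
}

#' Bootstrap percentile confidence interval (family resampling)
#'
#' Resamples by the chosen unit (families by default, preserving within-family
#' correlation) and returns the percentile 2.5/97.5 interval of the metric
#' over `B` replicates. Replicates on which the metric is undefined (e.g. a
#' single-class AUC resample) are redrawn, counted, and capped.
#'
#' @param data A tibble of per-subject rows including `family_id`.
#' @param metric Function `data -> numeric scalar` (may error on degenerate
#'   resamples).
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Seed for the resampling.
#' @param unit `"family"` or `"individual"`.
#' @param level Confidence level (default 0.95).
#' @return A list: `lower`, `upper`, `values`, `n_redrawn`.
#' @export
bootstrap_ci <- function(data, metric, B = 1000, seed = 1, unit = "family",
                         level = 0.95) {
  stopifnot(B >= 1)
  set.seed(seed)
  fams <- unique(data$family_id)
  vals <- numeric(B)
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    ok <- FALSE
    for (try in seq_len(50)) {
      d <- if (unit == "family") {
        pick <- sample(fams, length(fams), replace = TRUE)
        bind_rows(map(pick, function(fam) data[data$family_id == fam, ]))
      } else {
        data[sample(nrow(data), nrow(data), replace = TRUE), ]
      }
      v <- tryCatch(metric(d), error = function(e) NA_real_)
      if (is.finite(v)) { vals[b] <- v; ok <- TRUE; break }
      n_redrawn <- n_redrawn + 1L
    }
    if (!ok) vals[b] <- NA_real_
  }
  a <- (1 - level) / 2
  qs <- quantile(vals, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(lower = qs[1], upper = qs[2], values = vals, n_redrawn = n_redrawn)
}

new_validation_report <- function(task, subjects, B, seed, cutoffs,
                                  extra = list()) {
  ra <- roc_auc(subjects$score, subjects$label)
  auc_ci <- bootstrap_ci(subjects, function(d) roc_auc(d$score, d$label)$auc,
                         B = B, seed = seed)
  oe <- oe_ratio(subjects$label, subjects$score)
  oe_ci <- bootstrap_ci(subjects, function(d) oe_ratio(d$label, d$score),
                        B = B, seed = seed + 1L)
  ops <- map(cutoffs, function(ct) {
    tibble(cutoff = ct,
           tpr = mean(subjects$score[subjects$label == 1] >= ct),
           fpr = mean(subjects$score[subjects$label == 0] >= ct))
  }) %>% bind_rows()
  structure(
    c(list(task = task, subjects = subjects, roc = ra$roc, auc = ra$auc,
           auc_ci = c(auc_ci$lower, auc_ci$upper), oe = oe,
           oe_ci = c(oe_ci$lower, oe_ci$upper), operating_points = ops,
           counts = c(n = nrow(subjects), n_pos = ra$n_pos, n_neg = ra$n_neg),
           B = B, seed = seed),
      extra),
    class = "lfs_validation_report"
  )
}

#' @export
print.lfs_validation_report <- function(x, ...) {
  cat("<lfs_validation_report> task:", x$task, "\n")
  cat(sprintf("  n = %d (%d positive / %d negative)\n",
              x$counts["n"], x$counts["n_pos"], x$counts["n_neg"]))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  O/E %.2f (95%% CI %.2f-%.2f)\n", x$oe, x$oe_ci[1], x$oe_ci[2]))
  invisible(x)
}

#' @export
tidy.lfs_validation_report <- function(x, ...) {
  tibble(
    task = x$task,
    metric = c("auc", "oe"),
    estimate = c(x$auc, x$oe),
    conf.low = c(x$auc_ci[1], x$oe_ci[1]),
    conf.high = c(x$auc_ci[2], x$oe_ci[2])
  )
}

#' @export
glance.lfs_validation_report <- function(x, ...) {
  tibble(task = x$task, n = unname(x$counts["n"]),
         n_pos = unname(x$counts["n_pos"]), n_neg = unname(x$counts["n_neg"]),
         auc = x$auc, oe = x$oe, B = x$B)
}

#' @export
autoplot.lfs_validation_report <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = paste0(object$task, " (AUC ",
                                 sprintf("%.2f", object$auc), ")")) +
    ggplot2::theme_minimal()
}

# carrier posteriors for a set of ids, computing each family's phenotype
# tables once
cohort_posteriors <- function(cohort, ids, scenario, params, model, f) {
  cohort <- as_tibble(cohort)
  out <- map(split_families(cohort), function(p) {
    want <- intersect(ids, p$id)
    if (length(want) == 0) return(NULL)
    tabs <- phenotype_tables(p, params, model)
    bind_rows(map(want, function(tg) {
      carrier_posterior(p, tg, scenario, params, model, f, tables = tabs) %>%
        mutate(family_id = p$family_id[1])
    }))
  })
  bind_rows(out)
}

#' Mutation-prediction validation
#'
#' Scores tested validation subjects with their family-history carrier
#' posterior and compares against the confirmed genotypes. Scenario `"A"`
#' disregards all testing results and includes the probands; scenario `"B"`
#' clamps exactly the probands' confirmed genotypes and scores the tested
#' nonprobands.
#'
#' @param cohort An `lfs_pedigree` cohort with tested individuals.
#' @param scenario `"A"` or `"B"`.
#' @param cutoffs Decision thresholds for the reported operating points
#'   (default 0.20).
#' @param params,model,f Carrier-inference model (see [carrier_posterior()]).
#' @param B,seed Bootstrap replicates and seed.
#' @param criteria Also report the Classic/Chompret criteria as comparator
#'   operating points (family-level rules applied to each subject's family)?
#' @return An `lfs_validation_report`; scenario B carries an audit tibble
#'   `clamped` listing the proband clamps used.
#' @export
run_mutation_validation <- function(cohort, scenario = c("A", "B"),
                                    cutoffs = 0.20, params = mpc_params(),
                                    model = "mpc", f = 0.0006, B = 1000,
                                    seed = 1, criteria = TRUE) {
  scenario <- match.arg(scenario)
  cohort <- as_tibble(cohort)
  ex <- apply_exclusions(cohort)
  subj <- ex$subjects[ex$subjects$test != "untested", ]
  if (scenario == "B") subj <- subj[!subj$proband, ]
  if (nrow(subj) == 0) abort("no tested validation subjects")
  peel_scenario <- if (scenario == "A") "tests_ignored" else "proband_clamped"
  post <- cohort_posteriors(cohort, subj$id, peel_scenario, params, model, f)
  subj <- subj %>%
    left_join(post %>% select("family_id", "id", "prob"),
              by = c("family_id", "id")) %>%
    mutate(score = .data$prob, label = as.integer(.data$test == "carrier"))
  extra <- list(scenario = scenario)
  if (scenario == "B") {
    pro <- cohort[cohort$proband & cohort$test != "untested", ]
    extra$clamped <- tibble(family_id = pro$family_id, id = pro$id,
                            clamp = pro$test)
  }
  if (criteria) {
    crit <- map(split_families(cohort), function(p) {
      if (!any(p$proband)) return(NULL)
      tibble(family_id = p$family_id[1],
             classic = as.logical(classic_criteria(p)),
             chompret = as.logical(chompret_criteria(p)))
    }) %>% bind_rows()
    cs_subj <- subj %>% left_join(crit, by = "family_id")
    extra$criteria <- tibble(
      rule = c("classic", "chompret"),
      tpr = c(mean(cs_subj$classic[cs_subj$label == 1], na.rm = TRUE),
              mean(cs_subj$chompret[cs_subj$label == 1], na.rm = TRUE)),
      fpr = c(mean(cs_subj$classic[cs_subj$label == 0], na.rm = TRUE),
              mean(cs_subj$chompret[cs_subj$label == 0], na.rm = TRUE))
    )
  }
  new_validation_report(paste0("mutation-", scenario), subj, B, seed, cutoffs,
                        extra)
}

#' Cancer-risk validation
#'
#' Runs the cancer-risk prediction tasks on the validation subjects (probands
#' excluded for ascertainment reasons): task 1 discriminates subjects with at
#' least one primary from those without, scoring each at their task-1
#' evaluation age; task 2 discriminates multiple from single primaries at the
#' task-2 age; the CS model instead produces four one-vs-rest reports
#' (sarcoma, breast, other, death) at the age at first event. The secondary
#' filter `"inferred"` keeps tested subjects plus untested ones whose carrier
#' posterior is > 0.1 (inferred carriers) or < 0.001 (inferred wildtypes),
#' strict inequalities.
#'
#' @param cohort An `lfs_pedigree` cohort.
#' @param model `"mpc"`, `"cs"` or `"km"` (KM runs task 1 only).
#' @param filter `"all"` or `"inferred"`.
#' @param params,cs,f Model parameters for scoring and carrier inference.
#' @param B,seed Bootstrap settings.
#' @param cutoffs Operating-point cutoffs.
#' @return A named list of `lfs_validation_report`s (tasks that end up empty
#'   or single-class are flagged as `list(empty = TRUE, task = ...)`).
#' @export
run_cancer_validation <- function(cohort, model = c("mpc", "cs", "km"),
                                  filter = c("all", "inferred"),
                                  params = mpc_params(), cs = cs_params(),
                                  f = 0.0006, B = 1000, seed = 1,
                                  cutoffs = 0.20) {
  model <- match.arg(model)
  filter <- match.arg(filter)
  cohort <- as_tibble(cohort)
  ex <- apply_exclusions(cohort)
  subj <- build_groups(ex$subjects[!ex$subjects$proband, ])
  if (nrow(subj) == 0) return(list(task1 = list(empty = TRUE, task = "task1")))
  post <- cohort_posteriors(cohort, subj$id, "all_tests", params, "mpc", f)
  subj <- subj %>%
    left_join(post %>% select("family_id", "id", "prob"),
              by = c("family_id", "id"))
  if (filter == "inferred") {
    subj <- subj[subj$test != "untested" | subj$prob > 0.1 | subj$prob < 0.001, ]
  }
  S <- as.integer(subj$sex == "female")
  mk <- function(s, task, extra = list()) {
    if (nrow(s) == 0 || length(unique(s$label)) < 2) {
      return(list(empty = TRUE, task = task))
    }
    new_validation_report(task, s, B, seed, cutoffs, extra)
  }
  out <- list()
  if (model == "mpc") {
    q1 <- map_dbl(seq_len(nrow(subj)), function(i) {
      mpc_penetrance(subj$t1_age[i], 0, 0, 1, S[i], params)
    })
    q0 <- map_dbl(seq_len(nrow(subj)), function(i) {
      mpc_penetrance(subj$t1_age[i], 0, 0, 0, S[i], params)
    })
    s1 <- subj %>% mutate(score = .data$prob * q1 + (1 - .data$prob) * q0,
                          label = as.integer(.data$group >= 2))
    out$task1 <- mk(s1, "anycancer")
    # group-2 members need an age at last contact to be evaluated for task 2
    s2 <- subj[subj$group >= 2 & !is.na(subj$t2_age), ]
    if (nrow(s2) > 0) {
      S2 <- as.integer(s2$sex == "female")
      w1 <- map_dbl(seq_len(nrow(s2)), function(i) {
        mpc_penetrance(s2$t2_age[i], s2$t1_age[i], 1, 1, S2[i], params)
      })
      w0 <- map_dbl(seq_len(nrow(s2)), function(i) {
        mpc_penetrance(s2$t2_age[i], s2$t1_age[i], 1, 0, S2[i], params)
      })
      s2 <- s2 %>% mutate(score = .data$prob * w1 + (1 - .data$prob) * w0,
                          label = as.integer(.data$group == 3))
      out$task2 <- mk(s2, "spc-vs-mpc")
    } else {
      out$task2 <- list(empty = TRUE, task = "spc-vs-mpc")
    }
  } else if (model == "km") {
    tested <- subj[subj$test != "untested", ]
    km <- fit_km_penetrance(tibble(
      sex = tested$sex, carrier = as.integer(tested$test == "carrier"),
      age = tested$t1_age, event = as.integer(tested$group >= 2)))
    sk <- subj %>%
      mutate(score = map_dbl(seq_len(nrow(subj)), function(i) {
        km_risk(subj$t1_age[i], subj$prob[i], subj$sex[i], km)
      }),
      label = as.integer(.data$group >= 2))
    sk <- sk[!is.na(sk$score), ]
    out$task1 <- mk(sk, "anycancer-km", list(km = km))
  } else {
    # CS one-vs-rest at the age at first event
    for (k in CS_OUTCOMES) {
      qk1 <- map_dbl(seq_len(nrow(subj)), function(i) {
        cs_penetrance(subj$t1_age[i], 1, S[i], cs, outcomes = k)$q
      })
      qk0 <- map_dbl(seq_len(nrow(subj)), function(i) {
        cs_penetrance(subj$t1_age[i], 0, S[i], cs, outcomes = k)$q
      })
      lab <- if (k == "death") {
        as.integer(subj$group == 1 & !is.na(subj$first_type) &
                     subj$first_type == "death")
      } else {
        as.integer(subj$group >= 2 & subj$first_type == k)
      }
      sk <- subj %>% mutate(score = .data$prob * qk1 + (1 - .data$prob) * qk0,
                            label = lab)
      out[[paste0("cs-", k)]] <- mk(sk, paste0("cs-", k, "-vs-rest"))
    }
  }
  out
}
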