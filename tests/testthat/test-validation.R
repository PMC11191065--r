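test_that("exclusion rules mirror the missing-age categories", {
  coh <- as_lfs_pedigree(bind_rows(
    make_individual("a", alc = 60),                                  # complete healthy
    make_individual("b", alc = NA),                                  # healthy, no last contact
    make_individual("c", sex = "female", alc = 50,
                    cancers = cancer("breast", NA)),                 # SPC, unknown dx
    make_individual("d", sex = "female", alc = 50, proband = TRUE,
                    cancers = cancer("breast", 30))                  # complete SPC
  ))
  ex <- apply_exclusions(coh)
  expect_setequal(ex$subjects$id, c("a", "d"))
  expect_setequal(ex$excluded$id, c("b", "c"))
  expect_equal(ex$excluded$reason[ex$excluded$id == "b"],
               "unknown age at last contact")
  expect_equal(ex$excluded$reason[ex$excluded$id == "c"],
               "unknown age at cancer diagnosis")
  expect_equal(nrow(ex$subjects) + nrow(ex$excluded), nrow(coh))

  # complete cohort: nothing excluded; blanked categories match exclusions
  cfg <- cohort_config(n_families = 6, seed = 17, test_prob = 0.3)
  full <- simulate_cohort(cfg)
  expect_equal(nrow(apply_exclusions(full)$excluded), 0)
  ccb <- apply_missingness(full, "ccb", seed = 5)
  ex2 <- apply_exclusions(ccb)
  affected <- map_dbl(ccb$cancers, nrow) > 0
  expect_excluded <- ifelse(affected,
                            ccb$miss_category %in% c("dx", "both"),
                            ccb$miss_category %in% c("alc", "both"))
  expect_setequal(ex2$excluded$id, ccb$id[expect_excluded])
})

test_that("groups carry the task evaluation ages", {
  coh <- as_lfs_pedigree(bind_rows(
    make_individual("h", alc = 60),
    make_individual("s", sex = "female", alc = 50,
                    cancers = cancer("breast", 35)),
    make_individual("m", sex = "female", alc = 70, proband = FALSE,
                    cancers = bind_rows(cancer("breast", 30),
                                        cancer("other", 44, 2)))
  ))
  g <- build_groups(apply_exclusions(coh)$subjects)
  expect_equal(g$group[g$id == "h"], 1L)
  expect_equal(g$t1_age[g$id == "h"], 60)
  expect_equal(g$group[g$id == "s"], 2L)
  expect_equal(g$t1_age[g$id == "s"], 35)
  expect_equal(g$t2_age[g$id == "s"], 50)
  expect_equal(g$group[g$id == "m"], 3L)
  expect_equal(g$t1_age[g$id == "m"], 30)
  expect_equal(g$t2_age[g$id == "m"], 44)
})

test_that("roc_auc matches the O(n^2) pair-counting oracle exactly", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5))$auc, 0.5)
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
  set.seed(41)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    scores <- sample(round(runif(n), sample(1:3, 1)))  # force ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_identical(roc_auc(scores, labels)$auc, pair_auc(scores, labels))
  }
})

test_that("the ROC is a monotone staircase and AUC is rank-invariant", {
  set.seed(42)
  scores <- runif(60); labels <- rbinom(60, 1, 0.4)
  labels[1:2] <- c(0, 1)
  r <- roc_auc(scores, labels)
  expect_true(all(diff(r$roc$fpr) >= 0))
  expect_true(all(diff(r$roc$tpr) >= 0))
  expect_equal(utils::tail(r$roc, 1)$fpr, 1)
  expect_equal(utils::tail(r$roc, 1)$tpr, 1)
  expect_equal(roc_auc(exp(5 * scores), labels)$auc, r$auc)
})

test_that("oe_ratio is observed over expected", {
  expect_equal(oe_ratio(c(1, 0, 1), c(0.5, 0.5, 1)), 1)
  expect_equal(oe_ratio(c(0, 0), c(0.3, 0.3)), 0)
  expect_error(oe_ratio(c(1, 0), c(0, 0)), "zero expected")
})

test_that("bootstrap_ci is seeded, degenerate at B=1, and resamples families", {
  d <- tibble(family_id = rep(c("a", "b", "c"), each = 4),
              label = rbinom(12, 1, 0.5), score = runif(12))
  one <- bootstrap_ci(d, function(x) mean(x$score), B = 1, seed = 3)
  expect_equal(one$lower, one$upper)
  c1 <- bootstrap_ci(d, function(x) mean(x$score), B = 50, seed = 7)
  c2 <- bootstrap_ci(d, function(x) mean(x$score), B = 50, seed = 7)
  expect_identical(c1$values, c2$values)
  expect_lte(c1$lower, c1$upper)
})

test_that("mutation validation scores tested members and audits scenario B", {
  cfg <- cohort_config(n_families = 12, seed = 51, test_prob = 0.5)
  coh <- simulate_cohort(cfg)
  rep_a <- run_mutation_validation(coh, "A", B = 50, seed = 2,
                                   params = cfg$mpc, f = cfg$f)
  expect_s3_class(rep_a, "lfs_validation_report")
  expect_true(all(rep_a$subjects$test != "untested"))
  expect_gte(rep_a$auc, 0); expect_lte(rep_a$auc, 1)
  expect_equal(unname(rep_a$counts["n"]),
               rep_a$counts[["n_pos"]] + rep_a$counts[["n_neg"]])

  rep_b <- run_mutation_validation(coh, "B", B = 50, seed = 2,
                                   params = cfg$mpc, f = cfg$f)
  expect_false(any(rep_b$subjects$proband))
  pro <- as_tibble(coh) %>% filter(proband)
  expect_setequal(rep_b$clamped$id, pro$id)
  expect_true(all(rep_b$clamped$clamp == "carrier"))

  td <- tidy(rep_a)
  expect_equal(td$metric, c("auc", "oe"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
})

test_that("self-scored cohorts discriminate better than chance", {
  cfg <- cohort_config(n_families = 25, seed = 53, test_prob = 0.5)
  coh <- simulate_cohort(cfg)
  rep_a <- run_mutation_validation(coh, "A", B = 200, seed = 4,
                                   params = cfg$mpc, f = cfg$f)
  expect_gt(rep_a$auc, 0.5)
  expect_gt(rep_a$auc_ci[1], 0.5)
})

test_that("degenerate scores give AUC one half", {
  # structureless singleton families: every posterior equals the HW prior
  n <- 20
  coh <- map(seq_len(n), function(i) {
    x <- make_individual("1", alc = 0,
                         test = ifelse(i %% 2 == 0, "carrier", "wildtype"))
    x$proband <- TRUE
    x$family_id <- paste0("s", i)
    x
  }) %>% bind_rows() %>% as_lfs_pedigree()
  r <- run_mutation_validation(coh, "A", B = 10, seed = 1, criteria = FALSE)
  expect_equal(r$auc, 0.5)
})

test_that("cancer validation respects the inferred-probability filter", {
  cfg <- cohort_config(n_families = 15, seed = 55, test_prob = 0.4)
  coh <- simulate_cohort(cfg)
  all_r <- run_cancer_validation(coh, "mpc", "all", params = cfg$mpc,
                                 cs = cfg$cs, f = cfg$f, B = 50, seed = 3)
  inf_r <- run_cancer_validation(coh, "mpc", "inferred", params = cfg$mpc,
                                 cs = cfg$cs, f = cfg$f, B = 50, seed = 3)
  s_all <- all_r$task1$subjects
  s_inf <- inf_r$task1$subjects
  expect_lte(nrow(s_inf), nrow(s_all))
  kept_untested <- s_inf[s_inf$test == "untested", ]
  expect_true(all(kept_untested$prob > 0.1 | kept_untested$prob < 0.001))
  dropped <- s_all[!s_all$id %in% s_inf$id | !s_all$family_id %in%
                     s_inf$family_id, ]
  # no probands anywhere in the cancer tasks
  expect_false(any(s_all$proband))

  km_r <- run_cancer_validation(coh, "km", "all", params = cfg$mpc,
                                cs = cfg$cs, f = cfg$f, B = 50, seed = 3)
  expect_s3_class(km_r$task1, "lfs_validation_report")
  expect_equal(km_r$task1$task, "anycancer-km")

  cs_r <- run_cancer_validation(coh, "cs", "all", params = cfg$mpc,
                                cs = cfg$cs, f = cfg$f, B = 50, seed = 3)
  expect_setequal(names(cs_r), paste0("cs-", default_outcomes))
})

test_that("fixed-horizon self-scoring is calibrated (O/E near 1)", {
  # follow-up past the horizon and scores from the generating CS model make
  # O = E in expectation; single-replicate check (coverage is exercised by
  # the acceptance suite)
  set.seed(43)
  cfg <- cohort_config(n_families = 15, seed = 57, test_prob = 1,
                       censor_bounds = list(c(60, 90)))
  ped <- simulate_phenotypes(simulate_structure(cfg), cfg)
  ped$test <- ifelse(ped$genotype >= 1, "carrier", "wildtype")
  horizon <- 40
  lab <- map_int(ped$cancers, function(cc) {
    as.integer(nrow(cc) > 0 && cc$age_dx[cc$primary_index == 1] <= horizon)
  })
  qs <- map_dbl(seq_len(nrow(ped)), function(i) {
    sum(cs_penetrance(horizon, as.integer(ped$genotype[i] >= 1),
                      as.integer(ped$sex[i] == "female"), cfg$cs,
                      outcomes = c("sarcoma", "breast", "other"))$q)
  })
  d <- tibble(family_id = ped$family_id, label = lab, score = qs)
  ci <- bootstrap_ci(d, function(x) oe_ratio(x$label, x$score),
                     B = 200, seed = 6)
  expect_lte(ci$lower, 1)
  expect_gte(ci$upper, 1)
})

test_that("summary tables reproduce the clinical fixture margins", {
  fx <- synthetic_clinical_fixture()
  s <- summarize_cohort(fx)
  expect_equal(s$individual_missing$n, c(1748, 1339, 138, 72))
  expect_equal(s$individual_missing$pct, c("53", "41", "4", "2"))
  expect_equal(s$family_missing$n, c(10, 46, 0, 68))
  expect_equal(s$family_missing$pct, c("8", "37", "0", "55"))
  tot <- s$by_status %>% filter(group == "Total")
  expect_equal(tot$Total, 3297)
  expect_equal(tot$WT, 46); expect_equal(tot$Mut, 150)
  male_mpc <- s$by_status %>% filter(sex == "male", group == "MPC")
  expect_equal(unlist(male_mpc[, c("WT", "Mut", "U")]), c(1, 10, 20),
               ignore_attr = TRUE)
})

test_that("percentages below 1 keep one decimal and empty cohorts are zeroed", {
  expect_equal(lfsrisk:::fmt_pct(2, 613), "0.3")
  expect_equal(lfsrisk:::fmt_pct(10, 124), "8")
  expect_equal(lfsrisk:::fmt_pct(0, 124), "0")
  empty <- as_lfs_pedigree(make_individual("a"))[0, ]
  s <- summarize_cohort(empty)
  expect_true(all(s$by_status$Total == 0))
  expect_true(all(s$individual_missing$n == 0))
})
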