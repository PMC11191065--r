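test_that("phenotype likelihood degenerates to ones without usable data", {
  blank <- make_individual("a", alc = NA)
  expect_equal(phenotype_likelihood(blank[1, ], mpc_params()), c(1, 1, 1))
  zero <- make_individual("a", alc = 0)
  expect_equal(phenotype_likelihood(zero[1, ], cs_params(), model = "cs"),
               c(1, 1, 1))
})

test_that("a healthy 80-year-old is evidence against carrying", {
  old <- make_individual("a", sex = "male", alc = 80)
  for (model in c("mpc", "cs")) {
    par <- if (model == "mpc") mpc_params() else cs_params()
    l <- phenotype_likelihood(old[1, ], par, model)
    expect_lt(l[2], l[1])
    expect_equal(l[2], l[3])  # dominance
  }
})

test_that("single-primary likelihood matches direct frailty quadrature", {
  set.seed(21)
  for (i in 1:3) {
    mp <- mpc_params(shape = runif(1, 1, 3), scale = runif(1, 80, 300),
                     gamma_G = runif(1, 1, 3), theta = runif(1, 0.1, 0.8))
    ind <- make_individual("a", sex = "female", alc = 40,
                           cancers = cancer("other", 25))
    l <- phenotype_likelihood(ind[1, ], mp)
    for (G in 0:1) {
      intens <- function(t) {
        (mp$shape / mp$scale) * (t / mp$scale)^(mp$shape - 1) *
          lfsrisk:::mpc_linpred(mp, G, 1, as.integer(t > 25))
      }
      Lc <- lfsrisk:::mpc_cum_intensity(0, 40, G, 1, mp, t1 = 25)
      a <- 1 / mp$theta
      direct <- integrate(function(z) {
        dgamma(z, a, a) * z * intens(25) * exp(-z * Lc)
      }, 0, Inf, abs.tol = 1e-12)$value
      expect_equal(l[G + 1], direct, tolerance = 1e-8)
    }
  }
})

test_that("CS phenotype likelihood matches density and survival quadrature", {
  set.seed(22)
  cs <- random_cs_params()
  ind <- make_individual("a", sex = "female", alc = 40,
                         cancers = cancer("breast", 25))
  l <- phenotype_likelihood(ind[1, ], cs, model = "cs")
  for (G in 0:1) {
    e <- lfsrisk:::cs_linpred(cs, G, 1)
    a <- 1 / cs$theta
    direct <- integrate(function(z) {
      tot <- rowSums(lfsrisk:::cs_cumhaz_matrix(25, e, cs))
      dgamma(z, a, a) * z *
        lfsrisk:::cs_hazard_matrix(25, e, cs)[, "breast"] * exp(-z * tot)
    }, 0, Inf, abs.tol = 1e-12)$value
    expect_equal(l[G + 1], direct, tolerance = 1e-8)
  }
})

test_that("censoring before a known onset is a data error", {
  bad <- make_individual("a", sex = "female", alc = 20,
                         cancers = cancer("breast", 25))
  expect_error(phenotype_likelihood(bad[1, ], mpc_params()), "censoring")
})

test_that("peeling normalises to 1 with all-ones tables and 0 on contradictions", {
  trio <- make_trio()
  expect_equal(peel_likelihood(trio), 1)
  expect_equal(
    peel_likelihood(trio, clamps = list(p = "wildtype", m = "wildtype",
                                        c = "carrier")),
    0)
})

test_that("peeling equals brute-force enumeration on random pedigrees", {
  set.seed(23)
  for (i in 1:20) {
    p <- random_small_pedigree(10)
    tabs <- random_tables(p)
    cl <- list()
    if (i %% 2 == 0) {
      cl[[sample(p$id, 1)]] <- sample(c("carrier", "wildtype"), 1)
    }
    expect_lt(abs(peel_likelihood(p, tabs, cl, f = 0.05) -
                    brute_likelihood(p, tabs, cl, f = 0.05)), 1e-10)
  }
})

test_that("an isolated untested founder has the Hardy-Weinberg posterior", {
  f <- 0.0006
  solo <- as_lfs_pedigree(make_individual("a", alc = NA))
  post <- carrier_posterior(solo, "a", "tests_ignored", f = f)
  expect_equal(post$prob, 2 * f * (1 - f) + f^2, tolerance = 1e-12)
})

test_that("using the target's own test clamps the posterior to 0 or 1", {
  trio <- make_trio(child_test = "carrier", father_test = "wildtype")
  expect_equal(carrier_posterior(trio, "c", "all_tests")$prob, 1)
  expect_equal(carrier_posterior(trio, "p", "all_tests")$prob, 0)
  # scenario control: ignored tests leave the posterior interior
  p_ign <- carrier_posterior(trio, "c", "tests_ignored")$prob
  expect_gt(p_ign, 0); expect_lt(p_ign, 1)
})

test_that("posterior equals brute-force enumeration on a 6-member family", {
  set.seed(24)
  p <- random_small_pedigree(6, min_n = 5)
  tabs <- random_tables(p)
  for (tg in p$id) {
    expect_lt(abs(carrier_posterior(p, tg, "tests_ignored", tables = tabs,
                                    f = 0.01)$prob -
                    brute_posterior(p, tabs, tg, f = 0.01)), 1e-10)
  }
})

test_that("clamping a parent as carrier never decreases a child's posterior", {
  ped <- make_trio(child_cancers = cancer("breast", 28))
  base <- carrier_posterior(ped, "c", "tests_ignored")$prob
  ped2 <- make_trio(child_cancers = cancer("breast", 28),
                    mother_test = "carrier")
  up <- carrier_posterior(ped2, "c", "all_tests")$prob
  expect_gte(up, base)
  demo <- read_pedigree(
    system.file("extdata", "demo_family.ped", package = "lfsrisk"), "ped")
  b1 <- carrier_posterior(demo, "6", "tests_ignored")$prob
  b2 <- carrier_posterior(demo, "6", "all_tests")$prob  # mother is a carrier
  expect_gte(b2, b1)
})

test_that("posteriors are calibrated against simulated carrier truth", {
  # Hardy-Weinberg founders at an enriched allele frequency (no seeded
  # lineage, no ascertainment) so the inference prior equals the generative
  # law; testing of a random subset supplies clamps; scored with every test
  # used under the same CS model that generated the phenotypes. In bins of
  # >= 200 untested members the observed carrier fraction must cover the
  # mean predicted probability.
  set.seed(25)
  f_true <- 0.08
  cfg <- cohort_config(n_families = 60, f = f_true, seed_carrier = FALSE,
                       seed = 77)
  coh <- simulate_phenotypes(simulate_structure(cfg), cfg)
  tested <- runif(nrow(coh)) < 0.3
  coh$test <- ifelse(tested, ifelse(coh$genotype >= 1, "carrier", "wildtype"),
                     "untested")
  res <- map(split_families(as_tibble(coh)), function(p) {
    tabs <- lfsrisk:::phenotype_tables(p, cfg$cs, "cs")
    ids <- p$id[p$test == "untested"]
    if (length(ids) == 0) return(NULL)
    tibble(
      prob = map_dbl(ids, function(tg) {
        carrier_posterior(p, tg, "all_tests", tables = tabs,
                          f = f_true)$prob
      }),
      carrier = p$genotype[match(ids, p$id)] >= 1
    )
  }) %>% bind_rows()
  expect_gte(nrow(res), 400)
  res$bin <- cut(res$prob, c(-0.01, 0.1, 0.35, 1.01))
  for (b in levels(res$bin)) {
    d <- res[res$bin == b, ]
    if (nrow(d) < 200) next
    ci <- binom.test(sum(d$carrier), nrow(d))$conf.int
    expect_gte(mean(d$prob), ci[1] - 1e-9)
    expect_lte(mean(d$prob), ci[2] + 1e-9)
  }
})
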