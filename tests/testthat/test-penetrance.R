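test_that("cumulative hazards vanish at 0 and reduce to t/rho when exponential", {
  ch <- cs_cumulative_hazard(0, 1, 1)
  expect_equal(unlist(ch[1, default_outcomes]), rep(0, 4),
               ignore_attr = TRUE)
  exp_cs <- cs_params(
    shape = setNames(rep(1, 4), default_outcomes),
    scale = setNames(c(100, 200, 50, 80), default_outcomes),
    beta_G = setNames(rep(0, 4), default_outcomes),
    beta_S = setNames(rep(0, 4), default_outcomes),
    beta_GxS = setNames(rep(0, 4), default_outcomes))
  ch <- cs_cumulative_hazard(30, 0, 1, exp_cs)
  expect_equal(ch$sarcoma, 30 / 100)
  expect_equal(ch$other, 30 / 50)
  expect_error(cs_cumulative_hazard(-1, 0, 0), "nonnegative")
})

test_that("cumulative hazard matches quadrature of the hazard", {
  set.seed(11)
  cs <- random_cs_params()
  e <- lfsrisk:::cs_linpred(cs, 1, 1)
  for (k in default_outcomes) {
    num <- integrate(function(u) lfsrisk:::cs_hazard_matrix(u, e, cs)[, k],
                     0, 37.5, abs.tol = 1e-12, rel.tol = 1e-12)$value
    expect_equal(cs_cumulative_hazard(37.5, 1, 1, cs)[[k]], num,
                 tolerance = 1e-8)
  }
})

test_that("the breast hazard is structurally zero for males", {
  cs <- cs_params()
  expect_equal(cs_cumulative_hazard(60, 1, 0, cs)$breast, 0)
  expect_equal(cs_penetrance(60, 1, 0, cs, outcomes = "breast")$q, 0)
})

test_that("CS penetrance conserves probability and vanishes at 0", {
  set.seed(12)
  expect_equal(cs_penetrance(0, 1, 1)$q, rep(0, 4))
  for (i in 1:5) {
    cs <- random_cs_params()
    G <- sample(0:1, 1); S <- sample(0:1, 1)
    q <- cs_penetrance(c(10, 40, 80), G, S, cs)
    tot <- q %>% group_by(t) %>% summarise(s = sum(q)) %>% pull(s)
    expect_lt(max(abs(tot + cs_survival(c(10, 40, 80), G, S, cs) - 1)), 1e-8)
  }
})

test_that("CS penetrance agrees with the frailty Monte-Carlo oracle", {
  # common Weibull shape across outcomes gives the per-draw closed form
  # q_k(t | z) = (h_k / h_total) (1 - exp(-z Lambda_total(t)))
  set.seed(13)
  shp <- 2.6
  cs <- cs_params(shape = setNames(rep(shp, 4), default_outcomes),
                  scale = setNames(runif(4, 100, 350), default_outcomes),
                  theta = 0.5)
  G <- 1; S <- 1; t <- 50
  e <- lfsrisk:::cs_linpred(cs, G, S)
  h <- vapply(default_outcomes,
              function(k) e[[k]] / cs$scale[[k]]^shp, numeric(1))
  z <- rgamma(2e5, 1 / cs$theta, 1 / cs$theta)
  for (k in c("sarcoma", "breast")) {
    mc <- (h[[k]] / sum(h)) * (1 - exp(-z * sum(h) * t^shp))
    se <- sd(mc) / sqrt(length(mc))
    expect_lt(abs(cs_penetrance(t, G, S, cs, outcomes = k)$q - mean(mc)),
              3 * se)
  }
})

test_that("theta -> 0 recovers the frailty-free closed forms", {
  cs0 <- cs_params(theta = 0)
  q <- cs_penetrance(50, 1, 1, cs0)
  # frailty-free: q_k = int lambda_k exp(-Lambda_total); check conservation
  s <- cs_survival(50, 1, 1, cs0)
  expect_equal(sum(q$q) + s, 1, tolerance = 1e-8)
  mp0 <- mpc_params(theta = 0)
  L <- lfsrisk:::mpc_cum_intensity(0, 50, 1, 0, mp0)
  expect_lt(abs(mpc_penetrance(50, 0, 0, 1, 0, mp0) - (1 - exp(-L))), 1e-8)
  # small-theta continuity
  mp_eps <- mpc_params(theta = 1e-8)
  expect_lt(abs(mpc_penetrance(50, 0, 0, 1, 0, mp_eps) -
                  mpc_penetrance(50, 0, 0, 1, 0, mp0)), 1e-6)
})

test_that("MPC penetrance is 0 at t_prev, monotone, and rejects n_prev >= 2", {
  mp <- mpc_params()
  expect_equal(mpc_penetrance(30, 30, 1, 1, 1, mp), 0)
  q <- mpc_penetrance(seq(30, 80, by = 5), 30, 1, 1, 0, mp)
  expect_true(all(diff(q) >= 0))
  expect_error(mpc_penetrance(50, 30, 2, 1, 1, mp), "n_prev")
  expect_error(mpc_penetrance(20, 30, 1, 1, 1, mp), "t_next")
})

test_that("MPC penetrance matches the conditioned frailty Monte-Carlo oracle", {
  # importance sampling over 2e5 frailty draws, weights prop. to the
  # likelihood of exactly one event at t1 = 30 (z exp(-z Lambda(0, 30)))
  set.seed(14)
  mp <- mpc_params(theta = 0.3)
  for (i in 1:3) {
    G <- sample(0:1, 1); S <- sample(0:1, 1)
    L0 <- lfsrisk:::mpc_cum_intensity(0, 30, G, S, mp)
    L1 <- lfsrisk:::mpc_cum_intensity(30, 50, G, S, mp, t1 = 30)
    z <- rgamma(2e5, 1 / mp$theta, 1 / mp$theta)
    w <- z * exp(-z * L0)
    est <- sum(w * (1 - exp(-z * L1))) / sum(w)
    wn <- w / sum(w)
    se <- sqrt(sum(wn^2 * ((1 - exp(-z * L1)) - est)^2))
    expect_lt(abs(mpc_penetrance(50, 30, 1, G, S, mp) - est), 3 * se)
  }
})

test_that("risk curves are nondecreasing in age", {
  rc <- cs_risk_curve(1, 1, ages = seq(0, 100, by = 10))
  for (k in default_outcomes) {
    expect_true(all(diff(rc$prob[rc$outcome == k]) >= -1e-12))
  }
  mc <- mpc_risk_curve(25, 1, 1, 1, ages = seq(25, 95, by = 10))
  expect_true(all(diff(mc$prob) >= -1e-12))
})

test_that("KM penetrance handles single-subject, all-censored and simulated data", {
  one <- tibble(sex = "female", carrier = 1, age = 40, event = 1)
  km <- fit_km_penetrance(one)
  expect_equal(km_risk(39.9, 1, "female", km), 0)
  expect_equal(km_risk(40, 1, "female", km), 1)

  cens <- tibble(sex = rep("male", 5), carrier = 0,
                 age = c(10, 20, 30, 40, 50), event = 0)
  km2 <- fit_km_penetrance(cens)
  expect_equal(km_risk(c(5, 45), 0, "male", km2), c(0, 0))
  # empty stratum propagates missing
  expect_true(is.na(km_risk(30, 0.5, "female", km2)))

  # subjects from a known exponential onset: the KM estimate evaluates like
  # survfit, and the 95% pointwise band covers the truth at t in {20, 50}
  # at the nominal rate over 20 replicates of 200 subjects
  set.seed(15)
  rate <- 1 / 40
  inside <- matrix(NA, 20, 2)
  for (r in 1:20) {
    onset <- rexp(200, rate)
    cens_t <- runif(200, 30, 90)
    d <- tibble(sex = "female", carrier = 1,
                age = pmin(onset, cens_t),
                event = as.integer(onset <= cens_t))
    km3 <- fit_km_penetrance(d)
    sf <- survival::survfit(survival::Surv(age, event) ~ 1, data = d)
    for (j in 1:2) {
      tt <- c(20, 50)[j]
      i <- max(which(sf$time <= tt))
      truth <- 1 - exp(-rate * tt)
      inside[r, j] <- truth > 1 - sf$upper[i] && truth < 1 - sf$lower[i]
      expect_equal(km_risk(tt, 1, "female", km3), 1 - sf$surv[i])
    }
  }
  # binomial(20, 0.95): 17+ successes covers all but ~0.3% of draws
  expect_gte(colSums(inside)[1], 17)
  expect_gte(colSums(inside)[2], 17)
})

test_that("km_risk interpolates linearly in the carrier probability", {
  km <- list(fits = list(
    `female.1` = list(empty = FALSE, times = 10, pen = 0.8, n_risk = 1, n = 1),
    `female.0` = list(empty = FALSE, times = 10, pen = 0.2, n_risk = 1, n = 1)
  ))
  class(km) <- "km_penetrance"
  expect_equal(km_risk(20, 0.5, "female", km), 0.5)
  expect_equal(km_risk(20, 1, "female", km), 0.8)
  set.seed(16)
  for (i in 1:20) {
    p <- runif(1)
    v <- km_risk(20, p, "female", km)
    expect_gte(v, 0.2); expect_lte(v, 0.8)
  }
})

test_that("model parameters round-trip through the key-value config format", {
  cs <- random_cs_params()
  mp <- mpc_params(shape = 1.7, gamma_D = 1.1, theta = 0.42)
  f <- withr::local_tempfile(fileext = ".cfg")
  write_model_params(f, cs, mp)
  back <- read_model_params(f)
  expect_equal(back$cs[names(back$cs)], cs[names(cs)], tolerance = 1e-12)
  expect_equal(back$mpc[names(back$mpc)], mp[names(mp)], tolerance = 1e-12)
})
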