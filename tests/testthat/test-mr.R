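# Harmonization and the two-sample MR estimator suite.

test_that("harmonization reconciles allele labels and orientation", {
  exposure <- data.frame(snp = c("rs1", "rs2", "rs3"),
                         ea = c("A", "C", "A"), oa = c("G", "G", "T"),
                         eaf = c(0.3, 0.2, 0.5),
                         beta = c(0.1, -0.1, 0.2), se = 0.01, n = 1e5,
                         stringsAsFactors = FALSE)
  outcome <- exposure
  outcome$beta <- c(0.05, 0.03, 0.08)
  # rs1: swapped labels in the outcome -> beta_y sign flips
  outcome$ea[1] <- "G"; outcome$oa[1] <- "A"; outcome$eaf[1] <- 0.7
  h <- harmonize(exposure, outcome)
  expect_equal(h$beta_y[h$snp == "rs1"], -0.05)
  expect_equal(h$eaf[h$snp == "rs1"], 0.3)
  # rs2: negative exposure effect -> record flipped to beta_x > 0
  r2 <- h[h$snp == "rs2", ]
  expect_equal(r2$beta_x, 0.1)
  expect_equal(r2$beta_y, -0.03)
  expect_equal(r2$ea, "G"); expect_equal(r2$oa, "C")
  expect_equal(r2$eaf, 0.8)
  # rs3: palindromic A/T with EAF 0.5 -> dropped as ambiguous
  expect_false("rs3" %in% h$snp)
  expect_true("rs3" %in% attr(h, "dropped")$snp)
})

test_that("harmonization is an involution and drops irreconcilable alleles", {
  sim <- simulate_mr_instruments(mr_sim_config(n_instruments = 100, seed = 14))
  h <- harmonize(sim$exposure, sim$outcome)
  expect_true(all(h$beta_x >= 0))
  ex2 <- data.frame(snp = h$snp, ea = h$ea, oa = h$oa, eaf = h$eaf,
                    beta = h$beta_x, se = h$se_x, n = h$n_x,
                    stringsAsFactors = FALSE)
  ou2 <- data.frame(snp = h$snp, ea = h$ea, oa = h$oa, eaf = h$eaf,
                    beta = h$beta_y, se = h$se_y, n = h$n_y,
                    stringsAsFactors = FALSE)
  h2 <- harmonize(ex2, ou2)
  attr(h, "dropped") <- NULL; attr(h2, "dropped") <- NULL
  expect_equal(h2, h)
  # irreconcilable allele sets are dropped with a reason
  bad_out <- sim$outcome
  bad_out$ea[1] <- "A"; bad_out$oa[1] <- "A"
  hb <- harmonize(sim$exposure, bad_out)
  d <- attr(hb, "dropped")
  expect_true(sim$exposure$snp[1] %in% d$snp[d$reason == "irreconcilable alleles"])
})

test_that("Wald ratio arithmetic and the single-instrument IVW identity", {
  w <- wald_ratio(list(beta_x = 0.5, beta_y = 0.1, se_y = 0.02))
  expect_equal(w$theta, 0.2)
  expect_equal(w$se, 0.04)
  expect_equal(wald_ratio(list(beta_x = 0.5, beta_y = 0, se_y = 0.02))$theta, 0)
  expect_error(wald_ratio(list(beta_x = 0, beta_y = 1, se_y = 1)), "zero exposure")
  one <- make_instruments(0.31, 0.07, se_y = 0.013)
  ivw <- mr_ivw(one)
  wr <- wald_ratio(as.list(one[1, ]))
  expect_equal(ivw$theta, wr$theta, tolerance = 1e-14)
  expect_equal(ivw$se, wr$se, tolerance = 1e-14)
})

test_that("IVW recovers exact and homogeneous configurations", {
  # two instruments with identical Wald ratios: theta = ratio, Q = 0
  rec <- make_instruments(c(0.2, 0.4), c(0.06, 0.12), se_y = c(0.01, 0.03))
  ivw <- mr_ivw(rec)
  expect_equal(ivw$theta, 0.3, tolerance = 1e-12)
  expect_equal(ivw$Q, 0, tolerance = 1e-20)
  expect_equal(ivw$I2, 0)
  expect_equal(ivw$se, ivw$se_fixed)  # no overdispersion inflation
  # noiseless beta_y = theta * beta_x recovered exactly
  bx <- seq(0.05, 0.5, length.out = 10)
  ivw2 <- mr_ivw(make_instruments(bx, 0.17 * bx))
  expect_equal(ivw2$theta, 0.17, tolerance = 1e-14)
})

test_that("Egger WLS recovers intercept and slope of exact data", {
  bx <- seq(0.05, 0.5, length.out = 12)
  se_y <- seq(0.01, 0.04, length.out = 12)
  rec <- make_instruments(bx, 0.03 + 0.2 * bx, se_y = se_y)
  egger <- mr_egger(rec)
  expect_equal(egger$theta, 0.2, tolerance = 1e-10)
  expect_equal(egger$intercept, 0.03, tolerance = 1e-10)
  # independent WLS oracle
  o <- lm(I(0.03 + 0.2 * bx) ~ bx, weights = 1 / se_y^2)
  expect_equal(egger$theta, unname(coef(o)[2]), tolerance = 1e-10)
  # zero-intercept exact data
  egger0 <- mr_egger(make_instruments(bx, 0.2 * bx, se_y = se_y))
  expect_equal(egger0$intercept, 0, tolerance = 1e-12)
  expect_error(mr_egger(make_instruments(c(0.1, 0.2), c(0.01, 0.02))),
               "at least 3")
})

test_that("Egger detects directional pleiotropy with adequate power", {
  hits <- sapply(1:50, function(s) {
    sim <- simulate_mr_instruments(
      mr_sim_config(n_instruments = 200, theta = 0.1, pleiotropy_mean = 0.05,
                    pleiotropy_sd = 0.02, seed = s))
    h <- harmonize(sim$exposure, sim$outcome)
    mr_egger(h)$intercept_p < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("weighted median handles equal and degenerate weights", {
  rec <- make_instruments(rep(1, 5), c(1, 2, 3, 4, 5), se_y = 1)
  expect_equal(mr_weighted_median(rec)$theta, 3, tolerance = 1e-9)
  # weight concentrated on one instrument returns its ratio
  rec2 <- make_instruments(rep(1, 5), c(1, 2, 3, 4, 5),
                           se_y = c(10, 10, 10, 1e-4, 10))
  expect_equal(mr_weighted_median(rec2)$theta, 4, tolerance = 1e-3)
})

test_that("weighted median resists 30% invalid instruments better than IVW", {
  wins <- sapply(1:50, function(s) {
    set.seed(5000 + s)
    valid <- simulate_mr_instruments(
      mr_sim_config(n_instruments = 140, theta = 0.1, seed = 5000 + s))
    bad <- simulate_mr_instruments(
      mr_sim_config(n_instruments = 60, theta = 0.1, pleiotropy_mean = 0.3,
                    pleiotropy_sd = 0.05, seed = 6000 + s))
    h <- rbind(harmonize(valid$exposure, valid$outcome),
               harmonize(bad$exposure, bad$outcome))
    abs(mr_weighted_median(h)$theta - 0.1) < abs(mr_ivw(h)$theta - 0.1)
  })
  expect_gte(mean(wins), 0.8)
})

test_that("radial filtering excludes constructed outliers and is idempotent", {
  set.seed(50)
  bx <- runif(30, 0.1, 0.5)
  rec <- make_instruments(bx, 0.1 * bx + rnorm(30, 0, 0.01), se_y = 0.01)
  clean <- radial_filter(rec)
  expect_equal(length(clean$excluded), 0)
  # one instrument with a 10x ratio and small SE is removed in round 1
  out <- make_instruments(c(bx, 0.4), c(0.1 * bx + rnorm(30, 0, 0.01), 0.4),
                          se_y = c(rep(0.01, 30), 0.005))
  filt <- radial_filter(out)
  expect_true(out$snp[31] %in% filt$excluded)
  again <- radial_filter(filt$retained)
  expect_equal(length(again$excluded), 0)
})

test_that("Steiger filtering removes reverse-causal instruments and keeps ties", {
  # strong exposure, weak outcome association: retained
  rec <- make_instruments(c(0.2, 0.01), c(0.02, 0.3), eaf = c(0.3, 0.3))
  st <- steiger_filter(rec)
  expect_equal(st$retained$snp, "rs001")
  expect_equal(st$excluded, "rs002")
  # exact tie keeps the instrument
  tie <- make_instruments(0.2, 0.2, eaf = 0.3)
  expect_equal(nrow(steiger_filter(tie)$retained), 1)
  # missing EAF passes through with a tally
  rec$eaf <- NA_real_
  st2 <- steiger_filter(rec)
  expect_equal(nrow(st2$retained), 2)
  expect_equal(st2$n_unassessed, 2)
})

test_that("multivariable MR reduces to IVW without mediators and flags collinearity", {
  set.seed(60)
  bx <- runif(40, 0.05, 0.4)
  rec <- make_instruments(bx, 0.08 * bx + rnorm(40, 0, 0.01))
  rec$beta_bmi <- 0; rec$beta_height <- 0
  mv <- mr_mvmr(rec)
  expect_equal(mv$theta, mr_ivw(rec)$theta, tolerance = 1e-12)
  expect_equal(mv$dropped_exposures, c("bmi", "height"))
  # direct effect recovered in the presence of a mediated path; the
  # mediator effects correlate with the exposure so univariable IVW is
  # biased away from the direct effect
  bh <- 0.5 * bx + rnorm(40, 0, 0.03)
  rec2 <- make_instruments(bx, 0.05 * bx + 0.3 * bh + rnorm(40, 0, 0.005))
  rec2$beta_height <- bh
  mv2 <- mr_mvmr(rec2, exposures = c("x", "height"))
  expect_lt(abs(mv2$theta - 0.05), 3 * mv2$se)
  uni <- mr_ivw(rec2)
  expect_gt(abs(uni$theta - 0.05), abs(mv2$theta - 0.05))
  # duplicated exposure column -> rank error
  rec3 <- rec2; rec3$beta_bmi <- rec3$beta_height
  expect_error(mr_mvmr(rec3), "rank deficient")
})

test_that("all estimators are invariant to instrument ordering", {
  sim <- simulate_mr_instruments(
    mr_sim_config(n_instruments = 60, theta = 0.1, pleiotropy_sd = 0.02,
                  seed = 70))
  h <- harmonize(sim$exposure, sim$outcome)
  set.seed(71)
  hs <- h[sample(nrow(h)), , drop = FALSE]
  expect_equal(mr_ivw(hs)$theta, mr_ivw(h)$theta, tolerance = 1e-12)
  expect_equal(mr_egger(hs)$theta, mr_egger(h)$theta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(hs)$theta, mr_weighted_median(h)$theta,
               tolerance = 1e-9)
})

test_that("radial per-instrument Q contributions sum to Cochran's Q", {
  sim <- simulate_mr_instruments(
    mr_sim_config(n_instruments = 50, theta = 0.1, pleiotropy_sd = 0.03,
                  seed = 80))
  h <- harmonize(sim$exposure, sim$outcome)
  ivw <- mr_ivw(h)
  w <- h$beta_x^2 / h$se_y^2
  qj <- w * (h$beta_y / h$beta_x - ivw$theta)^2
  expect_equal(sum(qj), ivw$Q, tolerance = 1e-9)
  expect_true(ivw$I2 >= 0 && ivw$I2 <= 100)
})

test_that("null IVW p-values are uniform across seeds", {
  pvals <- sapply(1:200, function(s) {
    sim <- simulate_mr_instruments(
      mr_sim_config(n_instruments = 30, theta = 0, seed = 9000 + s))
    h <- harmonize(sim$exposure, sim$outcome)
    mr_ivw(h)$p
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("the suite wrapper applies filters and per-SD scaling", {
  sim <- simulate_mr_instruments(
    mr_sim_config(n_instruments = 100, theta = 0.1,
                  reverse_causal_fraction = 0.1, seed = 90))
  h <- harmonize(sim$exposure, sim$outcome)
  suite <- mr_all(h, steiger = TRUE, sd_scale = 5.5)
  expect_true(length(suite$filters$steiger_excluded) > 0)
  expect_named(suite$fits, c("ivw", "egger", "wm", "pwm"))
  suite1 <- mr_all(h, steiger = TRUE, sd_scale = 1)
  expect_equal(suite$fits$ivw$theta, 5.5 * suite1$fits$ivw$theta)
})
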