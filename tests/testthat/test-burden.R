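# Carrier collapsing and the three-step burden association.

test_that("collapsing codes any qualifying carrier as heterozygous once", {
  variants <- data.frame(variant_id = c("v1", "v2", "v3"),
                         gene = c("A", "A", "B"), stringsAsFactors = FALSE)
  calls <- data.frame(
    variant_id = c("v1", "v2", "v1", "v3", "v2"),
    sample_id = c("s1", "s1", "s2", "s3", "s4"),
    gt = c("het", "hom_alt", "het", "het", "missing"),
    stringsAsFactors = FALSE)
  cm <- collapse_gene_carriers(variants, calls, paste0("s", 1:5), "test")
  m <- as.matrix(cm)
  expect_equal(unname(m[, "A"]), c(1L, 1L, 0L, 0L, 0L))  # s1 twice -> still 1
  expect_equal(unname(m[, "B"]), c(0L, 0L, 1L, 0L, 0L))  # gene-specific
  # s4's only qualifying call was set missing by QC -> not a carrier
  expect_equal(m["s4", "A"], 0L)
  # gene with no qualifying variants is absent, not an error
  cm2 <- collapse_gene_carriers(variants[variants$gene == "A", ], calls,
                                paste0("s", 1:5))
  expect_false("B" %in% cm2$genes)
})

test_that("the full binary model reproduces the closed-form 2x2 odds ratio", {
  # carriers: 50 cases / 50 controls; non-carriers: 1,000 cases / 9,000 controls
  y <- c(rep(1, 50), rep(0, 50), rep(1, 1000), rep(0, 9000))
  carrier <- c(rep(1, 100), rep(0, 10000))
  fit <- fit_burden(carrier, y, family = "binomial", gate = 1)
  expect_equal(fit$stage, "full")
  expect_equal(fit$or, 9.0, tolerance = 1e-4)            # 4 significant figures
  woolf <- sqrt(1 / 50 + 1 / 50 + 1 / 1000 + 1 / 9000)
  expect_equal(fit$se, woolf, tolerance = 1e-4)
  expect_equal(fit$ci, exp(log(9) + c(-1, 1) * 1.96 * woolf), tolerance = 1e-3)
  expect_equal(fit$carriers, 100L)
  expect_equal(fit$case_carriers, 50)
})

test_that("degenerate carrier vectors are handled as specified", {
  y <- rbinom(100, 1, 0.3)
  expect_equal(fit_burden(rep(0, 100), y)$stage, "skipped")
  expect_error(fit_burden(rep(1, 100), y), "no contrast")
})

test_that("perfect separation is flagged, not fatal", {
  y <- c(rep(1, 20), rep(0, 80))
  carrier <- c(rep(1, 20), rep(0, 80))
  fit <- fit_burden(carrier, y, family = "binomial", gate = 1)
  expect_s3_class(fit, "burden_fit")
  expect_false(isTRUE(fit$converged))
})

test_that("preliminary and full stages agree in rank on strong signals", {
  set.seed(21)
  n <- 8000
  cov <- make_covariates(n, seed = 21)
  cc <- cohort_config(n_samples = n, seed = 21)
  X <- as.matrix(cov[, names(default_covariate_effects())])
  eta <- drop(X %*% default_covariate_effects())
  genes <- paste0("G", 1:30)
  carr <- lapply(genes, function(g) sample.int(n, 60))
  names(carr) <- genes
  beta <- runif(30, 0.5, 1.5)
  gmat <- matrix(0, n, 30)
  for (j in 1:30) gmat[carr[[j]], j] <- 1
  p <- plogis(qlogis(0.077) + eta - mean(eta) + drop(gmat %*% beta))
  y <- rbinom(n, 1, p)
  prelim_p <- numeric(30); full_p <- numeric(30)
  for (j in 1:30) {
    f1 <- fit_burden(carr[[j]], y, X, family = "binomial", gate = 0, n = n)
    f2 <- fit_burden(carr[[j]], y, X, family = "binomial", gate = 1, n = n)
    prelim_p[j] <- f1$p; full_p[j] <- f2$p
  }
  expect_gt(cor(rank(prelim_p), rank(full_p), method = "spearman"), 0.9)
})

test_that("inflation lambda matches its chi-square definition", {
  expect_equal(inflation_lambda(rep(0.5, 10)), 1.0)
  expect_equal(inflation_lambda(rep(0.05, 7)),
               qchisq(0.95, 1) / qchisq(0.5, 1), tolerance = 1e-6)
  set.seed(30)
  p <- runif(1e5)
  l <- inflation_lambda(p)
  expect_gt(l, 0.98); expect_lt(l, 1.02)
  expect_equal(inflation_lambda(sample(p)), l)  # order invariance
  expect_error(inflation_lambda(numeric(0)), "no p-values")
  expect_error(inflation_lambda(c(0.5, 0)), "0, 1")
})

test_that("heterogeneity Z follows the normal oracle", {
  h <- heterogeneity_z(1.0, 0.5, 1.0, 0.5)
  expect_equal(h$z, 0); expect_equal(h$p, 1)
  h2 <- heterogeneity_z(1.0, 0.5, 0.0, 0.5)
  expect_equal(h2$z, sqrt(2), tolerance = 1e-4)
  expect_equal(h2$p, 2 * pnorm(-sqrt(2)), tolerance = 1e-10)
  h3 <- heterogeneity_z(2.0, 0.1, 1.0, 0.1)
  expect_equal(h3$z, 1 / sqrt(0.02), tolerance = 1e-6)
  expect_equal(h3$p, 2 * pnorm(-1 / sqrt(0.02)), tolerance = 1e-12)
  expect_error(heterogeneity_z(1, 0, 1, 1), "positive")
})

test_that("gene summaries report cMAF, carriers, and penetrance conventions", {
  expect_equal(gene_summary(integer(0), c(1, 0), c(1e-4, 2e-4))$cmaf, 3e-4)
  s <- gene_summary(1:35, c(rep(1, 27), rep(0, 73)), 1e-4)
  expect_equal(s$carriers, 35L)
  expect_equal(s$penetrance, 27 / 35, tolerance = 1e-6)
  # zero carriers: penetrance absent, not zero
  expect_true(is.na(gene_summary(integer(0), c(1, 0), 1e-4)$penetrance))
})

test_that("significance flags require both p-threshold and carrier floor", {
  set.seed(33)
  n <- 6000
  cov <- make_covariates(n, seed = 33)
  cc <- cohort_config(n_samples = n, seed = 33,
                      covariate_effects = default_covariate_effects())
  ph_cov <- cov; ph_cov$sample_id <- cov$sample_id
  # a very strong gene with only 12 carriers and a strong gene with many
  small <- sample.int(n, 12); big <- sample.int(n, 200)
  eta <- numeric(n)
  eta[small] <- 4; eta[big] <- 1.2
  y <- rbinom(n, 1, plogis(qlogis(0.077) + eta))
  ph <- data.frame(sample_id = cov$sample_id, disease = y)
  cmx <- carrier_matrix(list(SMALL = small, BIG = big), cov$sample_id, "m")
  sc <- screen_config(sig_threshold = 1e-3,
                      covariates = names(default_covariate_effects()))
  scr <- run_exome_screen(list(m = cmx), ph, cov, sc)
  r <- scr$results
  expect_lt(r$p[r$gene == "SMALL"], 1e-3)          # passes the p threshold
  expect_true(r$carriers[r$gene == "SMALL"] < 30)
  expect_false(r$significant[r$gene == "SMALL"])   # blocked by the carrier floor
  expect_true(r$significant[r$gene == "BIG"])
})

test_that("sample exclusions remove carriers from the fit", {
  set.seed(35)
  n <- 2000
  cov <- make_covariates(n, seed = 35)
  y <- rbinom(n, 1, 0.1)
  ph <- data.frame(sample_id = cov$sample_id, disease = y)
  carr <- sample.int(n, 50)
  cmx <- carrier_matrix(list(G = carr), cov$sample_id)
  sc0 <- screen_config(covariates = c("age_std", "sex"))
  sc1 <- screen_config(covariates = c("age_std", "sex"),
                       exclude_samples = cov$sample_id[carr[1:14]])
  r0 <- run_exome_screen(list(m = cmx), ph, cov, sc0)$results
  r1 <- run_exome_screen(list(m = cmx), ph, cov, sc1)$results
  expect_equal(r0$carriers, 50L)
  expect_equal(r1$carriers, 36L)
})

test_that("domain partition testing compares in/out-of-interval burden", {
  set.seed(40)
  n <- 4000
  samples <- sprintf("S%06d", 1:n)
  variants <- data.frame(variant_id = paste0("v", 1:20),
                         gene = "KIN", stringsAsFactors = FALSE)
  ann <- data.frame(variant_id = variants$variant_id,
                    protein_pos = c(rep(1100, 10), rep(200, 10)),
                    stringsAsFactors = FALSE)
  calls <- data.frame(
    variant_id = rep(variants$variant_id, each = 10),
    sample_id = samples[sample.int(n, 200)],
    gt = "het", stringsAsFactors = FALSE)
  cin <- unique(calls$sample_id[calls$variant_id %in% paste0("v", 1:10)])
  eta <- numeric(n); eta[match(cin, samples)] <- 1.5
  y <- rbinom(n, 1, plogis(-2.5 + eta))
  res <- domain_partition_test(variants, ann, c(999, 1274), calls, samples,
                               y, family = "binomial")
  expect_s3_class(res$inside, "burden_fit")
  expect_s3_class(res$outside, "burden_fit")
  expect_true(is.finite(res$z) && res$p >= 0 && res$p <= 1)
  # effect concentrated inside the interval -> inside beta larger
  expect_gt(res$inside$beta, res$outside$beta)
})
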