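#' Configuration for the synthetic exome cohort generator
#'
#' Bundles and validates the parameters of the cohort simulator. Defaults
#' emulate, at reduced scale, a European-ancestry biobank exome cohort with
#' a 7.7% prevalent binary disease, a rare-variant site-frequency spectrum
#' truncated at MAF 0.1% with a large singleton share, and per-genotype
#' read evidence (negative-binomial depth, binomial allele depths with an
#' unbalanced-het error mode, and a low-quality call mode) so the QC
#' filters have true positives to find.
#'
#' @param n_samples,n_genes Cohort and gene-panel sizes.
#' @param mean_variants_per_gene Poisson mean of variants per gene (>= 1
#'   enforced by adding 1 to a Poisson draw).
#' @param maf_max Upper truncation of the minor-allele-frequency spectrum
#'   (default 0.001); frequencies are drawn log-uniformly (density
#'   proportional to 1/x, a heavy-tailed neutral-spectrum stand-in) between
#'   `maf_min` and `maf_max`.
#' @param maf_min Lower truncation; defaults to one allele copy,
#'   `1 / (2 n_samples)`.
#' @param singleton_fraction Fraction of variants forced to allele count 1.
#' @param depth_mean,depth_size Negative-binomial read-depth model.
#' @param gq_mean,gq_sd Genotype-quality noise (truncated to [0, 99]).
#' @param lowq_rate Probability a non-reference call is drawn from the
#'   low-quality mode (shallow depth, GQ < 20).
#' @param ab_error_rate Probability a heterozygous call draws its alternate
#'   reads from an unbalanced (alt fraction 0.12) rather than balanced
#'   binomial, emulating genotyping artefacts.
#' @param homref_lowq_rate Per-sample probability of an explicit
#'   low-quality homozygous-reference call at a variant (all other hom-ref
#'   calls are implicit and clean).
#' @param causal_genes data.frame with columns `gene`, `functional` (mask
#'   class driving carrier status), `beta` (log-odds carrier effect); NULL
#'   for a null cohort.
#' @param covariate_effects Named log-odds coefficients for the covariate
#'   set (standardized age, its square, sex, ten principal-component
#'   surrogates, and a 3-level sequencing-batch factor).
#' @param baseline_prevalence Target marginal disease prevalence.
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 5000L,
                          n_genes = 100L,
                          mean_variants_per_gene = 6,
                          maf_max = 0.001,
                          maf_min = NULL,
                          singleton_fraction = 0.5,
                          depth_mean = 40, depth_size = 8,
                          gq_mean = 70, gq_sd = 18,
                          lowq_rate = 0.01,
                          ab_error_rate = 0.01,
                          homref_lowq_rate = 0.001,
                          causal_genes = NULL,
                          covariate_effects = default_covariate_effects(),
                          baseline_prevalence = 0.077,
                          seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples")
  n_genes <- check_count(n_genes, "n_genes")
  check_prob(singleton_fraction, "singleton_fraction")
  check_prob(lowq_rate, "lowq_rate")
  check_prob(ab_error_rate, "ab_error_rate")
  check_prob(homref_lowq_rate, "homref_lowq_rate")
  check_prob(baseline_prevalence, "baseline_prevalence")
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1)
    stopf("'baseline_prevalence' must be in (0, 1)", class = "exburden_config_error")
  if (is.null(maf_min)) maf_min <- min(1 / (2 * n_samples), maf_max / 10)
  if (maf_min <= 0 || maf_max <= maf_min)
    stopf("'maf_min'/'maf_max' must satisfy 0 < maf_min < maf_max",
          class = "exburden_config_error")
  if (!is.null(causal_genes) &&
      !all(c("gene", "functional", "beta") %in% names(causal_genes)))
    stopf("'causal_genes' needs columns gene, functional, beta",
          class = "exburden_config_error")
  structure(list(
    n_samples = n_samples, n_genes = n_genes,
    mean_variants_per_gene = mean_variants_per_gene,
    maf_max = maf_max, maf_min = maf_min,
    singleton_fraction = singleton_fraction,
    depth_mean = depth_mean, depth_size = depth_size,
    gq_mean = gq_mean, gq_sd = gq_sd,
    lowq_rate = lowq_rate, ab_error_rate = ab_error_rate,
    homref_lowq_rate = homref_lowq_rate,
    causal_genes = causal_genes,
    covariate_effects = covariate_effects,
    baseline_prevalence = baseline_prevalence,
    seed = check_count(seed, "seed", min = 0L)), class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_covariate_effects <- function() {
  c(age_std = 0.30, age_std_sq = 0.05, sex = 0.40,
    stats::setNames(rep(0.02, 10), paste0("pc", 1:10)),
    batch_200k = 0.05, batch_450k = -0.05)
}

consequence_pool <- c(
  stop_gained = 0.04, frameshift_variant = 0.04,
  splice_acceptor_variant = 0.02, splice_donor_variant = 0.02,
  missense_variant = 0.50, synonymous_variant = 0.30,
  intron_variant = 0.05, splice_region_variant = 0.03)

#' Simulate a cohort: variants, genotype calls, annotations, covariates
#'
#' Generates the four tables the downstream QC/annotation/burden stages
#' consume. The genotype-call table is sparse: it lists every non-reference
#' call with simulated read evidence (DP, GQ, ref/alt allele depths) plus an
#' explicit low-quality subset of homozygous-reference calls; all remaining
#' hom-ref calls are implicit and clean. Emitted per-variant AC/AN are
#' recomputed from the generated genotypes, so allele accounting is exact
#' by construction.
#'
#' @param config A [cohort_config()].
#' @return List with elements `variants`, `calls`, `annotations`,
#'   `covariates`, `samples`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  samples <- sprintf("S%06d", seq_len(n))

  nv_per_gene <- 1L + stats::rpois(config$n_genes, config$mean_variants_per_gene - 1)
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  gene_of <- rep(genes, nv_per_gene)
  nv <- length(gene_of)
  vid <- sprintf("var%05d", seq_len(nv))

  # log-uniform MAF spectrum (density ~ 1/x) truncated to [maf_min, maf_max]
  maf <- exp(stats::runif(nv, log(config$maf_min), log(config$maf_max)))
  singleton <- stats::runif(nv) < config$singleton_fraction

  pos <- integer(nv); chrom <- character(nv)
  gene_idx <- match(gene_of, genes)
  chrom <- as.character(1 + (gene_idx %% 22))
  pos <- 1e6 + gene_idx * 1e5 + stats::ave(seq_len(nv), gene_of, FUN = seq_along) * 50L
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))

  # genotype sampling under Hardy-Weinberg; singletons get exactly one het
  calls_list <- vector("list", nv)
  ac <- integer(nv)
  for (i in seq_len(nv)) {
    if (singleton[i]) {
      het <- sample.int(n, 1L); hom <- integer(0)
    } else {
      n_hom <- stats::rbinom(1L, n, maf[i]^2)
      n_het <- stats::rbinom(1L, n - n_hom, 2 * maf[i] * (1 - maf[i]))
      idx <- sample.int(n, n_hom + n_het)
      hom <- idx[seq_len(n_hom)]
      het <- idx[n_hom + seq_len(n_het)]
    }
    k <- length(het) + length(hom)
    ac[i] <- length(het) + 2L * length(hom)
    if (k == 0L) { calls_list[[i]] <- NULL; next }
    calls_list[[i]] <- data.frame(
      variant_id = vid[i],
      sample_id = samples[c(het, hom)],
      gt = rep(c("het", "hom_alt"), c(length(het), length(hom))),
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls_list)

  # read evidence for non-reference calls
  m <- nrow(calls)
  lowq <- stats::runif(m) < config$lowq_rate
  dp <- stats::rnbinom(m, mu = config$depth_mean, size = config$depth_size) + 1L
  dp[lowq] <- stats::rpois(sum(lowq), 4) + 1L
  gq <- pmax(0, pmin(99, round(stats::rnorm(m, config$gq_mean, config$gq_sd))))
  gq[lowq] <- floor(stats::runif(sum(lowq), 0, 20))
  ab_err <- calls$gt == "het" & stats::runif(m) < config$ab_error_rate
  p_alt <- ifelse(calls$gt == "hom_alt", 0.98, ifelse(ab_err, 0.12, 0.5))
  ad_alt <- stats::rbinom(m, dp, p_alt)
  calls$dp <- as.integer(dp)
  calls$gq <- as.numeric(gq)
  calls$ad_ref <- as.integer(dp - ad_alt)
  calls$ad_alt <- as.integer(ad_alt)

  # explicit low-quality hom-ref calls
  n_hr <- stats::rbinom(nv, n, config$homref_lowq_rate)
  hr_rows <- which(n_hr > 0L)
  if (length(hr_rows)) {
    hr <- do.call(rbind, lapply(hr_rows, function(i) data.frame(
      variant_id = vid[i],
      sample_id = samples[sample.int(n, n_hr[i])],
      gt = "hom_ref", stringsAsFactors = FALSE)))
    k <- nrow(hr)
    hr$dp <- stats::rpois(k, 3)
    hr$gq <- floor(stats::runif(k, 0, 20))
    hr$ad_ref <- hr$dp
    hr$ad_alt <- 0L
    calls <- rbind(calls, hr)
  }
  calls <- calls[order(calls$variant_id, calls$sample_id), , drop = FALSE]
  rownames(calls) <- NULL

  variants <- data.frame(
    variant_id = vid, chrom = chrom, pos = as.integer(pos),
    ref = ref, alt = alt, type = "SNV", gene = gene_of,
    ac = ac, an = 2L * n, maf = pmin(ac / (2 * n), 1 - ac / (2 * n)),
    singleton = singleton, stringsAsFactors = FALSE)

  annotations <- simulate_annotations(variants, config)
  covariates <- simulate_covariates(n, samples)

  list(variants = variants, calls = calls, annotations = annotations,
       covariates = covariates, samples = samples)
}

# One prioritized-transcript-style annotation row per variant; causal genes
# get their mask's functional class enriched so qualifying variants exist.
#' @keywords internal
simulate_annotations <- function(variants, config) {
  nv <- nrow(variants)
  cons <- sample(names(consequence_pool), nv, replace = TRUE,
                 prob = consequence_pool)
  if (!is.null(config$causal_genes)) {
    for (j in seq_len(nrow(config$causal_genes))) {
      g <- config$causal_genes$gene[j]
      fn <- config$causal_genes$functional[j]
      ix <- which(variants$gene == g)
      if (fn %in% c("missense_REVEL50", "missense_REVEL70", "damaging")) {
        cons[ix] <- "missense_variant"
      } else if (fn == "HC_PTV") {
        cons[ix] <- sample(ptv_terms, length(ix), replace = TRUE)
      } else if (fn == "synonymous") {
        cons[ix] <- "synonymous_variant"
      }
    }
  }
  cls <- classify_consequence(cons)
  revel <- ifelse(cls == "missense", stats::runif(nv), NA_real_)
  if (!is.null(config$causal_genes)) {
    for (j in seq_len(nrow(config$causal_genes))) {
      ix <- which(variants$gene == config$causal_genes$gene[j] & cls == "missense")
      # damaging-score enrichment so causal genes clear the mask thresholds
      revel[ix] <- stats::runif(length(ix), 0.75, 1)
    }
  }
  cadd <- ifelse(cls %in% c("missense", "PTV"),
                 round(stats::runif(nv, 0, 45), 1), NA_real_)
  if (!is.null(config$causal_genes)) {
    for (j in seq_len(nrow(config$causal_genes))) {
      ix <- which(variants$gene == config$causal_genes$gene[j] &
                    cls %in% c("missense", "PTV"))
      cadd[ix] <- round(stats::runif(length(ix), 26, 45), 1)
    }
  }
  loftee <- ifelse(cls == "PTV",
                   sample(c("HC", "LC"), nv, replace = TRUE, prob = c(0.85, 0.15)),
                   NA_character_)
  data.frame(
    variant_id = variants$variant_id,
    gene = variants$gene,
    transcript_id = paste0("ENST", formatC(match(variants$gene, unique(variants$gene)),
                                           width = 8, flag = "0")),
    is_protein_coding = TRUE, is_mane_select = TRUE, is_canonical = TRUE,
    consequence = cons, revel = revel, cadd = cadd, loftee = loftee,
    protein_pos = sample.int(1500, nv, replace = TRUE),
    stringsAsFactors = FALSE)
}

#' @keywords internal
simulate_covariates <- function(n, samples) {
  age <- stats::rnorm(n, 57, 8)
  age_std <- (age - 57) / 8
  batch <- sample(c("b50k", "b200k", "b450k"), n, replace = TRUE,
                  prob = c(0.11, 0.33, 0.56))
  cov <- data.frame(
    sample_id = samples, age = age, age_std = age_std,
    age_std_sq = age_std^2, sex = stats::rbinom(n, 1, 0.55),
    stringsAsFactors = FALSE)
  for (k in 1:10) cov[[paste0("pc", k)]] <- stats::rnorm(n)
  cov$batch <- batch
  cov$batch_200k <- as.integer(batch == "b200k")
  cov$batch_450k <- as.integer(batch == "b450k")
  cov
}

#' @keywords internal
covariate_design <- function(covariates, effects) {
  miss <- setdiff(names(effects), names(covariates))
  if (length(miss))
    stopf("covariate columns missing: %s", paste(miss, collapse = ", "),
          class = "exburden_config_error")
  as.matrix(covariates[, names(effects), drop = FALSE])
}

#' Simulate binary and quantitative phenotypes from carrier status
#'
#' Draws a binary disease status from a logistic liability model,
#' `logit P(y = 1) = alpha + X beta_cov + G beta_gene`, where `G` is the
#' 0/1 gene-carrier matrix. The intercept `alpha` is calibrated by root
#' finding so that the marginal prevalence matches
#' `config$baseline_prevalence` given the realized covariates and carriers.
#' A quantitative trait with the same linear predictor (unit residual SD)
#' is drawn alongside.
#'
#' @param carriers Matrix (samples x genes) of 0/1 carrier indicators with
#'   rownames = sample ids and colnames = gene ids; may be NULL (no gene
#'   effects).
#' @param covariates Covariate table from [simulate_cohort()].
#' @param config The [cohort_config()]; `causal_genes$beta` supplies gene
#'   log-odds effects matched to `colnames(carriers)`.
#' @return data.frame with `sample_id`, binary `disease`, quantitative
#'   `quant`.
#' @export
simulate_phenotypes <- function(carriers, covariates, config) {
  stopifnot(inherits(config, "cohort_config"))
  X <- covariate_design(covariates, config$covariate_effects)
  eta <- drop(X %*% config$covariate_effects)
  if (!is.null(carriers)) {
    if (is.null(rownames(carriers)) ||
        !identical(rownames(carriers), covariates$sample_id))
      stopf("carrier matrix and covariates have mismatched sample identifiers",
            class = "exburden_alignment_error")
    if (!is.null(config$causal_genes) && ncol(carriers) > 0) {
      b <- stats::setNames(config$causal_genes$beta, config$causal_genes$gene)
      b <- b[colnames(carriers)]
      b[is.na(b)] <- 0
      eta <- eta + drop(carriers %*% b)
    }
  }
  alpha <- stats::uniroot(
    function(a) mean(stats::plogis(a + eta)) - config$baseline_prevalence,
    interval = c(-30, 30), tol = 1e-10)$root
  p <- stats::plogis(alpha + eta)
  data.frame(
    sample_id = covariates$sample_id,
    disease = stats::rbinom(length(p), 1, p),
    quant = eta + stats::rnorm(length(p)),
    stringsAsFactors = FALSE)
}

#' Configuration for the MR instrument simulator
#'
#' @param n_instruments Number of genetic instruments (>= 3 so Egger can
#'   run).
#' @param theta Causal effect of exposure on outcome, per SD of exposure.
#' @param pleiotropy_mean,pleiotropy_sd Normal direct (pleiotropic) effect
#'   distribution; zero mean is balanced, nonzero mean directional.
#' @param reverse_causal_fraction Fraction of instruments generated
#'   outcome-first (reverse causation) for Steiger filtering to find.
#' @param se_x,se_y Standard-error scales of the exposure and outcome
#'   effect estimates.
#' @param n_x,n_y GWAS sample sizes carried into the output table.
#' @param seed RNG seed.
#' @return List of class `mr_sim_config`.
#' @export
mr_sim_config <- function(n_instruments = 200L, theta = 0.1,
                          pleiotropy_mean = 0, pleiotropy_sd = 0,
                          reverse_causal_fraction = 0,
                          se_x = 0.004, se_y = 0.01,
                          n_x = 428525L, n_y = 893130L, seed = 1L) {
  n_instruments <- check_count(n_instruments, "n_instruments", min = 3L)
  check_prob(reverse_causal_fraction, "reverse_causal_fraction")
  if (se_x <= 0 || se_y <= 0)
    stopf("standard-error scales must be positive", class = "exburden_config_error")
  structure(list(n_instruments = n_instruments, theta = theta,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 reverse_causal_fraction = reverse_causal_fraction,
                 se_x = se_x, se_y = se_y, n_x = n_x, n_y = n_y,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "mr_sim_config")
}

#' Simulate two-sample MR summary statistics
#'
#' Instrument effects follow `beta_y = theta * beta_x + pleiotropy +
#' noise(se_y)`; reverse-causal instruments are generated outcome-first
#' (large outcome effect, weak induced exposure effect) so their outcome
#' variance explained exceeds their exposure variance explained. Allele
#' labels, effect-allele frequencies, and random strand/label flips between
#' the two tables are emitted so harmonization has real work to do.
#'
#' @param config An [mr_sim_config()].
#' @return List with `exposure` and `outcome` summary-statistic tables
#'   (columns snp, ea, oa, eaf, beta, se, n) and a `truth` table.
#' @export
simulate_mr_instruments <- function(config) {
  stopifnot(inherits(config, "mr_sim_config"))
  set.seed(config$seed)
  m <- config$n_instruments
  snp <- sprintf("rs%07d", sample.int(9e6, m))
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, m, replace = TRUE)
  oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1L), character(1))
  eaf <- stats::runif(m, 0.05, 0.95)

  reverse <- stats::runif(m) < config$reverse_causal_fraction
  beta_x_true <- abs(stats::rnorm(m, 0, 0.05)) + 5 * config$se_x
  pleio <- stats::rnorm(m, config$pleiotropy_mean, config$pleiotropy_sd)
  beta_y_true <- config$theta * beta_x_true + pleio
  if (any(reverse)) {
    k <- sum(reverse)
    by <- abs(stats::rnorm(k, 0, 0.2)) + 0.1   # strong outcome effect
    beta_y_true[reverse] <- by
    beta_x_true[reverse] <- 0.05 * by          # weak induced exposure effect
  }
  beta_x <- beta_x_true + stats::rnorm(m, 0, config$se_x)
  beta_y <- beta_y_true + stats::rnorm(m, 0, config$se_y)

  exposure <- data.frame(snp = snp, ea = ea, oa = oa, eaf = eaf,
                         beta = beta_x, se = config$se_x, n = config$n_x,
                         stringsAsFactors = FALSE)
  outcome <- data.frame(snp = snp, ea = ea, oa = oa, eaf = eaf,
                        beta = beta_y, se = config$se_y, n = config$n_y,
                        stringsAsFactors = FALSE)
  flip <- stats::runif(m) < 0.5
  outcome$ea[flip] <- oa[flip]
  outcome$oa[flip] <- ea[flip]
  outcome$eaf[flip] <- 1 - eaf[flip]
  outcome$beta[flip] <- -outcome$beta[flip]

  list(exposure = exposure, outcome = outcome,
       truth = data.frame(snp = snp, beta_x_true = beta_x_true,
                          beta_y_true = beta_y_true, pleiotropy = pleio,
                          reverse_causal = reverse, stringsAsFactors = FALSE))
}

#' Simulate a colocalization locus
#'
#' Produces two summary-statistic tracks over the same SNP set. With
#' `shared = TRUE` one causal SNP drives both tracks; with `shared = FALSE`
#' each track gets its own causal SNP; with `effect1 = effect2 = 0` both
#' tracks are pure noise. SNPs are independent (no LD), so causal z scores
#' appear only at the causal index.
#'
#' @param n_snps Number of SNPs in the window (>= 2).
#' @param shared Logical: single shared causal variant vs two distinct
#'   ones.
#' @param effect1,effect2 Causal z-score magnitudes for tracks 1 and 2.
#' @param se1,se2 Per-SNP standard errors of the two tracks.
#' @param seed RNG seed.
#' @return List with `track1`, `track2` (data.frames: snp, beta, se) and
#'   the causal indices.
#' @export
simulate_coloc_locus <- function(n_snps, shared, effect1 = 8, effect2 = 8,
                                 se1 = 0.02, se2 = 0.02, seed = 1L) {
  n_snps <- check_count(n_snps, "n_snps", min = 2L)
  set.seed(check_count(seed, "seed", min = 0L))
  snp <- sprintf("chr15_%d", 9e7 + sort(sample.int(5e5, n_snps)))
  i1 <- sample.int(n_snps, 1L)
  i2 <- if (shared) i1 else sample(setdiff(seq_len(n_snps), i1), 1L)
  z1 <- stats::rnorm(n_snps); z2 <- stats::rnorm(n_snps)
  z1[i1] <- z1[i1] + effect1
  z2[i2] <- z2[i2] + effect2
  list(track1 = data.frame(snp = snp, beta = z1 * se1, se = se1,
                           stringsAsFactors = FALSE),
       track2 = data.frame(snp = snp, beta = z2 * se2, se = se2,
                           stringsAsFactors = FALSE),
       causal1 = i1, causal2 = i2)
}
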