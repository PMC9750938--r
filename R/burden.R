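#' Collapse qualifying variants to per-gene carrier indicators
#'
#' Builds the "dummy genotype": a sample is a carrier of a gene (indicator
#' 1) iff it has at least one non-missing alternate genotype at a
#' qualifying variant of that gene, regardless of how many such variants it
#' carries. Missing genotypes contribute nothing. Genes with no qualifying
#' variants are omitted.
#'
#' @param variants Qualifying-variant table (columns `variant_id`, `gene`).
#' @param calls Post-QC call table (`variant_id`, `sample_id`, `gt`).
#' @param samples Character vector of all cohort sample ids.
#' @param mask Mask name attached to the result.
#' @return Object of class `carrier_matrix`: a list with `mask`, `samples`,
#'   `genes`, and `carriers`, a named list of integer sample indices per
#'   gene. Coerce with `as.matrix()`.
#' @export
collapse_gene_carriers <- function(variants, calls, samples, mask = "mask") {
  keep <- calls$variant_id %in% variants$variant_id &
    calls$gt %in% c("het", "hom_alt")
  cc <- calls[keep, , drop = FALSE]
  gene <- variants$gene[match(cc$variant_id, variants$variant_id)]
  si <- match(cc$sample_id, samples)
  if (anyNA(si))
    stopf("call table contains samples absent from the cohort",
          class = "exburden_alignment_error")
  carriers <- lapply(split(si, gene), function(ix) sort(unique(ix)))
  structure(list(mask = mask, samples = samples,
                 genes = names(carriers), carriers = carriers),
            class = "carrier_matrix")
}

#' Construct a carrier matrix from carrier index sets
#'
#' Low-level constructor for simulation and calibration studies that build
#' carrier sets directly rather than collapsing genotype calls.
#'
#' @param carriers Named list (one entry per gene) of integer sample
#'   indices.
#' @param samples Cohort sample ids.
#' @param mask Mask label.
#' @return A `carrier_matrix`.
#' @export
carrier_matrix <- function(carriers, samples, mask = "mask") {
  if (is.null(names(carriers)))
    stopf("'carriers' must be a named list of sample-index vectors",
          class = "exburden_data_error")
  structure(list(mask = mask, samples = samples, genes = names(carriers),
                 carriers = lapply(carriers, function(ix) sort(unique(as.integer(ix))))),
            class = "carrier_matrix")
}

#' @export
as.matrix.carrier_matrix <- function(x, ...) {
  m <- matrix(0L, length(x$samples), length(x$genes),
              dimnames = list(x$samples, x$genes))
  for (g in x$genes) m[x$carriers[[g]], g] <- 1L
  m
}

#' @export
print.carrier_matrix <- function(x, ...) {
  cat(sprintf("Carrier matrix [%s]: %d genes x %d samples; %d carrier entries\n",
              x$mask, length(x$genes), length(x$samples),
              sum(lengths(x$carriers))))
  invisible(x)
}

#' Screening configuration for the exome-wide burden scan
#'
#' @param sig_threshold Exome-wide significance threshold on the p-value
#'   (default 6.9e-7).
#' @param carrier_floor Minimum carrier count for a gene-mask pair to be
#'   reportable as significant (default 30).
#' @param gate Lenient preliminary-stage threshold below which the full
#'   generalized linear model is fit (default 1e-4).
#' @param covariates Covariate column names used in the null and full
#'   models.
#' @param exclude_samples Optional sample ids removed before fitting
#'   (supports sensitivity re-runs that drop specific carriers).
#' @return List of class `screen_config`.
#' @export
screen_config <- function(sig_threshold = 6.9e-7, carrier_floor = 30L,
                          gate = 1e-4,
                          covariates = names(default_covariate_effects()),
                          exclude_samples = NULL) {
  if (sig_threshold <= 0 || sig_threshold >= 1 || gate <= 0 || gate >= 1)
    stopf("thresholds must lie in (0, 1)", class = "exburden_config_error")
  if (carrier_floor < 0)
    stopf("carrier_floor must be >= 0", class = "exburden_config_error")
  structure(list(sig_threshold = sig_threshold,
                 carrier_floor = as.integer(carrier_floor), gate = gate,
                 covariates = covariates, exclude_samples = exclude_samples),
            class = "screen_config")
}

# Vectorized preliminary stage: OLS of null-model residuals on carrier
# status, one simple regression per gene, computed from sufficient
# statistics so a 20,000-sample x 2,000-gene scan takes seconds.
#' @keywords internal
prelim_stage <- function(resid, carriers) {
  n <- length(resid)
  rbar <- mean(resid)
  syy <- sum((resid - rbar)^2)
  k <- lengths(carriers)
  s1 <- vapply(carriers, function(ix) sum(resid[ix]), numeric(1))
  sxx <- k - k^2 / n
  sxy <- s1 - k * rbar
  beta <- sxy / sxx
  sse <- pmax(syy - beta * sxy, 0)
  se <- sqrt(sse / (n - 2) / sxx)
  t <- beta / se
  p <- 2 * stats::pt(-abs(t), n - 2)
  data.frame(gene = names(carriers), carriers = as.integer(k),
             beta = beta, se = se, p = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Burden association for one gene
#'
#' The three-step generalized linear procedure: (1) a null model of the
#' phenotype (treated as continuous) on the control covariates; (2) an
#' ordinary least-squares regression of the null-model residuals on
#' carrier status, giving the preliminary p-value; (3) for genes passing
#' the lenient gate, a full generalized linear model of the phenotype on
#' carrier status plus covariates with the appropriate family, from which
#' exact statistics (and, for binary traits, OR = exp(beta) with
#' exp(beta +/- 1.96 SE) confidence bounds) are reported.
#'
#' @param carrier Integer/logical 0-1 carrier vector, or integer sample
#'   indices when `n` is given.
#' @param phenotype Numeric response (binary 0/1 for `family =
#'   "binomial"`).
#' @param covariates Optional data.frame/matrix of covariates.
#' @param family `"binomial"` or `"gaussian"`.
#' @param gate Preliminary p-value below which the full model is fit; set
#'   to 1 to force the full model.
#' @param n Cohort size when `carrier` is an index vector.
#' @return Object of class `burden_fit` with stage `"preliminary"` or
#'   `"full"`, or a skip record (`stage = "skipped"`) when there are no
#'   carriers. Perfect separation / non-convergence is flagged via
#'   `converged`, not an error.
#' @export
fit_burden <- function(carrier, phenotype, covariates = NULL,
                       family = c("binomial", "gaussian"), gate = 1e-4,
                       n = length(phenotype)) {
  family <- match.arg(family)
  if (length(carrier) != n || !all(carrier %in% c(0, 1))) {
    carrier <- as.integer(seq_len(n) %in% carrier)
  }
  k <- sum(carrier)
  if (k == 0L)
    return(structure(list(stage = "skipped", skip_reason = "zero carriers",
                          carriers = 0L), class = "burden_fit"))
  if (k == n)
    stopf("carrier vector has no contrast (all samples are carriers)",
          class = "exburden_data_error")

  X <- if (is.null(covariates)) NULL else as.matrix(covariates)
  null_fit <- if (is.null(X)) stats::lm(phenotype ~ 1)
              else stats::lm(phenotype ~ X)
  r <- stats::residuals(null_fit)
  prelim <- prelim_stage(r, list(gene = which(carrier == 1L)))

  res <- list(stage = "preliminary", family = family,
              beta = prelim$beta, se = prelim$se, p = prelim$p,
              carriers = k,
              case_carriers = if (family == "binomial")
                sum(phenotype[carrier == 1L]) else NA_integer_,
              converged = TRUE)
  if (prelim$p < gate) {
    w <- NULL
    fit <- withCallingHandlers(
      if (is.null(X)) stats::glm(phenotype ~ carrier, family = family)
      else stats::glm(phenotype ~ carrier + X, family = family),
      warning = function(cond) {
        w <<- conditionMessage(cond); invokeRestart("muffleWarning")
      })
    cf <- summary(fit)$coefficients
    res$stage <- "full"
    res$beta <- cf["carrier", 1]
    res$se <- cf["carrier", 2]
    res$p <- cf["carrier", 4]
    separated <- family == "binomial" && (abs(res$beta) > 15 || res$se > 100)
    res$converged <- fit$converged && is.null(w) && !separated
    res$diagnostic <- if (separated && is.null(w)) "possible separation" else w
    if (family == "binomial") {
      res$or <- exp(res$beta)
      res$ci <- exp(res$beta + c(-1, 1) * 1.96 * res$se)
    }
  }
  structure(res, class = "burden_fit")
}

#' @export
print.burden_fit <- function(x, ...) {
  if (x$stage == "skipped") {
    cat("Burden fit skipped:", x$skip_reason, "\n"); return(invisible(x))
  }
  cat(sprintf("Burden fit (%s stage, %s): beta = %.4g (SE %.3g), p = %.3g\n",
              x$stage, x$family, x$beta, x$se, x$p))
  if (!is.null(x$or))
    cat(sprintf("  OR = %.3g [%.3g-%.3g]; carriers = %d (%d cases)\n",
                x$or, x$ci[1], x$ci[2], x$carriers, x$case_carriers))
  if (!isTRUE(x$converged))
    cat("  warning: fit did not converge cleanly (", x$diagnostic, ")\n")
  invisible(x)
}

#' @export
coef.burden_fit <- function(object, ...) {
  if (object$stage == "skipped") return(NULL)
  c(beta = object$beta, se = object$se, p = object$p)
}

#' Exome-wide collapsing burden screen
#'
#' Runs the three-step burden procedure for every gene in every mask:
#' one shared null model, a vectorized preliminary residual scan, and full
#' generalized linear fits for gate-passing genes. A gene-mask pair is
#' flagged significant when its final p-value is below the exome-wide
#' threshold AND its carrier count meets the reporting floor. Synonymous
#' masks serve as the negative control and are screened like any other.
#'
#' @param carrier_sets Named list of `carrier_matrix` objects (one per
#'   mask).
#' @param phenotype Phenotype table with `sample_id` and the response
#'   column.
#' @param covariates Covariate table (must include
#'   `config$covariates` columns).
#' @param config A [screen_config()].
#' @param response Response column name (default `"disease"`).
#' @param family Model family for full fits.
#' @param gene_maf Optional named list per mask of per-gene cumulative MAF
#'   (attached to results as `cmaf`).
#' @return Object of class `exwas_screen`: `results` data.frame (one row
#'   per gene-mask), `lambda` per mask, and the configuration.
#' @export
run_exome_screen <- function(carrier_sets, phenotype, covariates,
                             config = screen_config(),
                             response = "disease",
                             family = "binomial", gene_maf = NULL) {
  stopifnot(inherits(config, "screen_config"))
  if (!identical(phenotype$sample_id, covariates$sample_id))
    stopf("phenotype and covariate tables have mismatched sample identifiers",
          class = "exburden_alignment_error")
  keep <- rep(TRUE, nrow(phenotype))
  if (!is.null(config$exclude_samples))
    keep <- !(phenotype$sample_id %in% config$exclude_samples)
  y <- phenotype[[response]][keep]
  X <- as.matrix(covariates[keep, config$covariates, drop = FALSE])
  n <- length(y)
  null_fit <- stats::lm(y ~ X)
  r <- stats::residuals(null_fit)

  all_res <- list(); lambda <- c()
  for (mask in names(carrier_sets)) {
    cm <- carrier_sets[[mask]]
    if (!length(cm$genes)) next
    idx_keep <- which(keep)
    carr <- lapply(cm$carriers, function(ix) match(intersect(ix, idx_keep), idx_keep))
    carr <- carr[lengths(carr) > 0L]
    if (!length(carr)) next
    prelim <- prelim_stage(r, carr)
    prelim$mask <- mask
    prelim$stage <- "preliminary"
    prelim$case_carriers <- vapply(carr, function(ix) sum(y[ix]), numeric(1))
    prelim$or <- NA_real_; prelim$ci_lo <- NA_real_; prelim$ci_hi <- NA_real_
    hit <- which(prelim$p < config$gate)
    for (i in hit) {
      cv <- as.integer(seq_len(n) %in% carr[[prelim$gene[i]]])
      if (all(cv == cv[1])) next
      f <- fit_burden(cv, y, X, family = family, gate = 1)
      prelim$stage[i] <- f$stage
      prelim$beta[i] <- f$beta; prelim$se[i] <- f$se; prelim$p[i] <- f$p
      if (!is.null(f$or)) {
        prelim$or[i] <- f$or; prelim$ci_lo[i] <- f$ci[1]; prelim$ci_hi[i] <- f$ci[2]
      }
    }
    prelim$cmaf <- if (!is.null(gene_maf) && !is.null(gene_maf[[mask]]))
      unname(gene_maf[[mask]][prelim$gene]) else NA_real_
    prelim$penetrance <- ifelse(prelim$carriers > 0,
                                prelim$case_carriers / prelim$carriers, NA_real_)
    prelim$significant <- prelim$p < config$sig_threshold &
      prelim$carriers >= config$carrier_floor
    lambda[mask] <- inflation_lambda(prelim$p)
    all_res[[mask]] <- prelim
  }
  results <- do.call(rbind, all_res)
  rownames(results) <- NULL
  structure(list(results = results, lambda = lambda, config = config,
                 n_samples = n), class = "exwas_screen")
}

#' @export
print.exwas_screen <- function(x, ...) {
  cat(sprintf("Exome-wide burden screen: %d gene-mask tests on %d samples\n",
              nrow(x$results), x$n_samples))
  cat("  inflation lambda per mask:\n")
  for (m in names(x$lambda)) cat(sprintf("    %-28s %.3f\n", m, x$lambda[m]))
  sig <- x$results[x$results$significant, , drop = FALSE]
  cat(sprintf("  significant at p < %.2g with >= %d carriers: %d\n",
              x$config$sig_threshold, x$config$carrier_floor, nrow(sig)))
  if (nrow(sig)) {
    sig <- sig[order(sig$p), c("gene", "mask", "p", "or", "carriers")]
    print(utils::head(sig, 10), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.exwas_screen <- function(object, ...) {
  r <- object$results
  data.frame(mask = names(object$lambda),
             n_genes = as.integer(table(r$mask)[names(object$lambda)]),
             lambda = unname(object$lambda),
             n_significant = vapply(names(object$lambda), function(m)
               sum(r$significant[r$mask == m]), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(p, df = 1, lower.tail = FALSE)) / 0.4549364`,
#' the ratio of the median observed one-degree chi-square statistic to its
#' null median. Values near 1 indicate a calibrated test.
#'
#' @param p Vector of p-values in (0, 1].
#' @return The inflation factor lambda.
#' @export
inflation_lambda <- function(p) {
  if (!length(p)) stopf("no p-values supplied", class = "exburden_data_error")
  if (any(p <= 0 | p > 1)) stopf("p-values must lie in (0, 1]", class = "exburden_data_error")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Heterogeneity Z test between two effect estimates
#'
#' `Z = (beta1 - beta2) / sqrt(se1^2 + se2^2)` with a two-sided normal
#' p-value; used e.g. to compare burden effects between two protein-domain
#' partitions of the same gene.
#'
#' @param beta1,se1,beta2,se2 Effect estimates and standard errors.
#' @return List with `z` and `p`.
#' @export
heterogeneity_z <- function(beta1, se1, beta2, se2) {
  if (any(se1 <= 0) || any(se2 <= 0))
    stopf("standard errors must be positive", class = "exburden_data_error")
  z <- (beta1 - beta2) / sqrt(se1^2 + se2^2)
  list(z = z, p = z2p(z))
}

#' Gene-level summary: cumulative MAF, carriers, penetrance
#'
#' @param carrier_idx Integer sample indices of the gene's carriers.
#' @param disease Binary phenotype vector over the cohort.
#' @param mafs Post-QC minor allele frequencies of the gene's qualifying
#'   variants.
#' @return List with `cmaf` (sum of qualifying MAFs), `carriers`, and
#'   `penetrance` (affected carriers / carriers; `NA` when there are no
#'   carriers, by convention, never 0).
#' @export
gene_summary <- function(carrier_idx, disease, mafs) {
  k <- length(carrier_idx)
  list(cmaf = sum(mafs),
       carriers = k,
       penetrance = if (k == 0L) NA_real_ else sum(disease[carrier_idx]) / k)
}

#' Protein-domain partition test
#'
#' Splits a gene's qualifying variants at a protein-residue interval, fits
#' the burden model separately for carriers of in-domain and out-of-domain
#' variants, and tests effect heterogeneity between the two partitions
#' with [heterogeneity_z()].
#'
#' @param variants Qualifying-variant table with `variant_id`, `gene`.
#' @param annotations Prioritized annotations with `variant_id`,
#'   `protein_pos`.
#' @param interval Length-2 residue interval defining the domain.
#' @param calls,samples As in [collapse_gene_carriers()].
#' @param phenotype,covariates,family As in [fit_burden()].
#' @return List with the two `burden_fit`s and the heterogeneity `z`, `p`.
#' @export
domain_partition_test <- function(variants, annotations, interval, calls,
                                  samples, phenotype, covariates = NULL,
                                  family = "binomial") {
  pp <- annotations$protein_pos[match(variants$variant_id, annotations$variant_id)]
  inside <- !is.na(pp) & pp >= interval[1] & pp <= interval[2]
  fits <- lapply(list(variants[inside, ], variants[!inside, ]), function(v) {
    cm <- collapse_gene_carriers(v, calls, samples)
    ix <- unlist(cm$carriers, use.names = FALSE)
    fit_burden(unique(ix), phenotype, covariates, family = family,
               gate = 1, n = length(phenotype))
  })
  if (fits[[1]]$stage == "skipped" || fits[[2]]$stage == "skipped")
    stopf("a partition has zero carriers; heterogeneity test undefined",
          class = "exburden_data_error")
  het <- heterogeneity_z(fits[[1]]$beta, fits[[1]]$se,
                         fits[[2]]$beta, fits[[2]]$se)
  list(inside = fits[[1]], outside = fits[[2]], z = het$z, p = het$p)
}
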