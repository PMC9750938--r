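#' Harmonize exposure and outcome summary statistics
#'
#' Joins two GWAS summary-statistic tables on SNP id, reconciles allele
#' labels (sign-flipping the outcome effect and complementing its EAF when
#' its effect/other alleles are swapped relative to the exposure), drops
#' palindromic (A/T, C/G) SNPs whose EAF falls in the ambiguity window,
#' drops SNPs with irreconcilable allele sets, and finally orients every
#' instrument so the exposure-increasing allele is the effect allele
#' (beta_x >= 0; beta_y and EAF transformed accordingly). Harmonizing an
#' already harmonized table is a no-op.
#'
#' @param exposure,outcome data.frames with columns `snp`, `ea`, `oa`,
#'   `eaf`, `beta`, `se`, `n`.
#' @param palindromic_window EAF interval treated as ambiguous for
#'   palindromic SNPs (default `c(0.42, 0.58)`).
#' @return data.frame of harmonized instruments (`snp`, `ea`, `oa`, `eaf`,
#'   `beta_x`, `se_x`, `n_x`, `beta_y`, `se_y`, `n_y`) with a `dropped`
#'   attribute recording excluded SNPs and reasons.
#' @export
harmonize <- function(exposure, outcome, palindromic_window = c(0.42, 0.58)) {
  shared <- intersect(exposure$snp, outcome$snp)
  ex <- exposure[match(shared, exposure$snp), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp), , drop = FALSE]
  dropped <- data.frame(snp = character(0), reason = character(0),
                        stringsAsFactors = FALSE)

  same <- ex$ea == ou$ea & ex$oa == ou$oa
  swapped <- ex$ea == ou$oa & ex$oa == ou$ea
  bad <- !(same | swapped)
  if (any(bad))
    dropped <- rbind(dropped, data.frame(snp = ex$snp[bad],
                                         reason = "irreconcilable alleles",
                                         stringsAsFactors = FALSE))
  ou$beta[swapped] <- -ou$beta[swapped]
  ou$eaf[swapped] <- 1 - ou$eaf[swapped]

  comp <- c(A = "T", T = "A", C = "G", G = "C")
  palin <- comp[ex$ea] == ex$oa
  ambiguous <- palin & ex$eaf >= palindromic_window[1] &
    ex$eaf <= palindromic_window[2]
  if (any(ambiguous & !bad))
    dropped <- rbind(dropped, data.frame(snp = ex$snp[ambiguous & !bad],
                                         reason = "palindromic, ambiguous EAF",
                                         stringsAsFactors = FALSE))
  keep <- !bad & !ambiguous
  ex <- ex[keep, , drop = FALSE]; ou <- ou[keep, , drop = FALSE]

  flip <- ex$beta < 0
  res <- data.frame(
    snp = ex$snp,
    ea = ifelse(flip, ex$oa, ex$ea),
    oa = ifelse(flip, ex$ea, ex$oa),
    eaf = ifelse(flip, 1 - ex$eaf, ex$eaf),
    beta_x = abs(ex$beta), se_x = ex$se, n_x = ex$n,
    beta_y = ifelse(flip, -ou$beta, ou$beta), se_y = ou$se, n_y = ou$n,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  res
}

#' @keywords internal
check_instruments <- function(records, min_n) {
  if (nrow(records) < min_n)
    stopf("at least %d instruments required, got %d", min_n, nrow(records),
          class = "exburden_data_error")
  if (any(records$se_y <= 0) || any(records$se_x <= 0))
    stopf("instrument standard errors must be positive", class = "exburden_data_error")
  invisible(records)
}

#' @keywords internal
new_mr_result <- function(method, theta, se, n_inst, Q = NA_real_,
                          df = NA_real_, extra = list()) {
  i2 <- if (is.na(Q)) NA_real_ else max(0, (Q - df) / Q) * 100
  structure(c(list(method = method, theta = theta, se = se,
                   p = z2p(theta / se), n_instruments = n_inst,
                   Q = Q, I2 = i2), extra),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, digits = 4, ...) {
  cat(sprintf("MR %s: theta = %.4g (SE %.3g), p = %.3g, OR = %.4g; n = %d\n",
              x$method, x$theta, x$se, x$p, exp(x$theta), x$n_instruments))
  if (!is.na(x$Q))
    cat(sprintf("  Cochran Q = %.3g, I-square = %.1f%%\n", x$Q, x$I2))
  if (!is.null(x$intercept))
    cat(sprintf("  Egger intercept = %.4g (SE %.3g), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}

#' @export
coef.mr_result <- function(object, ...)
  c(theta = object$theta, se = object$se, p = object$p)

#' Per-variant Wald ratio
#'
#' `theta = beta_y / beta_x` with first-order standard error
#' `se_y / |beta_x|`.
#'
#' @param record One harmonized instrument (list/row with `beta_x`,
#'   `beta_y`, `se_y`).
#' @return List with `theta` and `se`.
#' @export
wald_ratio <- function(record) {
  if (record$beta_x == 0)
    stopf("Wald ratio undefined for zero exposure effect", class = "exburden_data_error")
  list(theta = record$beta_y / record$beta_x,
       se = record$se_y / abs(record$beta_x))
}

#' Inverse-variance weighted MR estimate
#'
#' The primary estimator: a weighted regression of outcome on exposure
#' effects through the origin with weights `1/se_y^2`, equivalently the
#' inverse-variance weighted meta-analysis of per-variant Wald ratios.
#' The fixed-effect standard error `1/sqrt(sum(beta_x^2/se_y^2))` is
#' multiplied by `sqrt(Q/df)` when Cochran's Q exceeds its degrees of
#' freedom (multiplicative random effects). With a single instrument (not
#' an error here, unlike < 1) the estimate reduces to its Wald ratio.
#'
#' @param records Harmonized instrument table.
#' @param random_effects Apply the multiplicative overdispersion factor
#'   when Q/df > 1 (default TRUE).
#' @return An `mr_result` with Q and I-square attached.
#' @export
mr_ivw <- function(records, random_effects = TRUE) {
  check_instruments(records, 1L)
  w <- 1 / records$se_y^2
  theta <- sum(records$beta_x * records$beta_y * w) / sum(records$beta_x^2 * w)
  se_fixed <- 1 / sqrt(sum(records$beta_x^2 * w))
  m <- nrow(records)
  Q <- sum(w * (records$beta_y - theta * records$beta_x)^2)
  df <- m - 1
  se <- se_fixed
  if (random_effects && m > 1 && Q / df > 1) se <- se_fixed * sqrt(Q / df)
  new_mr_result("IVW", theta, se, m, Q = if (m > 1) Q else NA_real_, df = df,
                extra = list(se_fixed = se_fixed))
}

#' MR-Egger regression
#'
#' Weighted least squares of `beta_y` on `beta_x` with a free intercept
#' and weights `1/se_y^2`. The slope estimates the causal effect under the
#' InSIDE assumption; a nonzero intercept indicates directional
#' (unbalanced horizontal) pleiotropy, tested at p < 0.05.
#'
#' @param records Harmonized instrument table (>= 3 instruments).
#' @return An `mr_result` carrying `intercept`, `intercept_se`,
#'   `intercept_p`.
#' @export
mr_egger <- function(records) {
  check_instruments(records, 3L)
  w <- 1 / records$se_y^2
  fit <- stats::lm(beta_y ~ beta_x, data = records, weights = w)
  cf <- summary(fit)$coefficients
  m <- nrow(records)
  sigma <- summary(fit)$sigma
  # lm SEs already carry sigma; rescale so underdispersion (sigma < 1)
  # does not shrink them below the fixed-effect level
  adj <- if (sigma > .Machine$double.eps) max(1, sigma) / sigma else 1
  slope <- cf["beta_x", 1]
  slope_se <- cf["beta_x", 2] * adj
  int <- cf["(Intercept)", 1]
  int_se <- cf["(Intercept)", 2] * adj
  Q <- sum(w * stats::residuals(fit)^2)
  res <- new_mr_result("Egger", slope, slope_se, m, Q = Q, df = m - 2,
                       extra = list(intercept = int, intercept_se = int_se,
                                    intercept_p = z2p(int / int_se)))
  res
}

#' Weighted / penalised weighted median MR estimate
#'
#' The weighted median of the per-variant Wald ratios with weights
#' `1/se_j^2` (inverse variance of each ratio); consistent when at least
#' half the weight comes from valid instruments. The penalised variant
#' multiplies each weight by `min(1, 20 q_j)`, where `q_j` is the
#' chi-square(1) upper-tail probability of instrument j's standardized
#' deviation from the IVW estimate, down-weighting heterogeneity outliers.
#' The standard error comes from a parametric bootstrap with a fixed seed.
#'
#' @param records Harmonized instrument table (>= 3 instruments).
#' @param penalised Apply the heterogeneity penalty.
#' @param n_boot Bootstrap draws (default 1000).
#' @param seed Bootstrap RNG seed.
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(records, penalised = FALSE, n_boot = 1000L,
                               seed = 20L) {
  check_instruments(records, 3L)
  ratio <- records$beta_y / records$beta_x
  ratio_se <- records$se_y / abs(records$beta_x)
  w <- 1 / ratio_se^2
  if (penalised) {
    ivw <- mr_ivw(records)
    qj <- stats::pchisq(w * (ratio - ivw$theta)^2, df = 1, lower.tail = FALSE)
    w <- w * pmin(1, 20 * qj)
  }
  theta <- weighted_median(ratio, w)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    rb <- stats::rnorm(length(ratio), ratio, ratio_se)
    weighted_median(rb, w)
  }, numeric(1))
  new_mr_result(if (penalised) "PWM" else "WM", theta, stats::sd(boot),
                nrow(records))
}

# Interpolated weighted median: sort values, find where the standardized
# cumulative weight crosses 1/2.
#' @keywords internal
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) - w / 2
  cw <- cw / sum(w)
  if (cw[1] >= 0.5) return(x[1])
  if (cw[length(cw)] <= 0.5) return(x[length(x)])
  stats::approx(cw, x, xout = 0.5, ties = "ordered")$y
}

#' Radial outlier filtering
#'
#' Iteratively removes instruments whose contribution `Q_j = w_j (theta_j -
#' theta_IVW)^2` to Cochran's Q is improbably large: at each round the IVW
#' estimate is refit and instruments with chi-square(1) upper-tail p below
#' `alpha / n` are dropped, until a fixed point is reached (so filtering an
#' already filtered set removes nothing).
#'
#' @param records Harmonized instrument table (>= 3 instruments).
#' @param alpha Per-round family-wise exclusion level (default 0.05,
#'   Bonferroni-divided by the current instrument count).
#' @return List with `retained` records and `excluded` SNP ids.
#' @export
radial_filter <- function(records, alpha = 0.05) {
  check_instruments(records, 3L)
  excluded <- character(0)
  repeat {
    if (nrow(records) < 2L)
      stopf("radial filtering excluded all instruments", class = "exburden_data_error")
    ivw <- mr_ivw(records)
    w <- records$beta_x^2 / records$se_y^2
    qj <- w * (records$beta_y / records$beta_x - ivw$theta)^2
    pj <- stats::pchisq(qj, df = 1, lower.tail = FALSE)
    out <- pj < alpha / nrow(records)
    if (!any(out)) break
    excluded <- c(excluded, records$snp[out])
    records <- records[!out, , drop = FALSE]
  }
  list(retained = records, excluded = excluded)
}

#' Steiger filtering for reverse causation
#'
#' Removes instruments that explain more variance in the outcome than in
#' the exposure. Variance explained is computed from summary statistics as
#' `r^2 = 2 EAF (1 - EAF) beta^2` on standardized traits. Ties are
#' retained; instruments lacking EAF or sample size are passed through
#' with a warning tally.
#'
#' @param records Harmonized instrument table with `eaf`.
#' @return List with `retained`, `excluded` SNP ids, and `n_unassessed`.
#' @export
steiger_filter <- function(records) {
  has <- !is.na(records$eaf) & !is.na(records$n_x) & !is.na(records$n_y)
  v <- 2 * records$eaf * (1 - records$eaf)
  r2x <- v * records$beta_x^2
  r2y <- v * records$beta_y^2
  out <- has & r2y > r2x
  list(retained = records[!out, , drop = FALSE],
       excluded = records$snp[out],
       n_unassessed = sum(!has))
}

#' Multivariable MR
#'
#' Estimates the direct effect of the primary exposure on the outcome,
#' adjusting for co-exposures (e.g. BMI and height), by weighted least
#' squares of `beta_y` on the matrix of exposure effects with no intercept
#' and weights `1/se_y^2`. When the co-exposure effects are all zero the
#' primary coefficient reduces to the univariable IVW estimate.
#'
#' @param records Harmonized table with `beta_y`, `se_y`, and one
#'   `beta_<exposure>` column per exposure.
#' @param exposures Character vector of exposure column suffixes; the
#'   first is the primary exposure.
#' @return An `mr_result` for the primary exposure plus the full
#'   coefficient table in `$coefficients`.
#' @export
mr_mvmr <- function(records, exposures = c("x", "bmi", "height")) {
  cols <- paste0("beta_", exposures)
  miss <- setdiff(cols, names(records))
  if (length(miss))
    stopf("exposure columns missing: %s", paste(miss, collapse = ", "),
          class = "exburden_data_error")
  B <- as.matrix(records[, cols, drop = FALSE])
  # co-exposures with identically zero effects carry no information;
  # dropping them reduces the fit to the remaining exposures (and, with a
  # single remaining column, exactly to IVW)
  zero_col <- apply(B, 2, function(col) all(col == 0))
  if (zero_col[1])
    stopf("primary exposure effects are all zero", class = "exburden_data_error")
  dropped_exposures <- exposures[zero_col]
  B <- B[, !zero_col, drop = FALSE]
  cols <- cols[!zero_col]
  exposures <- exposures[!zero_col]
  if (nrow(B) < ncol(B) + 1L)
    stopf("need at least %d instruments for %d exposures",
          ncol(B) + 1L, ncol(B), class = "exburden_data_error")
  qrB <- qr(B)
  if (qrB$rank < ncol(B))
    stopf("exposure-effect matrix is rank deficient (collinear: %s)",
          paste(cols[qrB$pivot[(qrB$rank + 1):ncol(B)]], collapse = ", "),
          class = "exburden_data_error")
  w <- 1 / records$se_y^2
  fit <- stats::lm.wfit(B, records$beta_y, w)
  rss <- sum(w * fit$residuals^2)
  df <- nrow(B) - ncol(B)
  XtX_inv <- chol2inv(qr.R(qr(B * sqrt(w))))
  sigma2 <- max(1, rss / df)   # multiplicative overdispersion, floored
  ses <- sqrt(diag(XtX_inv) * sigma2)
  cf <- data.frame(exposure = exposures, beta = unname(fit$coefficients),
                   se = ses, p = z2p(fit$coefficients / ses),
                   stringsAsFactors = FALSE)
  new_mr_result("MVMR", cf$beta[1], cf$se[1], nrow(B), Q = rss, df = df,
                extra = list(coefficients = cf,
                             dropped_exposures = dropped_exposures))
}

#' Run the full MR sensitivity suite
#'
#' Convenience wrapper: harmonizes (if given raw tables), optionally
#' applies Steiger and radial filtering, then runs IVW (primary), Egger,
#' weighted median, and penalised weighted median.
#'
#' @param records Harmonized instrument table (from [harmonize()]).
#' @param steiger,radial Apply the respective instrument filters first.
#' @param sd_scale Optional per-SD rescaling factor for the exposure
#'   (e.g. 5.5 units per SD): thetas are reported per SD by multiplying
#'   estimates by this factor.
#' @return Object of class `mr_analysis`: list of `mr_result`s plus the
#'   filtering record.
#' @export
mr_all <- function(records, steiger = FALSE, radial = FALSE, sd_scale = 1) {
  filters <- list()
  if (steiger) {
    st <- steiger_filter(records)
    filters$steiger_excluded <- st$excluded
    records <- st$retained
  }
  if (radial) {
    rd <- radial_filter(records)
    filters$radial_excluded <- rd$excluded
    records <- rd$retained
  }
  fits <- list(ivw = mr_ivw(records), egger = mr_egger(records),
               wm = mr_weighted_median(records),
               pwm = mr_weighted_median(records, penalised = TRUE))
  if (sd_scale != 1) {
    for (nm in names(fits)) {
      fits[[nm]]$theta <- fits[[nm]]$theta * sd_scale
      fits[[nm]]$se <- fits[[nm]]$se * sd_scale
    }
  }
  structure(list(fits = fits, filters = filters,
                 n_instruments = nrow(records), sd_scale = sd_scale),
            class = "mr_analysis")
}

#' @export
print.mr_analysis <- function(x, ...) {
  cat(sprintf("Two-sample MR suite on %d instruments", x$n_instruments))
  if (x$sd_scale != 1) cat(sprintf(" (per %.3g-unit SD)", x$sd_scale))
  cat("\n")
  for (f in x$fits) print(f)
  if (length(x$filters))
    for (nm in names(x$filters))
      cat(sprintf("  %s: %d instruments\n", nm, length(x$filters[[nm]])))
  invisible(x)
}

#' @export
summary.mr_analysis <- function(object, ...) {
  do.call(rbind, lapply(object$fits, function(f)
    data.frame(method = f$method, theta = f$theta, se = f$se, p = f$p,
               or = exp(f$theta), Q = f$Q, I2 = f$I2,
               stringsAsFactors = FALSE)))
}
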