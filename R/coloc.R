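#' Wakefield log approximate Bayes factor
#'
#' For a single SNP with estimated effect `beta` and standard error `se`,
#' under a N(0, W^2) effect prior:
#' `log ABF = 0.5 log(se^2 / (se^2 + W^2)) + 0.5 z^2 W^2 / (se^2 + W^2)`
#' with `z = beta / se`. The conventional prior SDs are W = 0.15 for
#' quantitative traits and W = 0.2 for case-control log-odds.
#'
#' @param beta,se Effect estimates and positive standard errors
#'   (vectorized).
#' @param W Prior effect standard deviation (> 0).
#' @return Log approximate Bayes factors (natural log).
#' @export
log_abf <- function(beta, se, W = 0.15) {
  if (any(se <= 0) || W <= 0)
    stopf("se and W must be positive", class = "exburden_data_error")
  z <- beta / se
  r <- W^2 / (se^2 + W^2)
  0.5 * log1p(-r) + 0.5 * z^2 * r
}

#' Bayes-factor colocalization of two association tracks
#'
#' Enumerates the five hypotheses about a locus shared between two traits
#' (H0: no association; H1/H2: association with trait 1/2 only; H3: two
#' distinct causal variants; H4: one shared causal variant) under the
#' one-causal-variant-per-trait assumption, accumulating per-SNP
#' approximate Bayes factors in log space (log-sum-exp), and returns the
#' normalized posterior probabilities PP0-PP4 together with per-SNP
#' posteriors for the shared-variant hypothesis.
#'
#' @param track1,track2 data.frames with `snp`, `beta`, `se` covering a
#'   common locus window; only the SNP intersection is used.
#' @param p1,p2 Prior probabilities a SNP is causal for trait 1 / 2
#'   (defaults 1e-4).
#' @param p12 Prior probability a SNP is causal for both (default 1e-5).
#' @param W1,W2 Prior effect SDs per track (0.15 quantitative, 0.2
#'   case-control).
#' @return Object of class `coloc_result` with `pp` (named PP0..PP4
#'   summing to 1), `snp_pp4` (per-SNP posterior under H4), `priors`, and
#'   `n_snps`.
#' @export
coloc_posteriors <- function(track1, track2, p1 = 1e-4, p2 = 1e-4,
                             p12 = 1e-5, W1 = 0.15, W2 = 0.15) {
  if (p1 <= 0 || p2 <= 0 || p12 <= 0)
    stopf("priors must be positive", class = "exburden_config_error")
  shared <- intersect(track1$snp, track2$snp)
  if (length(shared) < 2L)
    stopf("need at least 2 shared SNPs (got %d)", length(shared),
          class = "exburden_data_error")
  t1 <- track1[match(shared, track1$snp), , drop = FALSE]
  t2 <- track2[match(shared, track2$snp), , drop = FALSE]
  l1 <- log_abf(t1$beta, t1$se, W1)
  l2 <- log_abf(t2$beta, t2$se, W2)

  s1 <- logsumexp(l1)          # log sum_i ABF1_i
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)    # log sum_i ABF1_i ABF2_i
  lH0 <- 0
  lH1 <- log(p1) + s1
  lH2 <- log(p2) + s2
  # sum over ordered pairs i != j factorizes as (sum_i)(sum_j) - sum_i(ii)
  lH3 <- log(p1) + log(p2) + logdiffexp(s1 + s2, s12)
  lH4 <- log(p12) + s12

  lh <- c(lH0, lH1, lH2, lH3, lH4)
  pp <- exp(lh - logsumexp(lh))
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP", 0:4)
  snp_pp4 <- exp(l1 + l2 - s12)
  structure(list(pp = pp,
                 snp_pp4 = stats::setNames(snp_pp4, shared),
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 n_snps = length(shared)), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, digits = 4, ...) {
  cat(sprintf("Colocalization over %d shared SNPs (p1 = %g, p2 = %g, p12 = %g)\n",
              x$n_snps, x$priors["p1"], x$priors["p2"], x$priors["p12"]))
  print(round(x$pp, digits))
  best <- names(which.max(x$pp))
  lab <- c(PP0 = "no association", PP1 = "trait-1 only", PP2 = "trait-2 only",
           PP3 = "two distinct causal variants", PP4 = "one shared causal variant")
  cat(sprintf("  favoured: %s (%s)\n", best, lab[best]))
  invisible(x)
}
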