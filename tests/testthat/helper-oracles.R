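# Independent oracles used across the suite. Each is a deliberately naive
# reference implementation, kept separate from the package code paths.

# Exact two-sided binomial p at p0 = 0.5 by direct pmf summation
# (minimum-likelihood convention, with the customary relative tolerance
# for pmf ties).
ab_p_oracle <- function(k, n) {
  pmf <- dbinom(0:n, n, 0.5)
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
}

# One-call-at-a-time reference of the DP/GQ genotype gate.
filter_genotype_reference <- function(gt, dp, gq, vtype, gate = "and") {
  out <- character(length(gt))
  for (i in seq_along(gt)) {
    if (gt[i] == "missing") { out[i] <- "missing"; next }
    dp_min <- if (vtype[i] == "SNV") 7 else 10
    low_dp <- dp[i] < dp_min
    low_gq <- gq[i] < 20
    fail <- if (gate == "and") low_dp && low_gq else low_dp || low_gq
    out[i] <- if (fail) "missing" else gt[i]
  }
  out
}

# Apply a biallelic variant to a reference haplotype (1-based coordinates
# within the context string).
apply_variant <- function(ctx, pos, ref, alt) {
  stopifnot(substr(ctx, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(ctx, 1, pos - 1L), alt,
         substr(ctx, pos + nchar(ref), nchar(ctx)))
}

# Brute-force normalizer: enumerate every (pos, ref, alt) replacement on
# the context that yields the same alternate haplotype, keep the minimal
# representations (non-empty alleles, no shared flanking bases beyond the
# single anchor base an indel requires), and return the leftmost.
normalize_oracle <- function(ctx, pos, ref, alt) {
  target <- apply_variant(ctx, pos, ref, alt)
  L <- nchar(ctx)
  reps <- list()
  for (start in 1:L) {
    pre <- substr(ctx, 1, start - 1L)
    if (substr(target, 1, start - 1L) != pre) next
    for (rlen in 0:(L - start + 1L)) {
      post <- substr(ctx, start + rlen, L)
      alen <- nchar(target) - (start - 1L) - nchar(post)
      if (alen < 0) next
      if (substr(target, nchar(target) - nchar(post) + 1L, nchar(target)) != post) next
      r2 <- substr(ctx, start, start + rlen - 1L)
      a2 <- substr(target, start, start + alen - 1L)
      if (r2 == a2) next
      if (nchar(r2) == 0L || nchar(a2) == 0L) next        # VCF needs anchors
      # minimal: no shared last base; no shared first base unless required
      nr <- nchar(r2); na <- nchar(a2)
      if (substr(r2, nr, nr) == substr(a2, na, na) && (nr > 1L || na > 1L)) next
      if (nr > 1L && na > 1L && substr(r2, 1, 1) == substr(a2, 1, 1)) next
      reps[[length(reps) + 1L]] <- list(pos = start, ref = r2, alt = a2)
    }
  }
  stopifnot(length(reps) > 0L)
  best <- reps[[which.min(vapply(reps, `[[`, 0, "pos"))]]
  best
}

# Build a small harmonized instrument table directly (already oriented).
make_instruments <- function(beta_x, beta_y, se_x = 0.01, se_y = 0.02,
                             eaf = NULL, n_x = 4e5, n_y = 9e5) {
  m <- length(beta_x)
  if (is.null(eaf)) eaf <- rep(0.3, m)
  data.frame(snp = sprintf("rs%03d", seq_len(m)),
             ea = "A", oa = "G", eaf = eaf,
             beta_x = beta_x, se_x = rep_len(se_x, m), n_x = n_x,
             beta_y = beta_y, se_y = rep_len(se_y, m), n_y = n_y,
             stringsAsFactors = FALSE)
}

# Tiny deterministic cohort pieces for burden tests: a covariate table
# with the default effect columns.
make_covariates <- function(n, seed = 1) {
  set.seed(seed)
  cov <- data.frame(sample_id = sprintf("S%06d", seq_len(n)),
                    age_std = rnorm(n), stringsAsFactors = FALSE)
  cov$age_std_sq <- cov$age_std^2
  cov$sex <- rbinom(n, 1, 0.55)
  for (k in 1:10) cov[[paste0("pc", k)]] <- rnorm(n)
  cov$batch_200k <- rbinom(n, 1, 0.33)
  cov$batch_450k <- as.integer(cov$batch_200k == 0) * rbinom(n, 1, 0.8)
  cov
}
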