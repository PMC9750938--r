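#' Split a multi-allelic site and left-align each allele
#'
#' Decomposes a VCF-style record with one or more ALT alleles into biallelic
#' records, trims each REF/ALT pair to its minimal representation and shifts
#' indels to their leftmost equivalent placement, as `bcftools norm` would.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position of the first REF base.
#' @param ref Reference allele string.
#' @param alts Character vector of ALT alleles.
#' @param ref_seq Reference context sequence covering the site (a plain
#'   string of A/C/G/T).
#' @param ref_offset 1-based genomic position of the first base of `ref_seq`.
#' @param ac Optional per-allele alternate allele counts (recycled into the
#'   output unchanged).
#' @param an Optional total called allele number.
#'
#' @return A data.frame with one row per ALT allele and columns
#'   `chrom`, `pos`, `ref`, `alt`, `type` ("SNV" or "InDel"), and, when
#'   supplied, `ac` and `an`.
#' @examples
#' ref <- "GGCTCTCTCTAG"
#' split_and_left_align("1", 100, "CT", c("C", "CTT"), ref, 97)
#' @export
split_and_left_align <- function(chrom, pos, ref, alts, ref_seq, ref_offset,
                                 ac = NULL, an = NULL) {
  if (!nzchar(ref) || !length(alts))
    stopf("record must have non-empty REF and at least one ALT", class = "exburden_data_error")
  idx <- pos - ref_offset + 1L
  if (idx < 1L || idx + nchar(ref) - 1L > nchar(ref_seq))
    stopf("reference context does not cover %s:%d", chrom, pos, class = "exburden_data_error")
  if (substr(ref_seq, idx, idx + nchar(ref) - 1L) != ref)
    stopf("REF allele '%s' inconsistent with reference context at %s:%d",
          ref, chrom, pos, class = "exburden_data_error")
  if (!is.null(ac) && length(ac) != length(alts))
    stopf("ac must have one entry per ALT allele", class = "exburden_data_error")

  out <- vector("list", length(alts))
  for (i in seq_along(alts)) {
    norm <- normalize_allele_pair(pos, ref, alts[[i]], ref_seq, ref_offset)
    out[[i]] <- data.frame(
      chrom = chrom, pos = norm$pos, ref = norm$ref, alt = norm$alt,
      type = if (nchar(norm$ref) == 1L && nchar(norm$alt) == 1L) "SNV" else "InDel",
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (!is.null(ac)) res$ac <- ac
  if (!is.null(an)) res$an <- an
  res
}

# Minimal representation + left shift of a single REF/ALT pair.
# Algorithm: repeatedly (a) drop a shared terminal base, extending to the
# left with reference sequence whenever an allele would become empty;
# (b) finally trim the shared leading prefix down to one base.
#' @keywords internal
normalize_allele_pair <- function(pos, ref, alt, ref_seq, ref_offset) {
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L &&
        substr(ref, nr, nr) == substr(alt, na, na) &&
        (nr > 1L || na > 1L)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        idx <- pos - ref_offset  # base immediately left of the site
        if (idx < 1L)
          stopf("reference context too short to left-align at pos %d", pos,
                class = "exburden_data_error")
        b <- substr(ref_seq, idx, idx)
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
        pos <- pos - 1L
      }
      next
    }
    break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  if (ref == alt)
    stopf("allele pair normalizes to REF==ALT at pos %d", pos, class = "exburden_data_error")
  list(pos = pos, ref = ref, alt = alt)
}

#' Genotype-level depth/quality filter
#'
#' Sets genotype calls to missing when read depth and genotype quality fall
#' below the class-specific thresholds: SNVs require DP >= 7, indels
#' DP >= 10, both require GQ >= 20. With `gate = "and"` (default) a call is
#' removed only when depth AND quality both fail; `gate = "or"` removes a
#' call when either fails.
#'
#' @param gt Character vector of genotype classes
#'   (`"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`).
#' @param dp Integer read depths (>= 0).
#' @param gq Numeric genotype qualities (>= 0).
#' @param vtype `"SNV"` or `"InDel"`, scalar or per-call vector.
#' @param gate `"and"` (literal rule) or `"or"` (conservative rule).
#' @param dp_min_snv,dp_min_indel,gq_min Thresholds; defaults 7, 10, 20.
#'
#' @return The genotype vector with failing calls set to `"missing"`.
#' @examples
#' filter_genotype(c("het", "het"), dp = c(6, 100), gq = c(15, 99), vtype = "SNV")
#' @export
filter_genotype <- function(gt, dp, gq, vtype,
                            gate = c("and", "or"),
                            dp_min_snv = 7, dp_min_indel = 10, gq_min = 20) {
  gate <- match.arg(gate)
  n <- length(gt)
  vtype <- rep_len(vtype, n)
  if (!all(vtype %in% c("SNV", "InDel")))
    stopf("vtype must be 'SNV' or 'InDel'", class = "exburden_data_error")
  not_missing <- gt != "missing"
  if (any(not_missing & (is.na(dp) | is.na(gq) | dp < 0 | gq < 0)))
    stopf("negative or missing DP/GQ on a called genotype", class = "exburden_data_error")
  dp_min <- ifelse(vtype == "SNV", dp_min_snv, dp_min_indel)
  low_dp <- dp < dp_min
  low_gq <- gq < gq_min
  fail <- if (gate == "and") low_dp & low_gq else low_dp | low_gq
  gt[not_missing & fail] <- "missing"
  gt
}

#' Exact two-sided binomial allele-balance p-value
#'
#' Tests a heterozygous call's alternate-read fraction against the expected
#' 50% contribution with an exact binomial test. Two-sided p-values follow
#' the minimum-likelihood convention (sum of all outcome probabilities no
#' larger than the observed one), which at p0 = 0.5 reduces to
#' `min(1, 2 * pbinom(min(k, n - k), n, 0.5))`.
#'
#' @param alt_reads Alternate-supporting read counts (vectorized).
#' @param total_reads Total reads at the call (>= 1).
#'
#' @return Numeric vector of exact two-sided p-values.
#' @examples
#' allele_balance_p(c(10, 0, 5), c(20, 20, 20))
#' @export
allele_balance_p <- function(alt_reads, total_reads) {
  if (length(total_reads) == 1L) total_reads <- rep_len(total_reads, length(alt_reads))
  if (any(total_reads < 1))
    stopf("allele-balance test undefined for zero total reads", class = "exburden_data_error")
  if (any(alt_reads < 0 | alt_reads > total_reads))
    stopf("alt_reads must lie in [0, total_reads]", class = "exburden_data_error")
  k <- pmin(alt_reads, total_reads - alt_reads)
  pmin(1, 2 * stats::pbinom(k, total_reads, 0.5))
}

#' Apply the allele-balance filter to heterozygous SNV calls
#'
#' @param gt,vtype As in [filter_genotype()].
#' @param ad_alt Alternate read counts.
#' @param dp Total read depths used as the binomial denominator.
#' @param p_min Removal threshold; calls with p <= `p_min` are set missing
#'   (default `1e-3`).
#' @return Genotype vector with unbalanced het SNVs set to `"missing"`.
#' @export
filter_allele_balance <- function(gt, vtype, ad_alt, dp, p_min = 1e-3) {
  vtype <- rep_len(vtype, length(gt))
  idx <- which(gt == "het" & vtype == "SNV" & dp >= 1)
  if (length(idx)) {
    p <- allele_balance_p(ad_alt[idx], dp[idx])
    gt[idx[p <= p_min]] <- "missing"
  }
  gt
}

#' Per-variant missingness filter
#'
#' Recomputes the fraction of samples with a missing genotype after
#' genotype-level filtering and drops the variant when missingness exceeds
#' 50% (strictly).
#'
#' @param n_missing Number of samples with a missing genotype at the variant.
#' @param n_samples Total samples in the cohort (> 0).
#' @param max_missingness Drop threshold, default 0.5.
#' @return A list with `missingness` and logical `keep`.
#' @examples
#' apply_variant_missingness(6, 10)   # dropped
#' apply_variant_missingness(5, 10)   # retained (boundary is not strict)
#' @export
apply_variant_missingness <- function(n_missing, n_samples, max_missingness = 0.5) {
  if (any(n_samples <= 0))
    stopf("missingness undefined for zero samples", class = "exburden_data_error")
  miss <- n_missing / n_samples
  list(missingness = miss, keep = miss <= max_missingness)
}

#' Run full genotype-level and variant-level QC on a cohort call table
#'
#' Applies, in order: the DP/GQ gate, the heterozygous-SNV allele-balance
#' test, and the per-variant missingness filter; then recomputes AC/AN/MAF
#' from the surviving genotypes. The call table is sparse: homozygous
#' reference calls are implicit and clean unless listed explicitly.
#'
#' @param variants Variant table with columns `variant_id`, `type`, and
#'   optionally pre-QC `ac`/`an`.
#' @param calls Long call table with columns `variant_id`, `sample_id`,
#'   `gt`, `dp`, `gq`, `ad_ref`, `ad_alt`.
#' @param n_samples Cohort size (needed because hom-ref calls are implicit).
#' @param gate,p_min,max_missingness QC parameters, see the per-step
#'   functions.
#' @return A list with `variants` (kept variants with recomputed `ac`, `an`,
#'   `maf`, `missingness`), `calls` (post-filter calls for kept variants),
#'   and `report` (per-variant counts set missing by each rule and the keep
#'   flag).
#' @export
qc_genotypes <- function(variants, calls, n_samples, gate = "and",
                         p_min = 1e-3, max_missingness = 0.5) {
  n_samples <- check_count(n_samples, "n_samples")
  vt <- variants$type[match(calls$variant_id, variants$variant_id)]
  if (anyNA(vt))
    stopf("calls reference variants absent from the variant table", class = "exburden_data_error")

  gt0 <- calls$gt
  gt1 <- filter_genotype(gt0, calls$dp, calls$gq, vt, gate = gate)
  n_dpgq <- tapply(gt1 == "missing" & gt0 != "missing", calls$variant_id, sum)
  gt2 <- filter_allele_balance(gt1, vt, calls$ad_alt, calls$dp, p_min = p_min)
  n_ab <- tapply(gt2 != gt1, calls$variant_id, sum)

  calls$gt <- gt2
  miss_per_var <- tapply(calls$gt == "missing", calls$variant_id, sum)
  ids <- variants$variant_id
  nm <- as.integer(miss_per_var[ids]); nm[is.na(nm)] <- 0L
  mres <- apply_variant_missingness(nm, n_samples, max_missingness)

  # AC/AN from surviving genotypes; implicit hom-ref calls contribute 2 ref
  # alleles each.
  alt_dose <- c(hom_ref = 0L, het = 1L, hom_alt = 2L, missing = 0L)
  ac_tab <- tapply(alt_dose[calls$gt], calls$variant_id, sum)
  ac <- as.integer(ac_tab[ids]); ac[is.na(ac)] <- 0L
  an <- 2L * (n_samples - nm)
  maf <- ifelse(an > 0, pmin(ac / an, 1 - ac / an), NA_real_)

  report <- data.frame(
    variant_id = ids,
    n_dpgq_missing = as.integer(ifelse(is.na(n_dpgq[ids]), 0L, n_dpgq[ids])),
    n_allele_balance_missing = as.integer(ifelse(is.na(n_ab[ids]), 0L, n_ab[ids])),
    n_missing = nm,
    missingness = mres$missingness,
    keep = mres$keep,
    stringsAsFactors = FALSE)

  kept <- variants[mres$keep, , drop = FALSE]
  kept$ac <- ac[mres$keep]
  kept$an <- an[mres$keep]
  kept$maf <- maf[mres$keep]
  kept$missingness <- mres$missingness[mres$keep]
  keep_calls <- calls[calls$variant_id %in% kept$variant_id & calls$gt != "missing", , drop = FALSE]
  list(variants = kept, calls = keep_calls, report = report)
}
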