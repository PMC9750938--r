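#' Consequence severity ranking
#'
#' Fixed severity ordering of the consequence terms handled by the pipeline
#' (most severe first), following the standard VEP ordering. Terms outside
#' this table are rejected by the prioritization functions so that silent
#' misclassification cannot occur. A plain-text copy ships at
#' `system.file("extdata", "severity_ranking.tsv", package = "exburden")`.
#'
#' @format Character vector, most severe term first.
#' @export
vep_severity_ranking <- c(
  "transcript_ablation",
  "splice_acceptor_variant",
  "splice_donor_variant",
  "stop_gained",
  "frameshift_variant",
  "stop_lost",
  "start_lost",
  "inframe_insertion",
  "inframe_deletion",
  "missense_variant",
  "protein_altering_variant",
  "splice_region_variant",
  "incomplete_terminal_codon_variant",
  "start_retained_variant",
  "stop_retained_variant",
  "synonymous_variant",
  "coding_sequence_variant",
  "5_prime_UTR_variant",
  "3_prime_UTR_variant",
  "non_coding_transcript_exon_variant",
  "intron_variant",
  "upstream_gene_variant",
  "downstream_gene_variant",
  "intergenic_variant")

ptv_terms <- c("stop_gained", "frameshift_variant",
               "splice_acceptor_variant", "splice_donor_variant")

#' @keywords internal
severity_rank <- function(terms) {
  r <- match(terms, vep_severity_ranking)
  if (anyNA(r)) {
    bad <- unique(terms[is.na(r)])
    stopf("unknown consequence term(s): %s", paste(bad, collapse = ", "),
          class = "exburden_data_error")
  }
  r
}

#' Prioritize one transcript annotation per variant
#'
#' Reduces the multi-transcript annotation records of a single variant to
#' one record by lexicographic priority: protein-coding, then MANE-select,
#' then canonical. Flag ties are broken deterministically by the lowest
#' transcript id, so the result is independent of input order.
#'
#' @param records data.frame with logical columns `is_protein_coding`,
#'   `is_mane_select`, `is_canonical` and a character `transcript_id`.
#' @return The selected row of `records`.
#' @export
prioritize_transcript <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stopf("no annotation records supplied", class = "exburden_data_error")
  o <- order(!records$is_protein_coding, !records$is_mane_select,
             !records$is_canonical, records$transcript_id)
  records[o[1L], , drop = FALSE]
}

#' Most severe consequence among a set of terms
#'
#' @param terms Character vector of consequence terms drawn from
#'   [vep_severity_ranking].
#' @return The single most severe term.
#' @export
prioritize_consequence <- function(terms) {
  if (!length(terms)) stopf("no consequence terms supplied", class = "exburden_data_error")
  terms[which.min(severity_rank(terms))]
}

#' Collapse a consequence term to its functional class
#'
#' Stop-gained, frameshift, and splice acceptor/donor variants are grouped
#' into a single protein-truncating (PTV) class; missense and synonymous
#' keep their own classes; everything else is `"other"`.
#'
#' @param term Consequence term(s); vectorized.
#' @return `"PTV"`, `"missense"`, `"synonymous"`, or `"other"`.
#' @export
classify_consequence <- function(term) {
  severity_rank(term)  # validates
  out <- rep("other", length(term))
  out[term %in% ptv_terms] <- "PTV"
  out[term == "missense_variant"] <- "missense"
  out[term == "synonymous_variant"] <- "synonymous"
  out
}

#' Default collapsing mask set
#'
#' The cross of five functional classes (high-confidence PTV, missense with
#' REVEL >= 0.5, missense with REVEL >= 0.7, synonymous negative control,
#' and "damaging" = missense CADD >= 25 or HC PTV) with two frequency
#' strata (MAF < 0.1% and singletons).
#'
#' @return data.frame with columns `name`, `functional`, `frequency`.
#' @export
default_masks <- function() {
  fn <- c("HC_PTV", "missense_REVEL50", "missense_REVEL70", "synonymous", "damaging")
  fr <- c("MAF_lt_0.1pct", "singleton")
  g <- expand.grid(functional = fn, frequency = fr,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$name <- paste(g$functional, g$frequency, sep = ".")
  g[, c("name", "functional", "frequency")]
}

#' Test mask membership of annotated variants
#'
#' A variant belongs to a mask when it satisfies both the functional rule
#' and the frequency stratum. Functional rules: `HC_PTV` needs class PTV
#' and a LOFTEE high-confidence flag; the REVEL masks need class missense
#' and REVEL at or above 0.5 / 0.7; `damaging` is missense with CADD >= 25
#' or an HC PTV; `synonymous` needs class synonymous. Frequency strata:
#' `MAF_lt_0.1pct` requires post-QC MAF < 0.001; `singleton` requires
#' AC = 1. Variants lacking a score their class requires (e.g. missense
#' without REVEL) are non-members and counted in the returned diagnostics.
#'
#' @param ann data.frame with columns `class` (from
#'   [classify_consequence()]), `revel`, `cadd`, `loftee`, and post-QC
#'   `ac`, `an`.
#' @param mask One row of [default_masks()] (or a list with `functional`
#'   and `frequency`).
#' @return Logical membership vector with attribute `n_missing_score`.
#' @export
mask_membership <- function(ann, mask) {
  fn <- mask$functional
  revel <- if ("revel" %in% names(ann)) ann$revel else rep(NA_real_, nrow(ann))
  cadd <- if ("cadd" %in% names(ann)) ann$cadd else rep(NA_real_, nrow(ann))
  loftee <- if ("loftee" %in% names(ann)) ann$loftee else rep(NA_character_, nrow(ann))
  n_missing_score <- 0L
  hc_ptv <- ann$class == "PTV" & !is.na(loftee) & loftee == "HC"
  if (fn == "HC_PTV") {
    f <- hc_ptv
  } else if (fn %in% c("missense_REVEL50", "missense_REVEL70")) {
    thr <- if (fn == "missense_REVEL50") 0.5 else 0.7
    miss <- ann$class == "missense"
    n_missing_score <- sum(miss & is.na(revel))
    f <- miss & !is.na(revel) & revel >= thr
  } else if (fn == "synonymous") {
    f <- ann$class == "synonymous"
  } else if (fn == "damaging") {
    miss <- ann$class == "missense"
    n_missing_score <- sum(miss & is.na(cadd))
    f <- (miss & !is.na(cadd) & cadd >= 25) | hc_ptv
  } else {
    stopf("unknown functional class '%s'", fn, class = "exburden_config_error")
  }
  maf <- pmin(ann$ac / ann$an, 1 - ann$ac / ann$an)
  fr <- switch(mask$frequency,
               "MAF_lt_0.1pct" = maf < 0.001,
               "singleton" = ann$ac == 1L,
               stopf("unknown frequency class '%s'", mask$frequency,
                     class = "exburden_config_error"))
  out <- f & fr
  attr(out, "n_missing_score") <- n_missing_score
  out
}

#' Prioritize annotations for a whole variant table
#'
#' Applies transcript prioritization then consequence prioritization per
#' variant and attaches the functional class.
#'
#' @param annotations Long annotation table with one row per
#'   variant-transcript pair: columns `variant_id`, `gene`,
#'   `transcript_id`, `is_protein_coding`, `is_mane_select`,
#'   `is_canonical`, `consequence`, `revel`, `cadd`, `loftee`,
#'   `protein_pos`.
#' @return One row per variant with a `class` column added.
#' @export
prioritize_annotations <- function(annotations) {
  sp <- split(seq_len(nrow(annotations)), annotations$variant_id)
  rows <- vapply(sp, function(ix) {
    rec <- annotations[ix, , drop = FALSE]
    o <- order(!rec$is_protein_coding, !rec$is_mane_select, !rec$is_canonical,
               rec$transcript_id)
    ix[o[1L]]
  }, integer(1))
  out <- annotations[rows, , drop = FALSE]
  # a transcript row may carry several '&'-joined terms; keep the most severe
  out$consequence <- vapply(strsplit(out$consequence, "&", fixed = TRUE),
                            prioritize_consequence, character(1))
  out$class <- classify_consequence(out$consequence)
  rownames(out) <- NULL
  out
}
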