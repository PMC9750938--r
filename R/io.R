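# File formats: a minimal VCF v4.2 subset (CHROM..INFO AC,AN; FORMAT
# GT:DP:GQ:AD) and schema-checked TSV tables. All text is UTF-8,
# tab-delimited, '.' for missing.

#' Write a cohort to a minimal VCF
#'
#' Emits a VCFv4.2 subset with INFO `AC`/`AN` and FORMAT `GT:DP:GQ:AD`.
#' Explicit calls carry their read evidence; implicit clean
#' homozygous-reference calls are written as `0/0:.:.:.` so the sparse
#' call table round-trips losslessly through [read_cohort_vcf()].
#'
#' @param variants Variant table (`variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `ac`, `an`).
#' @param calls Sparse call table (`variant_id`, `sample_id`, `gt`, `dp`,
#'   `gq`, `ad_ref`, `ad_alt`).
#' @param samples All cohort sample ids (column order).
#' @param path Output path (plain text).
#' @export
write_cohort_vcf <- function(variants, calls, samples, path) {
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total called alleles\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  si <- match(calls$sample_id, samples)
  vi <- match(calls$variant_id, variants$variant_id)
  if (anyNA(si) || anyNA(vi))
    stopf("calls reference unknown samples or variants", class = "exburden_data_error")
  cell <- sprintf("%s:%d:%d:%d,%d", gt_code[calls$gt], calls$dp,
                  as.integer(calls$gq), calls$ad_ref, calls$ad_alt)
  lines <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    cells <- rep("0/0:.:.:.", length(samples))
    sel <- which(vi == i)
    cells[si[sel]] <- cell[sel]
    lines[i] <- paste(c(variants$chrom[i], variants$pos[i],
                        variants$variant_id[i], variants$ref[i],
                        variants$alt[i], ".", "PASS",
                        sprintf("AC=%d;AN=%d", variants$ac[i], variants$an[i]),
                        "GT:DP:GQ:AD", cells), collapse = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a minimal cohort VCF
#'
#' Parses a VCF written by [write_cohort_vcf()] (or any VCF restricted to
#' the same subset) via the `vcfR` parser into the package's variant and
#' sparse call tables. `0/0` genotypes without read evidence are treated
#' as implicit clean hom-ref calls and omitted from the call table.
#'
#' @param path VCF path.
#' @return List with `variants`, `calls`, `samples`.
#' @export
read_cohort_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info <- fix$INFO
  getinfo <- function(key) {
    m <- regmatches(info, regexpr(paste0(key, "=[0-9]+"), info))
    out <- rep(NA_integer_, length(info))
    hit <- grepl(paste0(key, "="), info)
    out[hit] <- as.integer(sub(paste0(key, "="), "", m))
    out
  }
  variants <- data.frame(
    variant_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    type = ifelse(nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L, "SNV", "InDel"),
    ac = getinfo("AC"), an = getinfo("AN"), stringsAsFactors = FALSE)

  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP")
  gq <- vcfR::extract.gt(v, element = "GQ")
  ad <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(gt)
  rownames(gt) <- variants$variant_id

  explicit <- which(!(gt %in% c("0/0", "0|0")) | !is.na(dp), arr.ind = TRUE)
  if (nrow(explicit)) {
    g <- gt[explicit]
    cls <- rep("missing", length(g))
    cls[g %in% c("0/0", "0|0")] <- "hom_ref"
    cls[g %in% c("0/1", "1/0", "0|1", "1|0")] <- "het"
    cls[g %in% c("1/1", "1|1")] <- "hom_alt"
    adr <- ad[explicit]
    adsplit <- strsplit(ifelse(is.na(adr), ".,.", adr), ",", fixed = TRUE)
    calls <- data.frame(
      variant_id = variants$variant_id[explicit[, 1]],
      sample_id = samples[explicit[, 2]],
      gt = cls,
      dp = suppressWarnings(as.integer(dp[explicit])),
      gq = suppressWarnings(as.numeric(gq[explicit])),
      ad_ref = suppressWarnings(as.integer(vapply(adsplit, `[`, "", 1L))),
      ad_alt = suppressWarnings(as.integer(vapply(adsplit, `[`, "", 2L))),
      stringsAsFactors = FALSE)
    calls <- calls[order(calls$variant_id, calls$sample_id), , drop = FALSE]
    rownames(calls) <- NULL
  } else {
    calls <- data.frame(variant_id = character(0), sample_id = character(0),
                        gt = character(0), dp = integer(0), gq = numeric(0),
                        ad_ref = integer(0), ad_alt = integer(0),
                        stringsAsFactors = FALSE)
  }
  list(variants = variants, calls = calls, samples = samples)
}

# Declared column types per supported table schema.
table_schemas <- list(
  annotation = c(variant_id = "character", gene = "character",
                 transcript_id = "character", is_protein_coding = "logical",
                 is_mane_select = "logical", is_canonical = "logical",
                 consequence = "character", revel = "numeric",
                 cadd = "numeric", loftee = "character",
                 protein_pos = "integer"),
  phenotype = c(sample_id = "character", disease = "integer",
                quant = "numeric"),
  sumstats = c(snp = "character", ea = "character", oa = "character",
               eaf = "numeric", beta = "numeric", se = "numeric",
               n = "numeric"))

#' Write a table as schema-conformant TSV
#'
#' Tab-delimited, UTF-8, `.` for missing values, no quoting.
#'
#' @param table data.frame to write.
#' @param path Output path.
#' @export
write_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a TSV against a named schema
#'
#' @param path Input path.
#' @param schema One of `"annotation"`, `"phenotype"`, `"sumstats"`, or a
#'   named character vector of column classes.
#' @return data.frame with columns coerced to the declared classes; a
#'   schema violation raises an error naming the line and column.
#' @export
read_tsv_checked <- function(path, schema) {
  if (is.character(schema) && length(schema) == 1L) {
    if (!schema %in% names(table_schemas))
      stopf("unknown schema '%s'", schema, class = "exburden_config_error")
    schema <- table_schemas[[schema]]
  }
  raw <- utils::read.delim(path, colClasses = "character", na.strings = ".",
                           check.names = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(names(schema), names(raw))
  if (length(miss))
    stopf("%s: missing required column(s): %s", path,
          paste(miss, collapse = ", "), class = "exburden_data_error")
  for (col in names(schema)) {
    x <- raw[[col]]
    coerced <- switch(schema[[col]],
                      character = x,
                      numeric = suppressWarnings(as.numeric(x)),
                      integer = suppressWarnings(as.integer(x)),
                      logical = as.logical(x))
    bad <- which(!is.na(x) & is.na(coerced))
    if (length(bad))
      stopf("%s: line %d, column '%s': cannot parse '%s' as %s",
            path, bad[1] + 1L, col, x[bad[1]], schema[[col]],
            class = "exburden_data_error")
    raw[[col]] <- coerced
  }
  raw
}
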