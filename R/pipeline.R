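#' Validate a pipeline configuration
#'
#' The configuration is a named list (or a YAML file path) with sections
#' `seed`, `output_dir`, and either `cohort` (synthetic-cohort parameters
#' passed to [cohort_config()]) or `inputs` (paths to a genotype VCF,
#' annotation TSV, and phenotype/covariate TSV), plus optional `qc`,
#' `masks`, and `screen` sections. Unknown keys are rejected and all
#' referenced paths must exist at validation time.
#'
#' @param config Named list or path to a YAML file.
#' @return The validated configuration list.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stopf("config file '%s' does not exist", config, class = "exburden_config_error")
    config <- yaml::read_yaml(config)
  }
  allowed <- c("seed", "output_dir", "cohort", "inputs", "qc", "masks",
               "screen", "write_vcf", "log_level")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "),
          class = "exburden_config_error")
  if (is.null(config$output_dir))
    stopf("configuration key 'output_dir' is required", class = "exburden_config_error")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$cohort) && is.null(config$inputs))
    stopf("configuration needs either 'cohort' (simulate) or 'inputs' (paths)",
          class = "exburden_config_error")
  if (!is.null(config$inputs)) {
    need <- c("vcf", "annotations", "phenotypes", "covariates")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss))
      stopf("inputs missing path(s): %s", paste(miss, collapse = ", "),
            class = "exburden_config_error")
    for (p in unlist(config$inputs))
      if (!file.exists(p))
        stopf("input path '%s' does not exist", p, class = "exburden_config_error")
  }
  config
}

#' Run the end-to-end collapsing burden pipeline
#'
#' Orchestrates the stages in their canonical order: obtain a cohort
#' (simulate or read), genotype/variant QC, annotation prioritization and
#' mask assignment, carrier collapsing, the exome-wide burden screen, and
#' diagnostics export. Deterministic given the seed. Writes result TSVs,
#' QQ/Manhattan/forest data exports, and a JSON run manifest recording the
#' seed, thresholds, and variant counts in/out of every filter.
#'
#' @param config See [validate_pipeline_config()].
#' @return Invisibly, a list with the `exwas_screen` object, the manifest,
#'   and output paths.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  if (!is.null(config$cohort)) {
    cc <- do.call(cohort_config, c(config$cohort, list(seed = seed)))
    cohort <- simulate_cohort(cc)
    # true carriers of causal genes (pre-QC truth) drive the phenotype
    carr_true <- NULL
    if (!is.null(cc$causal_genes)) {
      qual <- cohort$variants[cohort$variants$gene %in% cc$causal_genes$gene, ]
      cmx <- collapse_gene_carriers(qual, cohort$calls, cohort$samples, "truth")
      carr_true <- as.matrix(cmx)
      carr_true <- carr_true[cohort$samples, , drop = FALSE]
    }
    phenotypes <- simulate_phenotypes(carr_true, cohort$covariates, cc)
    if (isTRUE(config$write_vcf))
      write_cohort_vcf(cohort$variants, cohort$calls, cohort$samples,
                       file.path(config$output_dir, "cohort.vcf"))
  } else {
    vc <- read_cohort_vcf(config$inputs$vcf)
    cohort <- list(variants = vc$variants, calls = vc$calls,
                   samples = vc$samples,
                   annotations = read_tsv_checked(config$inputs$annotations,
                                                  "annotation"),
                   covariates = utils::read.delim(config$inputs$covariates,
                                                  na.strings = "."))
    cohort$variants$gene <-
      cohort$annotations$gene[match(cohort$variants$variant_id,
                                    cohort$annotations$variant_id)]
    phenotypes <- read_tsv_checked(config$inputs$phenotypes, "phenotype")
  }

  qc_args <- config$qc
  qc <- do.call(qc_genotypes,
                c(list(variants = cohort$variants, calls = cohort$calls,
                       n_samples = length(cohort$samples)), qc_args))

  ann <- prioritize_annotations(cohort$annotations)
  ann <- ann[ann$variant_id %in% qc$variants$variant_id, , drop = FALSE]
  ann$ac <- qc$variants$ac[match(ann$variant_id, qc$variants$variant_id)]
  ann$an <- qc$variants$an[match(ann$variant_id, qc$variants$variant_id)]
  ann$maf <- qc$variants$maf[match(ann$variant_id, qc$variants$variant_id)]

  masks <- if (!is.null(config$masks)) {
    dm <- default_masks(); dm[dm$name %in% config$masks, , drop = FALSE]
  } else default_masks()

  carrier_sets <- list(); gene_maf <- list(); mask_counts <- list()
  for (i in seq_len(nrow(masks))) {
    mk <- masks[i, ]
    member <- mask_membership(ann, mk)
    qual <- qc$variants[qc$variants$variant_id %in% ann$variant_id[member], ]
    qual$gene <- ann$gene[match(qual$variant_id, ann$variant_id)]
    mask_counts[[mk$name]] <- nrow(qual)
    if (!nrow(qual)) next
    carrier_sets[[mk$name]] <-
      collapse_gene_carriers(qual, qc$calls, cohort$samples, mk$name)
    gene_maf[[mk$name]] <- vapply(split(qual$maf, qual$gene), sum, numeric(1))
  }

  sc_args <- config$screen
  sc <- do.call(screen_config, if (is.null(sc_args)) list() else sc_args)
  screen <- run_exome_screen(carrier_sets, phenotypes, cohort$covariates,
                             config = sc, gene_maf = gene_maf)

  paths <- export_diagnostics(screen, config$output_dir,
                              gene_pos = cohort$variants)
  manifest <- list(
    package_version = as.character(utils::packageVersion("exburden")),
    seed = seed,
    thresholds = list(significance = sc$sig_threshold,
                      carrier_floor = sc$carrier_floor, gate = sc$gate),
    counts = list(
      n_samples = length(cohort$samples),
      variants_in = nrow(cohort$variants),
      variants_kept = nrow(qc$variants),
      variants_dropped = nrow(cohort$variants) - nrow(qc$variants),
      qualifying_per_mask = mask_counts),
    lambda = as.list(screen$lambda))
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(screen = screen, qc = qc, manifest = manifest,
                 paths = c(paths, manifest = manifest_path)))
}

#' Export QQ, Manhattan, and forest data behind the screen
#'
#' Plain TSVs: `results.tsv` (all gene-mask rows), `qq.tsv` (per-mask
#' expected vs observed -log10 p with the inflation lambda), `manhattan.tsv`
#' (gene position vs p), `forest.tsv` (significant gene-mask pairs with OR
#' and confidence bounds).
#'
#' @param screen An `exwas_screen`.
#' @param dir Output directory.
#' @param gene_pos Optional variant table (`gene`, `chrom`, `pos`) giving
#'   each gene a plotting coordinate.
#' @return Named vector of file paths.
#' @export
export_diagnostics <- function(screen, dir, gene_pos = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- screen$results
  p_results <- file.path(dir, "results.tsv")
  cols <- c("gene", "mask", "stage", "beta", "se", "p", "or", "ci_lo",
            "ci_hi", "carriers", "case_carriers", "cmaf", "penetrance",
            "significant")
  if (is.null(r)) r <- as.data.frame(stats::setNames(
    replicate(length(cols), logical(0), simplify = FALSE), cols))
  write_tsv(r[, intersect(cols, names(r)), drop = FALSE], p_results)

  qq <- do.call(rbind, lapply(unique(r$mask), function(m) {
    p <- sort(r$p[r$mask == m])
    k <- length(p)
    data.frame(mask = m, rank = seq_len(k),
               expected = -log10((seq_len(k) - 0.5) / k),
               observed = -log10(p),
               lambda = unname(screen$lambda[m]), stringsAsFactors = FALSE)
  }))
  if (is.null(qq)) qq <- data.frame(mask = character(0), rank = integer(0),
                                    expected = numeric(0), observed = numeric(0),
                                    lambda = numeric(0))
  p_qq <- file.path(dir, "qq.tsv")
  write_tsv(qq, p_qq)

  mh <- r[, intersect(c("gene", "mask", "p", "significant"), names(r)), drop = FALSE]
  if (!is.null(gene_pos) && nrow(mh)) {
    ix <- match(mh$gene, gene_pos$gene)
    mh$chrom <- gene_pos$chrom[ix]
    mh$pos <- gene_pos$pos[ix]
  }
  p_mh <- file.path(dir, "manhattan.tsv")
  write_tsv(mh, p_mh)

  fo <- r[isTRUE(nrow(r) > 0) & r$significant %in% TRUE, , drop = FALSE]
  p_fo <- file.path(dir, "forest.tsv")
  write_tsv(fo[, intersect(cols, names(fo)), drop = FALSE], p_fo)

  c(results = p_results, qq = p_qq, manhattan = p_mh, forest = p_fo)
}
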