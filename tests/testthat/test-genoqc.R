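# Variant normalization and genotype-level QC.

test_that("biallelic SNVs pass through splitting unchanged", {
  ctx <- "ACGTACGTACGT"
  out <- split_and_left_align("1", 5, "A", "T", ctx, 1)
  expect_equal(out$pos, 5)
  expect_equal(out$ref, "A")
  expect_equal(out$alt, "T")
  expect_equal(out$type, "SNV")
})

test_that("multi-allelic indel splits into minimally represented alleles", {
  # pos 100 REF=CT ALT=C,CTT on context ...ACTG...
  ctx <- "AACTGG"
  out <- split_and_left_align("1", 100, "CT", c("C", "CTT"), ctx, 98,
                              ac = c(3L, 1L), an = 200L)
  expect_equal(nrow(out), 2L)
  del <- out[1, ]; ins <- out[2, ]
  expect_equal(del$type, "InDel")
  expect_equal(nchar(del$ref) - nchar(del$alt), 1L)   # 1-bp deletion
  expect_equal(nchar(ins$alt) - nchar(ins$ref), 1L)   # 1-bp insertion
  expect_equal(out$ac, c(3L, 1L))
  # agree with the brute-force enumeration oracle
  for (i in 1:2) {
    o <- normalize_oracle(ctx, 3, "CT", c("C", "CTT")[i])
    expect_equal(out$pos[i] - 97L, o$pos)
    expect_equal(out$ref[i], o$ref)
    expect_equal(out$alt[i], o$alt)
  }
})

test_that("deletions in homopolymer runs shift to the leftmost placement", {
  ctx <- "GATTTTTC"   # TTTTT run at 3..7
  out <- split_and_left_align("1", 6, "TT", "T", ctx, 1)
  o <- normalize_oracle(ctx, 6, "TT", "T")
  expect_equal(out$pos, o$pos)
  expect_equal(out$ref, o$ref)
  expect_equal(out$alt, o$alt)
  expect_equal(out$pos, 2)  # anchored on the G-adjacent base
})

test_that("random indel representations normalize to the oracle's answer", {
  set.seed(7)
  for (rep in 1:60) {
    # 'GC' prefix anchors left shifts inside the context window
    ctx <- paste0("GC", paste(sample(c("A", "T"), 12, TRUE), collapse = ""))
    pos <- sample(4:9, 1)
    rlen <- sample(1:3, 1)
    ref <- substr(ctx, pos, pos + rlen - 1L)
    alt <- if (runif(1) < 0.5) substr(ctx, pos, pos) else
      paste0(ref, sample(c("A", "T"), 1))
    if (ref == alt) next
    out <- split_and_left_align("1", pos, ref, alt, ctx, 1)
    o <- normalize_oracle(ctx, pos, ref, alt)
    expect_equal(out$pos, o$pos)
    expect_equal(out$ref, o$ref)
    expect_equal(out$alt, o$alt)
  }
})

test_that("splitting rejects a REF inconsistent with the reference context", {
  expect_error(split_and_left_align("1", 3, "T", "C", "AAAAA", 1),
               "inconsistent")
})

test_that("depth/quality gate matches the stated thresholds", {
  expect_equal(filter_genotype("het", 6, 15, "SNV"), "missing")
  expect_equal(filter_genotype("het", 9, 19, "InDel"), "missing")
  expect_equal(filter_genotype("het", 100, 99, "SNV"), "het")
  # conjunction: one failing leg alone does not remove the call
  expect_equal(filter_genotype("het", 6, 50, "SNV"), "het")
  expect_equal(filter_genotype("het", 30, 10, "SNV"), "het")
  # disjunctive gate removes either
  expect_equal(filter_genotype("het", 6, 50, "SNV", gate = "or"), "missing")
  expect_equal(filter_genotype("het", 30, 10, "SNV", gate = "or"), "missing")
  expect_error(filter_genotype("het", -1, 50, "SNV"), "negative")
})

test_that("raising thresholds never decreases the number of missing calls", {
  set.seed(11)
  n <- 500
  gt <- sample(c("het", "hom_alt", "hom_ref"), n, TRUE)
  dp <- rpois(n, 12); gq <- runif(n, 0, 60)
  vt <- sample(c("SNV", "InDel"), n, TRUE)
  prev <- -1L
  for (thr in seq(0, 40, by = 5)) {
    miss <- sum(filter_genotype(gt, dp, gq, vt, gate = "or",
                                dp_min_snv = thr, dp_min_indel = thr,
                                gq_min = thr) == "missing")
    expect_gte(miss, prev)
    prev <- miss
  }
})

test_that("allele-balance p is exact, symmetric, and thresholds correctly", {
  expect_equal(allele_balance_p(10, 20), 1.0)
  expect_equal(allele_balance_p(0, 20), 2 * 0.5^20)
  p5 <- allele_balance_p(5, 20)
  expect_equal(p5, ab_p_oracle(5, 20), tolerance = 1e-12)
  expect_gt(p5, 1e-3)  # retained at the 1e-3 removal threshold
  expect_lt(allele_balance_p(0, 20), 1e-3)
  # symmetry p(k, n) = p(n-k, n), exhaustive to n = 60 here
  for (n in 1:60) {
    p <- allele_balance_p(0:n, n)
    expect_equal(p, rev(p))
  }
  expect_error(allele_balance_p(5, 0), "zero total reads")
  expect_error(allele_balance_p(5, 3), "alt_reads")
})

test_that("allele-balance p agrees with binom.test on a random sample", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(1:200, 1); k <- sample(0:n, 1)
    expect_equal(allele_balance_p(k, n),
                 binom.test(k, n, 0.5)$p.value, tolerance = 1e-12)
  }
})

test_that("unbalanced het SNVs are set missing, indels and homs untouched", {
  gt <- c("het", "het", "hom_alt", "het")
  vt <- c("SNV", "InDel", "SNV", "SNV")
  out <- filter_allele_balance(gt, vt, ad_alt = c(0, 0, 30, 10),
                               dp = c(30, 30, 30, 20))
  expect_equal(out, c("missing", "het", "hom_alt", "het"))
})

test_that("missingness filter drops strictly above 50%", {
  expect_false(apply_variant_missingness(6, 10)$keep)
  expect_true(apply_variant_missingness(5, 10)$keep)
  expect_true(apply_variant_missingness(0, 10)$keep)
  expect_error(apply_variant_missingness(0, 0), "zero samples")
})

test_that("cohort QC recomputes AC/AN and never increases them", {
  cc <- cohort_config(n_samples = 400, n_genes = 40, seed = 5,
                      lowq_rate = 0.15, ab_error_rate = 0.1)
  co <- simulate_cohort(cc)
  qc <- qc_genotypes(co$variants, co$calls, 400)
  pre <- co$variants[match(qc$variants$variant_id, co$variants$variant_id), ]
  expect_true(all(qc$variants$ac <= pre$ac))
  expect_true(all(qc$variants$an <= pre$an))
  expect_true(all(qc$report$missingness >= 0 & qc$report$missingness <= 1))
  # counts are conserved per filter
  expect_equal(nrow(qc$variants) + sum(!qc$report$keep), nrow(co$variants))
})
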