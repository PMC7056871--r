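test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- small_sim_config(seed = 5L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$sumstats, b$sumstats)
  expect_identical(a$counts, b$counts)
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$truth, b$truth)
})

test_that("infeasible planting is rejected", {
  expect_error(sim_config(n_planted = 50L, n_mirnas = 10L), "infeasible")
})

test_that("stored summary statistics match an independent regression oracle", {
  co <- simulate_cohort(small_sim_config(seed = 6L))
  set.seed(61)
  pick <- co$sumstats[sample.int(nrow(co$sumstats), 15), ]
  for (i in seq_len(nrow(pick))) {
    g <- co$genotypes[, pick$rsid[i]]
    y <- co$phenotypes$gwas[[pick$trait[i]]]
    fit <- summary(stats::lm(y ~ g))
    expect_equal(pick$beta[i], unname(fit$coefficients["g", "Estimate"]),
                 tolerance = 1e-8)
    expect_equal(pick$se[i], unname(fit$coefficients["g", "Std. Error"]),
                 tolerance = 1e-8)
    expect_equal(pick$p[i], unname(fit$coefficients["g", "Pr(>|t|)"]),
                 tolerance = 1e-8)
  }
})

test_that("mean-SD profile of simulated log2-CPM decreases in the mean", {
  co <- simulate_cohort(small_sim_config(seed = 8L))
  lc <- cpm_log2(co$counts)
  keep <- !(rownames(lc) %in% co$housekeeping)
  m <- rowMeans(lc[keep, ])
  s <- apply(lc[keep, ], 1, sd)
  # strong negative rank association between mean and SD
  expect_lt(cor(m, s, method = "spearman"), -0.6)
})

test_that("planted SNP effects are overwhelmingly detectable at the study threshold", {
  # analytic power of the two-sided Wald test: beta 0.4, maf 0.3, n 5000
  beta <- 0.4; maf <- 0.3; n <- 5000
  se <- 1 / sqrt(n * 2 * maf * (1 - maf))
  ncp <- beta / se
  thr <- 2.12e-5
  z_crit <- qnorm(thr / 2, lower.tail = FALSE)
  power <- pnorm(-z_crit + ncp) + pnorm(-z_crit - ncp)
  expect_gte(power, 0.99)

  # one simulated replicate: every planted SNP-trait pair beats its threshold
  co <- simulate_cohort(small_sim_config(seed = 9L, n_gwas = 5000L))
  hits <- dplyr::inner_join(co$truth, co$sumstats,
                            by = c(rsid = "rsid", trait = "trait"))
  expect_equal(nrow(hits), nrow(co$truth))
  expect_true(all(hits$p < thr))
})

test_that("a null cohort produces near-nominal significant fractions", {
  co <- simulate_cohort(small_sim_config(seed = 10L, n_planted = 0L))
  frac <- mean(co$sumstats$p < 0.05, na.rm = TRUE)
  # SNPs are LD-correlated, so allow a generous band around 0.05
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
  expect_equal(nrow(co$truth), 0)
})

test_that("the full pipeline recovers planted three-layer miRNAs", {
  cfg <- sim_config(seed = 21L, n_gwas = 1500L, n_meth = 350L, n_expr = 450L,
                    n_mirnas = 60L, n_snps = 600L, n_cpgs = 300L,
                    n_eqtl_snps = 60L, n_planted = 6L)
  co <- simulate_cohort(cfg)
  res <- run_pipeline(co)
  sel <- res$records$mirna[res$records$selected]
  expect_gte(sum(co$truth$mirna_id %in% sel), ceiling(0.9 * nrow(co$truth)))
  # evidence matrix only contains SNP-layer miRNAs
  sig_fams <- unique(mirna_family(
    res$snp_results$mirna_id[res$snp_results$significant]
  ))
  expect_setequal(res$evidence$mirna, sig_fams)
  # planted me-QTL pairs are all cis by construction
  expect_true(all(co$meqtl$cis_trans == "cis"))
  expect_gte(nrow(res$meqtl_crossref), 1)
})

test_that("cohorts round-trip through the pipeline's file formats", {
  co <- simulate_cohort(small_sim_config(seed = 12L))
  d <- withr::local_tempdir()
  paths <- write_cohort(co, d)

  ann <- read_mirna_gff(paths[["gff"]])
  expect_equal(nrow(ann$precursors), nrow(co$annotation$precursors))
  expect_equal(ann$precursors$start, co$annotation$precursors$start)
  expect_equal(sort(ann$matures$mature_id),
               sort(co$annotation$matures$mature_id))
  # mature arms derive from their precursor
  expect_true(all(ann$matures$mirna_id %in% ann$precursors$mirna_id))

  snps <- read_snp_catalog(paths[["region_snps"]])
  expect_equal(nrow(snps), nrow(co$region_snps))
  expect_equal(sort(snps$site_id), sort(co$region_snps$site_id))

  cpgs <- read_cpg_manifest(paths[["cpg_manifest"]])
  expect_equal(cpgs$site_id, co$cpg_manifest$site_id)

  meth <- read_matrix_tsv(paths[["methylation"]])
  expect_equal(dim(meth), dim(co$methylation))
  expect_equal(unname(meth[3, 5]), unname(co$methylation[3, 5]),
               tolerance = 1e-9)

  ss <- read_sumstats(paths[["sumstats"]], trait = "ignored", panel = "1000g")
  expect_equal(nrow(ss), nrow(co$sumstats))

  ph <- read_phenotypes(paths[["pheno_meth"]])
  expect_equal(ph$sample_id, co$phenotypes$meth$sample_id)

  mq <- read_meqtl(paths[["meqtl"]])
  expect_equal(mq$cis_trans, co$meqtl$cis_trans)
})

test_that("summary-statistic readers tolerate header dialects", {
  d <- withr::local_tempdir()
  f <- file.path(d, "ss.tsv")
  readr::write_tsv(tibble::tibble(
    SNP = c("rs1", "rs2"), CHR = "1", BP = c(100L, 200L),
    A1 = c("A", "C"), A2 = c("G", "T"),
    BETA = c(0.1, -0.2), SE = c(0.01, 0.02), P = c(1e-8, 0.5),
    N = c(10000, 10000)
  ), f)
  ss <- read_sumstats(f, trait = "TC", panel = "hapmap")
  expect_equal(ss$rsid, c("rs1", "rs2"))
  expect_equal(ss$beta, c(0.1, -0.2))
  expect_equal(ss$p, c(1e-8, 0.5))

  # explicit column map overrides sniffing
  f2 <- file.path(d, "ss2.tsv")
  readr::write_tsv(tibble::tibble(MarkerName = "rs9", P.value = 0.01), f2)
  ss2 <- read_sumstats(f2, trait = "TC", panel = "1000g",
                       col_map = c(rsid = "MarkerName", p = "P.value"))
  expect_equal(ss2$rsid, "rs9")
  expect_equal(ss2$p, 0.01)

  f3 <- file.path(d, "ss3.tsv")
  readr::write_tsv(tibble::tibble(foo = "rs1", bar = 0.5), f3)
  expect_error(read_sumstats(f3, trait = "TC"), "col_map")
})

test_that("sites-only VCF catalogs are read when vcfR is available", {
  skip_if_not_installed("vcfR")
  d <- withr::local_tempdir()
  f <- file.path(d, "sites.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "1\t12345\trs100\tA\tG\t.\t.\t.",
    "1\t22345\trs200\tC\tT\t.\t.\t."
  ), f)
  cat <- read_snp_vcf(f)
  expect_equal(cat$site_id, c("rs100", "rs200"))
  expect_equal(cat$pos, c(12345L, 22345L))
  expect_equal(cat$a1, c("G", "T")) # ALT is the effect allele
})

test_that("target-gene BED intervals parse with their miRNA link", {
  d <- withr::local_tempdir()
  f <- file.path(d, "genes.bed")
  writeLines(c("1\t1000\t2000\tmir-a|GENE1", "2\t5000\t9000\tmir-b|GENE2"), f)
  g <- read_target_genes_bed(f)
  expect_equal(g$mirna_id, c("mir-a", "mir-b"))
  expect_equal(g$gene, c("GENE1", "GENE2"))
  expect_equal(g$start0, c(1000L, 5000L))
})
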