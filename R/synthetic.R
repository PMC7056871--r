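#' Simulation configuration
#'
#' Defaults emulate the study design at desk scale: a large GWAS cohort
#' (n = 5,000) so consortium-scale SNP effects are detectable at Bonferroni
#' thresholds around 2e-5, a methylation cohort of 700 with technical batch
#' random intercepts, an expression cohort of 1,000, 300 miRNAs, 5,000 SNPs
#' in AR(1) LD blocks and 2,000 CpGs in miRNA flanks. Counts follow a
#' log-normal model on the log2-CPM scale whose SD decreases with the mean
#' (`sd = 2 * exp(-mean / 3) + 0.2`), the profile the LLOQ stage assumes.
#'
#' @param seed Integer RNG seed; identical config + seed gives identical
#'   cohorts.
#' @param n_gwas,n_meth,n_expr Cohort sizes per omics layer.
#' @param n_mirnas,n_snps,n_cpgs Feature counts (`n_snps` includes
#'   `n_eqtl_snps` distal miR-eQTL catalog SNPs).
#' @param n_eqtl_snps Distal miR-eQTL catalog SNPs.
#' @param n_planted Number of planted three-layer miRNAs (each gets a SNP, a
#'   CpG and an expression effect on one shared trait).
#' @param flank_bp Regulatory flank (default 2000).
#' @param ld_rho AR(1) latent correlation within LD blocks, in [0, 1).
#' @param block_size SNPs per LD block.
#' @param maf_range Minor allele frequency range.
#' @param snp_beta Planted per-allele SNP effect on the trait scale.
#' @param meth_base,meth_effect,meth_noise_sd,batch_sd,n_batches Methylation
#'   model: beta-value baseline, effect per trait SD, residual SD, batch
#'   intercept SD, number of batches.
#' @param expr_effect Trait effect per SD of log2-CPM for planted miRNAs.
#' @param disease_logor Planted log-odds-ratio for disease traits.
#' @param prevalence Named prevalences for T2D and CHD.
#' @param mean_range Range of per-miRNA mean log2-CPM for unplanted miRNAs;
#'   planted miRNAs draw from the upper half.
#' @param n_housekeeping Housekeeping probes appended to the count matrix.
#' @param traits GWAS trait codes simulated (continuous association scores).
#' @param planted_traits Traits planted effects may use (continuous traits
#'   measured in all cohorts).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_gwas = 5000L, n_meth = 700L, n_expr = 1000L,
                       n_mirnas = 300L, n_snps = 5000L, n_cpgs = 2000L,
                       n_eqtl_snps = 300L, n_planted = 10L,
                       flank_bp = 2000L, ld_rho = 0.8, block_size = 25L,
                       maf_range = c(0.05, 0.5), snp_beta = 0.4,
                       meth_base = 0.5, meth_effect = 0.01,
                       meth_noise_sd = 0.02, batch_sd = 0.01, n_batches = 8L,
                       expr_effect = 0.25, disease_logor = 0.5,
                       prevalence = c(T2D = 0.15, CHD = 0.10),
                       mean_range = c(-2, 10), n_housekeeping = 13L,
                       traits = setdiff(trait_vocabulary(), "CHD"),
                       planted_traits = c("BMI", "WC", "WHR", "FG", "HDL",
                                          "TC", "LDL", "TG", "SBP", "DBP")) {
  stopifnot(ld_rho >= 0, ld_rho < 1, n_planted >= 0)
  if (n_planted > n_mirnas) {
    stop("infeasible config: more planted miRNAs than miRNAs", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

# chromosome labels used by the generator
.sim_chroms <- as.character(1:22)

# AR(1) latent Gaussian haplotypes thresholded to dosages {0,1,2}
.sim_genotypes <- function(n, mafs, block_id, rho) {
  p <- length(mafs)
  hap <- function() {
    e <- matrix(rnorm(n * p), n, p)
    z <- e
    if (p >= 2) {
      for (j in 2:p) {
        if (block_id[j] == block_id[j - 1]) {
          z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * e[, j]
        }
      }
    }
    z
  }
  thr <- qnorm(1 - mafs)
  g <- (hap() > rep(thr, each = n)) + (hap() > rep(thr, each = n))
  storage.mode(g) <- "integer"
  g
}

# single-variant OLS summary statistics for one trait against all SNPs;
# gc is the column-centered genotype matrix, sxx its column sums of squares
.sim_sumstats_one <- function(gc, sxx, y) {
  n <- length(y)
  yc <- y - mean(y)
  sxy <- as.numeric(crossprod(gc, yc))
  syy <- sum(yc^2)
  beta <- sxy / sxx
  sigma2 <- (syy - beta * sxy) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  p <- 2 * pt(-abs(beta / se), df = n - 2)
  list(beta = unname(beta), se = unname(se), p = unname(p))
}

.sim_covariates <- function(n, prefix) {
  tibble::tibble(
    sample_id = sprintf("%s%04d", prefix, seq_len(n)),
    age = round(rnorm(n, 65, 8), 1),
    sex = rbinom(n, 1, 0.5),
    current_smoking = rbinom(n, 1, 0.2),
    monocytes = pmax(rnorm(n, 0.08, 0.02), 0),
    granulocytes = pmax(rnorm(n, 0.60, 0.08), 0),
    lymphocytes = pmax(rnorm(n, 0.30, 0.06), 0),
    bmi = round(rnorm(n, 27, 4), 1),
    diabetic_med = rbinom(n, 1, 0.1),
    lipid_med = rbinom(n, 1, 0.2),
    bp_med = rbinom(n, 1, 0.25)
  )
}

#' Simulate a complete multi-omics cohort with planted truth
#'
#' Generates internally consistent inputs for every pipeline stage: a miRNA
#' annotation, SNP and miR-eQTL catalogs, genotypes with AR(1) LD blocks,
#' per-trait GWAS summary statistics computed from those genotypes by
#' single-variant regression, a methylation matrix with batch random
#' intercepts, a miRNA count matrix with a decreasing mean-SD profile,
#' phenotype tables per cohort, me-QTL / miR-eQTM reference tables, and
#' truth tables recording every planted effect. Each planted miRNA carries
#' a SNP, a CpG and an expression effect on one shared trait, so the
#' integration stage can be validated against known truth.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_cohort` list; see the elements documented in the
#'   package vignette.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nm <- config$n_mirnas

  ## miRNA annotation: precursors spaced 1 Mb apart, two mature arms inside
  chrom <- .sim_chroms[(seq_len(nm) - 1) %% length(.sim_chroms) + 1]
  locus <- ((seq_len(nm) - 1) %/% length(.sim_chroms))
  prec_start <- 1e6L + locus * 1000000L + sample(0:5000, nm, replace = TRUE)
  prec_len <- sample(70:110, nm, replace = TRUE)
  strand <- sample(c("+", "-"), nm, replace = TRUE)
  mirna_id <- sprintf("mir-s%03d", seq_len(nm))
  precursors <- tibble::tibble(
    mirna_id = mirna_id, chrom = chrom,
    start = prec_start, end = prec_start + prec_len, strand = strand,
    context = sample(c("intergenic", "intronic", "exonic"), nm,
                     replace = TRUE, prob = c(0.5, 0.4, 0.1))
  )
  matures <- dplyr::bind_rows(
    tibble::tibble(
      mature_id = sprintf("miR-s%03d-5p", seq_len(nm)), mirna_id = mirna_id,
      chrom = chrom, start = prec_start + 8L, end = prec_start + 29L,
      strand = strand
    ),
    tibble::tibble(
      mature_id = sprintf("miR-s%03d-3p", seq_len(nm)), mirna_id = mirna_id,
      chrom = chrom, start = prec_start + prec_len - 29L,
      end = prec_start + prec_len - 8L, strand = strand
    )
  )
  annotation <- list(precursors = precursors, matures = matures)

  ## SNP catalogs: region-scan SNPs inside flanks, eQTL SNPs distal
  n_region <- config$n_snps - config$n_eqtl_snps
  snp_mirna <- (seq_len(n_region) - 1) %% nm + 1
  span <- config$flank_bp
  snp_pos <- precursors$start[snp_mirna] +
    sample(-span:(span + 60L), n_region, replace = TRUE)
  region_snps <- tibble::tibble(
    site_id = sprintf("rsS%06d", seq_len(n_region)), site_kind = "snp",
    chrom = precursors$chrom[snp_mirna], pos = as.integer(snp_pos),
    a1 = sample(c("A", "C", "G", "T"), n_region, replace = TRUE),
    a2 = NA_character_, source = "region_scan"
  )
  region_snps$a2 <- vapply(region_snps$a1, function(a) {
    sample(setdiff(c("A", "C", "G", "T"), a), 1)
  }, character(1))
  eq_mirna <- sample.int(nm, config$n_eqtl_snps, replace = TRUE)
  eqtl_snps <- tibble::tibble(
    site_id = sprintf("rsE%06d", seq_len(config$n_eqtl_snps)),
    site_kind = "snp", chrom = precursors$chrom[eq_mirna],
    pos = as.integer(precursors$start[eq_mirna] +
                       sample(300000:500000, config$n_eqtl_snps, replace = TRUE)),
    a1 = "A", a2 = "G", source = "eqtl_catalog",
    mirna_id = precursors$mirna_id[eq_mirna]
  )
  catalog <- dplyr::bind_rows(region_snps,
                              dplyr::select(eqtl_snps, -"mirna_id"))
  catalog <- catalog[order(catalog$chrom, catalog$pos), , drop = FALSE]

  ## genotypes: AR(1) blocks along the position-sorted catalog
  mafs <- runif(nrow(catalog), config$maf_range[1], config$maf_range[2])
  block_id <- paste(
    catalog$chrom,
    (seq_len(nrow(catalog)) - 1) %/% config$block_size
  )
  G <- .sim_genotypes(config$n_gwas, mafs, block_id, config$ld_rho)
  colnames(G) <- catalog$site_id

  ## planted miRNAs: one shared trait per miRNA across all three layers
  planted_idx <- if (config$n_planted > 0) {
    sort(sample.int(nm, config$n_planted))
  } else integer(0)
  planted <- tibble::tibble(
    mirna_id = precursors$mirna_id[planted_idx],
    trait = if (length(planted_idx) > 0) {
      sample(config$planted_traits, length(planted_idx), replace = TRUE)
    } else character(0)
  )
  # planted SNP: a region-scan SNP of that miRNA
  planted$rsid <- vapply(planted$mirna_id, function(m) {
    k <- which(precursors$mirna_id == m)
    cand <- region_snps$site_id[snp_mirna == k]
    sample(cand, 1)
  }, character(1))

  ## GWAS phenotypes and summary statistics
  gwas_ph <- .sim_covariates(config$n_gwas, "G")
  traits <- config$traits
  trait_vals <- matrix(rnorm(config$n_gwas * length(traits)),
                       config$n_gwas, length(traits),
                       dimnames = list(NULL, traits))
  for (i in seq_len(nrow(planted))) {
    tr <- planted$trait[i]
    if (!tr %in% traits) next
    g <- G[, planted$rsid[i]]
    trait_vals[, tr] <- trait_vals[, tr] + config$snp_beta * g
  }
  for (tr in traits) gwas_ph[[tr]] <- trait_vals[, tr]
  panel_of_trait <- setNames(
    rep(c("hapmap", "1000g"), length.out = length(traits)), traits
  )
  # HapMap-imputed GWAS cover a subset of the catalog; 1000G covers all.
  # Planted variants are always measured (a planted truth must be
  # observable in the layer that is supposed to recover it).
  hapmap_cov <- sort(union(
    sample.int(nrow(catalog), round(0.6 * nrow(catalog))),
    match(planted$rsid, catalog$site_id)
  ))
  Gc <- sweep(G, 2, colMeans(G))
  sxx <- colSums(Gc^2)
  sumstats <- dplyr::bind_rows(lapply(traits, function(tr) {
    idx <- if (panel_of_trait[tr] == "hapmap") hapmap_cov else seq_len(nrow(catalog))
    st <- .sim_sumstats_one(Gc, sxx, trait_vals[, tr])
    tibble::tibble(
      rsid = catalog$site_id[idx], trait = tr,
      chrom = catalog$chrom[idx], pos = catalog$pos[idx],
      effect_allele = catalog$a1[idx], other_allele = catalog$a2[idx],
      beta = st$beta[idx], se = st$se[idx], p = st$p[idx],
      n = config$n_gwas, panel = panel_of_trait[tr]
    )
  }))
  rm(Gc)

  ## CpG manifest: CpGs inside miRNA flanks
  cpg_mirna <- (seq_len(config$n_cpgs) - 1) %% nm + 1
  cpg_manifest <- tibble::tibble(
    site_id = sprintf("cgS%06d", seq_len(config$n_cpgs)), site_kind = "cpg",
    chrom = precursors$chrom[cpg_mirna],
    pos = as.integer(precursors$start[cpg_mirna] +
                       sample(-span:(span + 60L), config$n_cpgs, replace = TRUE)),
    source = "manifest"
  )
  planted$cpg <- vapply(planted$mirna_id, function(m) {
    k <- which(precursors$mirna_id == m)
    sample(cpg_manifest$site_id[cpg_mirna == k], 1)
  }, character(1))

  ## methylation cohort
  meth_ph <- .sim_covariates(config$n_meth, "M")
  meth_ph$batch <- sprintf("b%02d", sample.int(config$n_batches,
                                               config$n_meth, replace = TRUE))
  meth_traits <- matrix(rnorm(config$n_meth * length(traits)),
                        config$n_meth, length(traits),
                        dimnames = list(NULL, traits))
  for (tr in traits) meth_ph[[tr]] <- meth_traits[, tr]
  batch_fx <- rnorm(config$n_batches, 0, config$batch_sd)
  names(batch_fx) <- sprintf("b%02d", seq_len(config$n_batches))
  base <- runif(config$n_cpgs, config$meth_base - 0.2, config$meth_base + 0.2)
  meth <- matrix(
    rnorm(config$n_cpgs * config$n_meth, 0, config$meth_noise_sd),
    config$n_cpgs, config$n_meth,
    dimnames = list(cpg_manifest$site_id, meth_ph$sample_id)
  )
  meth <- meth + base + rep(batch_fx[meth_ph$batch], each = config$n_cpgs)
  for (i in seq_len(nrow(planted))) {
    tr <- planted$trait[i]
    meth[planted$cpg[i], ] <- meth[planted$cpg[i], ] +
      config$meth_effect * scale(meth_ph[[tr]])[, 1]
  }
  meth <- pmin(pmax(meth, 0.001), 0.999)

  ## expression cohort: counts with decreasing mean-SD on the log2-CPM scale
  expr_ph <- .sim_covariates(config$n_expr, "E")
  mature_ids <- sprintf("miR-s%03d-5p", seq_len(nm))
  mu <- runif(nm, config$mean_range[1], config$mean_range[2])
  upper_half <- mean(config$mean_range) + c(0, diff(config$mean_range) / 2)
  mu[planted_idx] <- runif(length(planted_idx), upper_half[1] + 2, upper_half[2])
  sd_of_mean <- function(m) 2 * exp(-m / 3) + 0.2
  hk_ids <- if (config$n_housekeeping > 0) {
    sprintf("HK-%02d", seq_len(config$n_housekeeping))
  } else character(0)
  all_ids <- c(mature_ids, hk_ids)
  mu_all <- c(mu, rep(11, length(hk_ids)))
  sd_all <- sd_of_mean(mu_all)
  x <- matrix(rnorm(length(all_ids) * config$n_expr,
                    mean = rep(mu_all, config$n_expr),
                    sd = rep(sd_all, config$n_expr)),
              length(all_ids), config$n_expr,
              dimnames = list(all_ids, expr_ph$sample_id))
  lib <- round(runif(config$n_expr, 2e6, 4e6))
  lambda <- pmax(2^x - 1, 0) * rep(lib, each = length(all_ids)) / 1e6
  counts <- matrix(rpois(length(lambda), lambda), nrow(lambda), ncol(lambda),
                   dimnames = dimnames(lambda))
  log2cpm <- cpm_log2(counts)
  expr_traits_m <- matrix(rnorm(config$n_expr * length(traits)),
                          config$n_expr, length(traits),
                          dimnames = list(NULL, traits))
  planted$mature_id <- sprintf("miR-s%03d-5p", planted_idx)
  for (i in seq_len(nrow(planted))) {
    tr <- planted$trait[i]
    expr_traits_m[, tr] <- expr_traits_m[, tr] +
      config$expr_effect * scale(log2cpm[planted$mature_id[i], ])[, 1]
  }
  for (tr in traits) expr_ph[[tr]] <- expr_traits_m[, tr]
  for (d in intersect(names(config$prevalence), c("T2D", "CHD"))) {
    eta <- qlogis(config$prevalence[[d]])
    expr_ph[[d]] <- rbinom(config$n_expr, 1, plogis(eta))
  }

  ## reference tables: me-QTLs (planted SNP-CpG pairs, cis) and miR-eQTMs
  meqtl <- if (nrow(planted) > 0) {
    tibble::tibble(
      rsid = planted$rsid,
      snp_chr = catalog$chrom[match(planted$rsid, catalog$site_id)],
      snp_pos = catalog$pos[match(planted$rsid, catalog$site_id)],
      cpg = planted$cpg,
      cpg_chr = cpg_manifest$chrom[match(planted$cpg, cpg_manifest$site_id)],
      cpg_pos = cpg_manifest$pos[match(planted$cpg, cpg_manifest$site_id)],
      fdr = 0.001
    )
  } else {
    tibble::tibble(rsid = character(0), snp_chr = character(0),
                   snp_pos = integer(0), cpg = character(0),
                   cpg_chr = character(0), cpg_pos = integer(0),
                   fdr = numeric(0))
  }
  if (nrow(meqtl) > 0) {
    meqtl$cis_trans <- classify_cis_trans(meqtl$snp_chr, meqtl$snp_pos,
                                          meqtl$cpg_chr, meqtl$cpg_pos)
  } else {
    meqtl$cis_trans <- character(0)
  }
  eqtm <- tibble::tibble(
    cpg = planted$cpg, mirna = planted$mature_id,
    direction = -1, fdr = 0.001
  )
  flags <- tibble::tibble(mirna = planted$mirna_id, eqtl_evidence = TRUE,
                          tissue_expression = TRUE, structure_change = FALSE)

  structure(list(
    config = config,
    annotation = annotation,
    snp_catalog = catalog,
    region_snps = region_snps,
    eqtl_snps = eqtl_snps,
    genotypes = G,
    mafs = setNames(mafs, catalog$site_id),
    sumstats = sumstats,
    panel_of_trait = panel_of_trait,
    cpg_manifest = cpg_manifest,
    methylation = meth,
    counts = counts,
    housekeeping = hk_ids,
    phenotypes = list(gwas = gwas_ph, meth = meth_ph, expr = expr_ph),
    meqtl = meqtl,
    eqtm = eqtm,
    flags = flags,
    truth = planted
  ), class = "synthetic_cohort")
}

#' Empirical LD (r-squared) matrices per chromosome
#'
#' Squared Pearson correlations of dosages, computed per chromosome from the
#' cohort's genotype matrix.
#'
#' @param cohort A `synthetic_cohort`.
#' @param rsids Optional subset of SNP ids.
#' @return Named list of r2 matrices, one per chromosome.
#' @export
cohort_ld_matrices <- function(cohort, rsids = NULL) {
  cat <- cohort$snp_catalog
  if (!is.null(rsids)) cat <- cat[cat$site_id %in% rsids, , drop = FALSE]
  lapply(split(cat$site_id, cat$chrom), function(ids) {
    g <- cohort$genotypes[, ids, drop = FALSE]
    keep <- apply(g, 2, stats::sd) > 0
    r <- stats::cor(g[, keep, drop = FALSE])^2
    r
  })
}

#' Per-panel independent-SNP counts and Bonferroni thresholds
#'
#' For each imputation panel, LD-prunes (per chromosome) the catalog SNPs
#' present in that panel's GWAS and derives the panel's Bonferroni threshold
#' from the pruned count.
#'
#' @param cohort A `synthetic_cohort`.
#' @param alpha Family-wise level (default 0.05).
#' @param r2_max,window_bp Pruning parameters (defaults 0.7 / 250 kb).
#' @return List with `m` (named pruned counts per panel) and `thresholds`
#'   (named p-value cutoffs per panel).
#' @export
panel_thresholds <- function(cohort, alpha = 0.05, r2_max = 0.7,
                             window_bp = 250000L) {
  panels <- unique(cohort$sumstats$panel)
  m <- setNames(integer(length(panels)), panels)
  for (pn in panels) {
    ids <- unique(cohort$sumstats$rsid[cohort$sumstats$panel == pn])
    cat <- cohort$snp_catalog[cohort$snp_catalog$site_id %in% ids, ,
                              drop = FALSE]
    lds <- cohort_ld_matrices(cohort, rsids = ids)
    kept <- 0L
    for (ch in names(lds)) {
      sub <- cat[cat$chrom == ch, , drop = FALSE]
      kept <- kept + length(
        ld_prune(sub$site_id, lds[[ch]], r2_max = r2_max,
                 window_bp = window_bp, positions = sub$pos)
      )
    }
    m[pn] <- kept
  }
  list(m = m, thresholds = vapply(m, function(k) bonferroni_threshold(alpha, k),
                                  numeric(1)))
}

#' Run the full multi-omics pipeline on a synthetic cohort
#'
#' Annotation, per-panel pruning/thresholds, GWAS candidate testing, the
#' candidate-based EWAS and expression scans (restricted to SNP-implicated
#' miRNAs and their SNP-layer traits), me-QTL / miR-eQTM cross-referencing
#' and three-layer integration.
#'
#' @param cohort A `synthetic_cohort`.
#' @param alpha_fw Family-wise level for the SNP layer (default 0.05).
#' @param alpha_nominal Nominal level for the CpG/expression layers
#'   (default 0.05).
#' @return List with every stage's output: `regions`, `annotations`,
#'   `thresholds`, `snp_results`, `mirna_summary`, `ewas`, `expression`
#'   (normalization + results), `meqtl_crossref`, `eqtm_crossref`,
#'   `evidence`, `records`.
#' @export
run_pipeline <- function(cohort, alpha_fw = 0.05, alpha_nominal = 0.05) {
  cfg <- cohort$config
  regions <- build_mirna_regions(cohort$annotation, flank_bp = cfg$flank_bp)
  snp_ann <- map_sites_to_regions(cohort$region_snps, regions)
  snp_ann <- dplyr::bind_rows(
    snp_ann,
    eqtl_annotations(cohort$eqtl_snps)
  )
  cpg_ann <- map_sites_to_regions(cohort$cpg_manifest, regions)

  thr <- panel_thresholds(cohort, alpha = alpha_fw)
  snp_results <- test_gwas_associations(snp_ann, cohort$sumstats,
                                        thr$thresholds,
                                        catalog = cohort$snp_catalog)
  mirna_summary <- summarize_by_mirna(snp_results)

  sig <- snp_results[snp_results$significant, , drop = FALSE]
  sig_mirnas <- unique(sig$mirna_id)
  sig_traits <- unique(sig$trait)

  cand_probes <- unique(cpg_ann$site_id[cpg_ann$mirna_id %in% sig_mirnas])
  meth_traits <- intersect(sig_traits, names(cohort$phenotypes$meth))
  ewas <- run_ewas(cohort$methylation, cohort$phenotypes$meth, cand_probes,
                   meth_traits, annotations = cpg_ann, alpha = alpha_nominal)
  ewas <- ewas[ewas$mirna_id %in% sig_mirnas | is.na(ewas$mirna_id), ,
               drop = FALSE]

  norm <- normalize_expression(cohort$counts,
                               housekeeping = cohort$housekeeping)
  mature_map <- cohort$annotation$matures
  sig_matures <- mature_map$mature_id[mature_map$mirna_id %in% sig_mirnas]
  cand_matures <- intersect(sig_matures, norm$well_expressed)
  expr_traits <- intersect(sig_traits, names(cohort$phenotypes$expr))
  expr_results <- run_expression_assoc(norm$log2cpm, cohort$phenotypes$expr,
                                       cand_matures, expr_traits,
                                       alpha = alpha_nominal)
  # report results at precursor level via the mature->precursor map
  if (nrow(expr_results) > 0) {
    expr_results$mirna_id <- mature_map$mirna_id[
      match(expr_results$feature_id, mature_map$mature_id)
    ]
  }

  meqtl_x <- crossref_meqtl(snp_results, cohort$meqtl, ewas)
  eqtm_x <- crossref_eqtm(ewas, cohort$eqtm)
  eqtm_x_fam <- eqtm_x
  if (nrow(eqtm_x_fam) > 0) {
    # eqtm catalog names mature miRNAs; map to precursor ids for evidence
    idx <- match(eqtm_x_fam$mirna, mature_map$mature_id)
    eqtm_x_fam$mirna[!is.na(idx)] <- mature_map$mirna_id[idx[!is.na(idx)]]
  }

  cpg_tested <- unique(cpg_ann$mirna_id[cpg_ann$site_id %in% cand_probes])
  expr_tested <- unique(mature_map$mirna_id[
    mature_map$mature_id %in% cand_matures
  ])
  evidence <- build_evidence_matrix(
    snp_results, cpg_results = ewas, expr_results = expr_results,
    eqtm = eqtm_x_fam, flags = cohort$flags,
    cpg_tested = cpg_tested, expr_tested = expr_tested
  )
  records <- prioritize(select_multiomics(evidence))

  list(regions = regions, annotations = list(snp = snp_ann, cpg = cpg_ann),
       thresholds = thr, snp_results = snp_results,
       mirna_summary = mirna_summary, ewas = ewas,
       expression = list(normalization = norm, results = expr_results),
       meqtl_crossref = meqtl_x, eqtm_crossref = eqtm_x,
       evidence = evidence, records = records)
}

#' Write a synthetic cohort to the pipeline's file formats
#'
#' Emits the exact formats every reader in the package consumes: GFF3
#' annotation, TSV SNP catalogs and CpG manifest, TSV summary statistics,
#' methylation/count matrices, phenotype CSVs and reference tables.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory.
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- c(
    gff = file.path(dir, "mirna_annotation.gff3"),
    region_snps = file.path(dir, "snp_catalog_region.tsv"),
    eqtl_snps = file.path(dir, "snp_catalog_eqtl.tsv"),
    cpg_manifest = file.path(dir, "cpg_manifest.tsv"),
    sumstats = file.path(dir, "sumstats.tsv"),
    methylation = file.path(dir, "methylation.tsv"),
    counts = file.path(dir, "counts.tsv"),
    pheno_gwas = file.path(dir, "phenotypes_gwas.csv"),
    pheno_meth = file.path(dir, "phenotypes_meth.csv"),
    pheno_expr = file.path(dir, "phenotypes_expr.csv"),
    meqtl = file.path(dir, "meqtl.tsv"),
    eqtm = file.path(dir, "eqtm.tsv"),
    flags = file.path(dir, "flags.tsv")
  )
  prec <- cohort$annotation$precursors
  mat <- cohort$annotation$matures
  gff_lines <- c(
    "##gff-version 3",
    sprintf("%s\t.\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
            prec$chrom, prec$start, prec$end, prec$strand,
            prec$mirna_id, prec$mirna_id),
    sprintf("%s\t.\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;Derives_from=%s",
            mat$chrom, mat$start, mat$end, mat$strand,
            mat$mature_id, mat$mature_id, mat$mirna_id)
  )
  writeLines(gff_lines, p[["gff"]])
  rs <- dplyr::rename(cohort$region_snps, rsid = "site_id")
  readr::write_tsv(dplyr::select(rs, -"site_kind"), p[["region_snps"]])
  es <- dplyr::rename(cohort$eqtl_snps, rsid = "site_id")
  readr::write_tsv(dplyr::select(es, -"site_kind"), p[["eqtl_snps"]])
  readr::write_tsv(
    tibble::tibble(probe_id = cohort$cpg_manifest$site_id,
                   chrom = cohort$cpg_manifest$chrom,
                   pos = cohort$cpg_manifest$pos),
    p[["cpg_manifest"]]
  )
  readr::write_tsv(cohort$sumstats, p[["sumstats"]])
  write_matrix_tsv(cohort$methylation, p[["methylation"]], id_col = "probe_id")
  write_matrix_tsv(cohort$counts, p[["counts"]], id_col = "mirna_id")
  readr::write_csv(cohort$phenotypes$gwas, p[["pheno_gwas"]])
  readr::write_csv(cohort$phenotypes$meth, p[["pheno_meth"]])
  readr::write_csv(cohort$phenotypes$expr, p[["pheno_expr"]])
  readr::write_tsv(cohort$meqtl, p[["meqtl"]])
  readr::write_tsv(cohort$eqtm, p[["eqtm"]])
  readr::write_tsv(cohort$flags, p[["flags"]])
  invisible(p)
}
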