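#' Top SNP-layer loci fixture (20 rows)
#'
#' The printed table of the strongest SNP-trait associations, one row per
#' locus. Composite miRNA labels (e.g. `miR-10b-5p/126-5p`) mark SNPs
#' annotated to two miRNAs; [expand_locus_mirnas()] splits them.
#'
#' @return Tibble `mirna, rsid, chrom, pos, alleles, gene, location, trait,
#'   beta, p`.
#' @export
top_snp_loci_fixture <- function() {
  tibble::tribble(
    ~mirna, ~rsid, ~chrom, ~pos, ~alleles, ~gene, ~location, ~trait, ~beta, ~p,
    "miR-6886", "rs17248720", "19", 11198187L, "C/T", "LDLR", "Intronic", "LDL", 0.226, 2.40e-148,
    "miR-6863", "rs13306673", "16", 56900931L, "C/T", "SLC12A3", "Intronic", "HDL", 0.098, 2.76e-48,
    "miR-4263", "rs2305929", "2", 28113911L, "G/A", "BRE", "Intronic", "TG", 0.064, 1.13e-44,
    "miR-6773", "rs8057119", "16", 68268836L, "T/C", "ESRP2", "Intronic", "HDL", 0.072, 5.21e-40,
    "miR-611", "rs174538", "11", 61560081L, "G/A", "THEM258", "Exonic", "LDL", 0.050, 1.07e-34,
    "miR-1908-5p", "rs174548", "11", 61571348L, "C/G", "FADS1", "Exonic", "LDL", 0.047, 2.29e-31,
    "miR-10b-5p/126-5p", "rs532436", "9", 136149830L, "A/G", "ABO", "Exonic/Intronic", "LDL", 0.079, 4.02e-30,
    "miR-4721", "rs4788099", "16", 28763228L, "G/A", "TUMF", "Exonic", "BMI", 0.031, 1.09e-24,
    "miR-4531", "rs6509170", "19", 45159636L, "C/A", "LOC107985305", "Intronic", "LDL", 0.127, 1.54e-22,
    "miR-199a-1", "rs11085748", "19", 10927540L, "T/C", "DNM2", "Intronic", "LDL", 0.055, 1.46e-19,
    "miR-4999", "rs7254882", "19", 8359822L, "C/T", "MIR4999", "Intergenic", "HDL", 0.033, 6.66e-18,
    "miR-4639", "rs3757354", "6", 16127407L, "C/T", "MYLIP", "Intronic", "LDL", 0.038, 2.09e-17,
    "miR-640", "rs1000237", "19", 19518316L, "T/A", "GATAD2A", "Intronic", "TG", 0.033, 1.61e-16,
    "miR-3161", "rs79837139", "11", 48000780L, "C/T", "PTPRJ", "Intronic", "HDL", 0.062, 2.99e-16,
    "miR-100-5p/125b-5p", "rs7117842", "11", 122663796L, "C/T", "UBASH3B", "Intergenic/Intergenic", "TC", 0.029, 2.48e-15,
    "miR-148a", "rs4722551", "7", 25991826L, "C/T", "MIR148A", "Intergenic", "LDL", 0.039, 3.95e-14,
    "miR-139", "rs11605042", "11", 72700619L, "A/G", "ARAP1", "Intronic", "Pro-Ins", -0.053, 5.24e-13,
    "miR-3941", "rs71486610", "10", 124134803L, "C/G", "PLEKHA1", "Intronic", "T2D", -0.081, 3.30e-11,
    "miR-6745", "rs901750", "11", 47209472L, "A/G", "PACSIN3", "Intronic", "HDL", 0.024, 3.95e-11,
    "miR-196a-2-3p", "rs11614913", "12", 53991815L, "C/T", "MIR196A2", "Intergenic", "WHR", 0.029, 6.90e-11
  )
}

#' Split composite locus miRNA labels
#'
#' `miR-10b-5p/126-5p` becomes `c("miR-10b-5p", "miR-126-5p")`: the SNP is
#' annotated to both miRNAs of the locus.
#'
#' @param mirna Character vector of (possibly composite) labels.
#' @return List of character vectors, one element per input label.
#' @export
expand_locus_mirnas <- function(mirna) {
  lapply(strsplit(mirna, "/", fixed = TRUE), function(parts) {
    vapply(parts, function(p) {
      if (grepl("^(miR|mir|let)", p)) p else paste0("miR-", p)
    }, character(1), USE.NAMES = FALSE)
  })
}

#' me-QTL cross-reference fixture (8 SNP-CpG pairs)
#'
#' The printed table of cis-me-QTLs whose SNP is trait-associated: 8 pairs
#' over 7 unique SNPs (one SNP regulates two CpGs).
#'
#' @return Tibble `mirna, rsid, cpg, cis_trans, mir_eqtl, snp_traits,
#'   cpg_traits` (trait sets comma-separated).
#' @export
meqtl_fixture <- function() {
  tibble::tribble(
    ~mirna, ~rsid, ~cpg, ~cis_trans, ~mir_eqtl, ~snp_traits, ~cpg_traits,
    "miR-611", "rs174538", "cg16150798", "cis", FALSE, "FG,LDL,HDL,TG,TC", "WC",
    "miR-588", "rs9388486", "cg20229609", "cis", FALSE, "T2D", "SBP,DBP",
    "miR-1908-5p", "rs174548", "cg03921599", "cis", TRUE, "FG,HbA1c,LDL,HDL,TG,TC", "LDL,TC",
    "miR-199a-1", "rs3786719", "cg02907064", "cis", FALSE, "LDL,TC", "LDL",
    "miR-6745", "rs901750", "cg00724111", "cis", FALSE, "HDL", "FI,SBP,DBP",
    "miR-8073", "rs3809346", "cg22382805", "cis", FALSE, "CAD", "FI",
    "miR-653,miR-489", "rs2528521", "cg06934092", "cis", FALSE, "BMI", "FG,FI,TC",
    "miR-8073", "rs3809346", "cg19700260", "cis", FALSE, "CAD", "DBP"
  )
}

#' Plasma expression association fixture (12 rows)
#'
#' Mature miRNAs whose plasma level is associated with the same trait as
#' their SNP-layer evidence.
#'
#' @return Tibble `mirna, beta, p, trait`.
#' @export
expression_fixture <- function() {
  tibble::tribble(
    ~mirna, ~beta, ~p, ~trait,
    "miR-126-3p", 0.379, 1.09e-14, "TC",
    "miR-10b-5p", 0.352, 3.30e-11, "TC",
    "miR-126-5p", 0.258, 3.75e-11, "TC",
    "miR-148a-3p", 0.189, 8.01e-06, "TC",
    "miR-199a-1-3p", 0.171, 3.38e-05, "TC",
    "miR-125b-5p", 0.159, 2.43e-03, "TC",
    "miR-100-5p", 0.141, 3.15e-03, "TC",
    "miR-6886-3p", -0.083, 9.49e-03, "TC",
    "miR-126-5p", -0.365, 1.24e-02, "CHD",
    "miR-4681", -0.440, 2.13e-02, "WC",
    "miR-199a-1-5p", 0.074, 3.38e-02, "TC",
    "miR-126-3p", -0.385, 3.54e-02, "CHD"
  )
}

#' Multi-omics integration fixture (5 miRNAs)
#'
#' The five miRNAs supported by all three layers, with their full SNP-layer
#' trait sets, the CpG and expression evidence, the miR-eQTM link, and the
#' miR-eQTL ("GWAS") prioritization flag (true for four of the five).
#'
#' @return Tibble `mirna, snp_traits, rsid, snp_p, eqtl_evidence, cpg,
#'   cpg_p, cpg_trait, eqtm_cpg, eqtm_trait, expr_p, expr_trait`.
#' @export
integration_fixture <- function() {
  tibble::tribble(
    ~mirna, ~snp_traits, ~rsid, ~snp_p, ~eqtl_evidence,
    ~cpg, ~cpg_p, ~cpg_trait, ~eqtm_cpg, ~eqtm_trait, ~expr_p, ~expr_trait,
    "miR-10b-5p", "LDL,TC,CAD,T2D", "rs532436", 4.02e-30, TRUE,
    "cg25820279", 4.37e-02, "TC", NA, NA, 3.30e-11, "TC",
    "miR-148a-3p", "LDL,TC,TG", "rs4722551", 3.95e-14, TRUE,
    "cg18188200", 1.94e-03, "TC", NA, NA, 8.01e-06, "TC",
    "miR-125b-5p", "TC,LDL,HDL", "rs7117842", 2.48e-15, TRUE,
    "cg06749053", 2.39e-02, "LDL", "cg26363555", "HDL", 2.43e-03, "TC",
    "miR-100-5p", "TC,LDL,HDL", "rs7117842", 2.48e-15, TRUE,
    "cg14724899", 4.02e-02, "HDL", NA, NA, 3.15e-03, "TC",
    "miR-6886-3p", "LDL,TC,CAD", "rs17248720", 2.40e-148, FALSE,
    "cg19751789", 8.03e-04, "TC", NA, NA, 9.49e-03, "TC"
  )
}

#' miR-eQTM fixture (2 CpGs, 3 pairs)
#'
#' The two CpGs associated (FDR < 0.01) with miRNA expression: one CpG
#' regulates two miRNAs of the same locus.
#'
#' @return Tibble `cpg, mirna, direction, fdr, cpg_traits`.
#' @export
eqtm_fixture <- function() {
  tibble::tribble(
    ~cpg, ~mirna, ~direction, ~fdr, ~cpg_traits,
    "cg26363555", "miR-125b-5p", -1, 0.005, "FG,DBP,HDL",
    "cg26363555", "miR-100-5p", -1, 0.005, "FG,DBP,HDL",
    "cg03891346", "miR-100-5p", -1, 0.005, "WC"
  )
}

# split "A,B,C" trait strings into character vectors
split_traits <- function(x) strsplit(x, ",", fixed = TRUE)

#' Assemble the three fixture evidence layers
#'
#' Builds SNP-, CpG- and expression-layer association tables from the
#' printed fixture tables, ready for [build_evidence_matrix()]. The SNP
#' layer uses the full trait sets of the five integrated miRNAs plus the top
#' loci for the remaining miRNAs (the locus table lists only each SNP's top
#' trait). Expression rows for miRNAs outside the fixture SNP layer (the
#' printed SNP table covers only the top 20 of the full candidate set) are
#' dropped, with the candidate-based restriction this implies.
#'
#' @return List `snp_results`, `cpg_results`, `expr_results` (association
#'   tibbles), `eqtm` (CpG-miRNA pairs for the integrated set), `flags`
#'   (prioritization flags per miRNA).
#' @export
fixture_evidence_layers <- function() {
  integ <- integration_fixture()
  top <- top_snp_loci_fixture()

  snp_rows <- list()
  for (i in seq_len(nrow(integ))) {
    traits <- split_traits(integ$snp_traits[i])[[1]]
    snp_rows[[i]] <- association_result(
      integ$rsid[i], integ$mirna[i], traits, "snp",
      NA_real_, NA_real_, integ$snp_p[i], NA_integer_, threshold = 1
    )
  }
  integ_fams <- mirna_family(integ$mirna)
  expanded <- expand_locus_mirnas(top$mirna)
  for (i in seq_len(nrow(top))) {
    for (id in expanded[[i]]) {
      if (mirna_family(id) %in% integ_fams) next
      snp_rows[[length(snp_rows) + 1L]] <- association_result(
        top$rsid[i], id, top$trait[i], "snp",
        top$beta[i], NA_real_, top$p[i], NA_integer_, threshold = 1
      )
    }
  }
  snp_results <- dplyr::bind_rows(snp_rows)

  cpg_results <- association_result(
    integ$cpg, integ$mirna, integ$cpg_trait, "cpg",
    NA_real_, NA_real_, integ$cpg_p, NA_integer_, threshold = 0.05
  )

  expr <- expression_fixture()
  snp_fams <- unique(mirna_family(snp_results$mirna_id))
  expr <- expr[mirna_family(expr$mirna) %in% snp_fams, , drop = FALSE]
  expr_results <- association_result(
    expr$mirna, expr$mirna, expr$trait, "expression",
    expr$beta, NA_real_, expr$p, NA_integer_, threshold = 0.05
  )

  eqtm <- integ[!is.na(integ$eqtm_cpg), c("eqtm_cpg", "mirna", "eqtm_trait")]
  names(eqtm) <- c("cpg", "mirna", "cpg_traits")
  flags <- tibble::tibble(mirna = integ$mirna,
                          eqtl_evidence = integ$eqtl_evidence)
  list(snp_results = snp_results, cpg_results = cpg_results,
       expr_results = expr_results, eqtm = eqtm, flags = flags)
}

#' Synthetic SNP catalogs matching the published cardinalities
#'
#' Deterministically constructs a region-scan catalog of 18,545 rsIDs and a
#' miR-eQTL catalog of 5,528 rsIDs sharing exactly 83 ids, so their union is
#' 23,990. IDs and positions are synthetic; only the cardinalities mirror
#' the real catalogs.
#'
#' @param n_region,n_eqtl,n_overlap Catalog sizes and overlap.
#' @return List of two catalog tibbles `region` and `eqtl`.
#' @export
fixture_snp_catalogs <- function(n_region = 18545L, n_eqtl = 5528L,
                                 n_overlap = 83L) {
  stopifnot(n_overlap <= n_region, n_overlap <= n_eqtl)
  region_ids <- sprintf("rs%07d", seq_len(n_region))
  eqtl_only <- sprintf("rs%07d", n_region + seq_len(n_eqtl - n_overlap))
  eqtl_ids <- c(region_ids[seq_len(n_overlap)], eqtl_only)
  mk <- function(ids, source) {
    tibble::tibble(
      site_id = ids, site_kind = "snp", chrom = "1",
      pos = match(ids, union(region_ids, eqtl_only)) * 100L,
      source = source
    )
  }
  list(region = mk(region_ids, "region_scan"), eqtl = mk(eqtl_ids, "eqtl_catalog"))
}

#' Write fixture tables to TSV files
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
make_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    top_snp_loci = file.path(dir, "top_snp_loci.tsv"),
    meqtl = file.path(dir, "meqtl_crossref.tsv"),
    expression = file.path(dir, "expression_assoc.tsv"),
    integration = file.path(dir, "integration.tsv"),
    eqtm = file.path(dir, "eqtm.tsv")
  )
  readr::write_tsv(top_snp_loci_fixture(), paths[["top_snp_loci"]])
  readr::write_tsv(meqtl_fixture(), paths[["meqtl"]])
  readr::write_tsv(expression_fixture(), paths[["expression"]])
  readr::write_tsv(integration_fixture(), paths[["integration"]])
  readr::write_tsv(eqtm_fixture(), paths[["eqtm"]])
  cats <- fixture_snp_catalogs()
  region_path <- file.path(dir, "snp_catalog_region.tsv")
  eqtl_path <- file.path(dir, "snp_catalog_eqtl.tsv")
  readr::write_tsv(cats$region, region_path)
  readr::write_tsv(cats$eqtl, eqtl_path)
  invisible(c(paths, region = region_path, eqtl = eqtl_path))
}
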