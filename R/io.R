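#' Read a miRBase-dialect GFF3 miRNA annotation
#'
#' Expects `miRNA_primary_transcript` features (precursors) and `miRNA`
#' features (mature arms) whose `Derives_from` attribute points at the
#' precursor's `ID`. Names come from the `Name` attribute. Coordinates are
#' kept 1-based inclusive, as in the file.
#'
#' @param path GFF3 file path.
#' @return List with tibbles `precursors` (`mirna_id`, `chrom`, `start`,
#'   `end`, `strand`) and `matures` (`mature_id`, `mirna_id`, `chrom`,
#'   `start`, `end`, `strand`).
#' @export
read_mirna_gff <- function(path) {
  gff <- rtracklayer::readGFF(path)
  gff <- as.data.frame(gff, stringsAsFactors = FALSE)
  is_prec <- gff$type == "miRNA_primary_transcript"
  is_mat <- gff$type == "miRNA"
  prec <- tibble::tibble(
    id = as.character(gff$ID[is_prec]),
    mirna_id = as.character(gff$Name[is_prec]),
    chrom = as.character(gff$seqid[is_prec]),
    start = as.integer(gff$start[is_prec]),
    end = as.integer(gff$end[is_prec]),
    strand = as.character(gff$strand[is_prec])
  )
  derives <- if ("Derives_from" %in% names(gff)) {
    as.character(gff$Derives_from[is_mat])
  } else {
    rep(NA_character_, sum(is_mat))
  }
  mat <- tibble::tibble(
    mature_id = as.character(gff$Name[is_mat]),
    mirna_id = prec$mirna_id[match(derives, prec$id)],
    chrom = as.character(gff$seqid[is_mat]),
    start = as.integer(gff$start[is_mat]),
    end = as.integer(gff$end[is_mat]),
    strand = as.character(gff$strand[is_mat])
  )
  list(precursors = dplyr::select(prec, -"id"), matures = mat)
}

#' Read a TSV SNP catalog
#'
#' Expected columns `rsid, chrom, pos, a1, a2, source` (extra columns such as
#' `mirna_id` for eQTL catalogs are kept). Positions 1-based.
#'
#' @param path TSV file path.
#' @return Tibble with `site_id`, `site_kind = "snp"`, `chrom`, `pos`, `a1`,
#'   `a2`, `source` (+ passthrough columns).
#' @export
read_snp_catalog <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  names(raw)[names(raw) == "rsid"] <- "site_id"
  raw$site_kind <- "snp"
  raw$pos <- as.integer(raw$pos)
  dplyr::relocate(tibble::as_tibble(raw), "site_id", "site_kind", "chrom", "pos")
}

#' Read a sites-only VCF as a SNP catalog
#'
#' Alternate SNP input; uses the `vcfR` package. REF/ALT become `a2`/`a1`
#' (effect allele = ALT).
#'
#' @param path VCF file path (plain text).
#' @param source Source tag recorded for every site.
#' @return Catalog tibble as in [read_snp_catalog()].
#' @export
read_snp_vcf <- function(path, source = "region_scan") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF catalogs requires the 'vcfR' package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  tibble::tibble(
    site_id = fix$ID, site_kind = "snp", chrom = fix$CHROM,
    pos = as.integer(fix$POS), a1 = fix$ALT, a2 = fix$REF, source = source
  )
}

#' Read an Illumina-450K-like CpG manifest
#'
#' Expected columns `probe_id, chrom, pos` (1-based).
#'
#' @param path TSV file path.
#' @return Tibble with `site_id`, `site_kind = "cpg"`, `chrom`, `pos`,
#'   `source = "manifest"`.
#' @export
read_cpg_manifest <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  tibble::tibble(
    site_id = raw$probe_id, site_kind = "cpg", chrom = raw$chrom,
    pos = as.integer(raw$pos), source = "manifest"
  )
}

# header dialects accepted by the summary-statistic reader
.sumstat_dialects <- list(
  rsid = c("rsid", "snp", "snpid", "markername", "rs_id", "id"),
  chrom = c("chrom", "chr", "chromosome"),
  pos = c("pos", "bp", "position", "base_pair_location"),
  effect_allele = c("effect_allele", "a1", "allele1", "ea", "alt"),
  other_allele = c("other_allele", "a2", "allele2", "oa", "ref", "nea"),
  beta = c("beta", "effect", "b", "beta_coefficient"),
  se = c("se", "stderr", "standard_error"),
  p = c("p", "pval", "p_value", "pvalue", "p.value"),
  n = c("n", "samplesize", "n_samples")
)

#' Read GWAS summary statistics
#'
#' Tolerant of common header dialects (`SNP`/`rsid`, `P`/`pval`,
#' `BETA`/`Effect`, ...); an explicit `col_map` (named vector mapping
#' canonical name -> file column) overrides sniffing.
#'
#' @param path TSV file path.
#' @param trait Trait code attached to every row.
#' @param panel Imputation panel, `"hapmap"` or `"1000g"`.
#' @param col_map Optional named character vector, e.g.
#'   `c(rsid = "MarkerName", p = "P.value")`.
#' @return Tibble with `rsid, trait, chrom, pos, effect_allele, other_allele,
#'   beta, se, p, n, panel` (missing optional columns become NA).
#' @export
read_sumstats <- function(path, trait, panel = c("hapmap", "1000g"),
                          col_map = NULL) {
  panel <- match.arg(panel)
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  lower <- tolower(names(raw))
  pick <- function(canon) {
    if (!is.null(col_map) && canon %in% names(col_map)) {
      return(raw[[col_map[[canon]]]])
    }
    idx <- which(lower %in% .sumstat_dialects[[canon]])
    if (length(idx) == 0) return(NULL)
    raw[[idx[1]]]
  }
  num_or_na <- function(canon) {
    x <- pick(canon)
    if (is.null(x)) rep(NA_real_, nrow(raw)) else as.numeric(x)
  }
  rsid <- pick("rsid")
  p <- pick("p")
  if (is.null(rsid) || is.null(p)) {
    stop("could not locate rsid/p columns in ", path,
         "; supply col_map", call. = FALSE)
  }
  tibble::tibble(
    rsid = as.character(rsid), trait = trait,
    chrom = {x <- pick("chrom"); if (is.null(x)) NA_character_ else as.character(x)},
    pos = {x <- pick("pos"); if (is.null(x)) NA_integer_ else as.integer(x)},
    effect_allele = {x <- pick("effect_allele"); if (is.null(x)) NA_character_ else as.character(x)},
    other_allele = {x <- pick("other_allele"); if (is.null(x)) NA_character_ else as.character(x)},
    beta = num_or_na("beta"),
    se = num_or_na("se"),
    p = as.numeric(p),
    n = num_or_na("n"),
    panel = panel
  )
}

#' Read a probes-x-samples numeric matrix from TSV
#'
#' First column holds feature ids; remaining columns are samples (header row
#' of sample ids). Used for methylation beta-values and miRNA counts.
#'
#' @param path TSV file path.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- as.character(raw[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a probes-x-samples matrix to TSV
#' @param m Matrix with rownames (features) and colnames (samples).
#' @param path Output path.
#' @param id_col Name of the id column in the header.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- tibble::as_tibble(m, rownames = id_col)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a phenotype/covariate table (CSV)
#' @param path CSV path; must contain `sample_id`.
#' @return Tibble, one row per sample.
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot("sample_id" %in% names(ph))
  ph
}

#' Read gene intervals from BED
#'
#' BED is 0-based half-open; the name column is `mirna_id|gene` linking each
#' target-gene interval to the miRNA it is a validated target of.
#'
#' @param path BED file path (3+ columns, tab-separated, no header).
#' @return Tibble `mirna_id, gene, chrom, start0, end0`.
#' @export
read_target_genes_bed <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "start0", "end0", "name"),
    col_types = "ciic", show_col_types = FALSE
  )
  parts <- strsplit(raw$name, "|", fixed = TRUE)
  tibble::tibble(
    mirna_id = vapply(parts, `[`, character(1), 1),
    gene = vapply(parts, function(x) if (length(x) > 1) x[2] else NA_character_, character(1)),
    chrom = raw$chrom, start0 = raw$start0, end0 = raw$end0
  )
}

#' Read an me-QTL reference table
#' @param path TSV with `rsid, snp_chr, snp_pos, cpg, cpg_chr, cpg_pos, fdr`.
#' @return Tibble with those columns plus `cis_trans` from
#'   [classify_cis_trans()].
#' @export
read_meqtl <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  m$cis_trans <- classify_cis_trans(m$snp_chr, m$snp_pos, m$cpg_chr, m$cpg_pos)
  tibble::as_tibble(m)
}

#' Read a miR-eQTM reference table
#' @param path TSV with `cpg, mirna, direction, fdr`.
#' @param fdr_max Retain pairs with `fdr < fdr_max` (default 0.01).
#' @return Tibble of retained pairs.
#' @export
read_eqtm <- function(path, fdr_max = 0.01) {
  e <- readr::read_tsv(path, show_col_types = FALSE)
  tibble::as_tibble(e[e$fdr < fdr_max, , drop = FALSE])
}
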