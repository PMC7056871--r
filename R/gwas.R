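#' Bonferroni threshold from a count of independent tests
#'
#' Family-wise alpha divided by the number of independent tests, where
#' independence is established upstream by LD pruning.
#'
#' @param alpha Family-wise error level in (0, 1].
#' @param m Number of independent tests (positive integer).
#' @return The per-test p-value threshold `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha <= 1)
  if (length(m) != 1 || is.na(m) || m < 1 || m != round(m)) {
    stop("m must be a positive integer count of tests", call. = FALSE)
  }
  alpha / m
}

#' Greedy windowed LD pruning
#'
#' Position-ordered sliding-window pruning: windows of `window_bp` advance by
#' half a window; within each window, while any surviving pair has
#' `r2 > r2_max`, the worst pair (largest r2, lexicographic tie-break on
#' indices) loses its larger-index member. Window passes repeat until no SNP
#' is dropped, so the result is idempotent. Missing pairwise values are
#' treated as r2 = 0 (independent) with a message. Output preserves input
#' order.
#'
#' @param rsids Character vector of SNP ids.
#' @param ld Square symmetric r2 matrix with dimnames covering `rsids`
#'   (diagonal 1).
#' @param r2_max Prune threshold in (0, 1]; pairs strictly above it cannot
#'   both survive a window (default 0.7).
#' @param window_bp Window size in bp (default 250000).
#' @param positions Integer positions aligned with `rsids` (same chromosome
#'   assumed; for multi-chromosome input call per chromosome).
#' @return Character vector of retained rsids, in input order.
#' @export
ld_prune <- function(rsids, ld, r2_max = 0.7, window_bp = 250000L, positions = NULL) {
  stopifnot(r2_max > 0, r2_max <= 1)
  n <- length(rsids)
  if (n <= 1) return(rsids)
  if (is.null(positions)) positions <- seq_len(n)
  miss <- setdiff(rsids, rownames(ld))
  if (length(miss) > 0) {
    message("ld_prune: ", length(miss),
            " SNP(s) missing from the LD matrix treated as independent")
  }
  ord <- order(positions, seq_len(n))
  ids <- rsids[ord]
  pos <- positions[ord]
  alive <- rep(TRUE, n)

  r2_of <- function(a, b) {
    if (a %in% rownames(ld) && b %in% colnames(ld)) ld[a, b] else 0
  }
  prune_window <- function(widx) {
    repeat {
      cur <- widx[alive[widx]]
      if (length(cur) < 2) return()
      pairs <- utils::combn(cur, 2)
      r2 <- mapply(function(i, j) r2_of(ids[i], ids[j]), pairs[1, ], pairs[2, ])
      offending <- which(r2 > r2_max)
      if (length(offending) == 0) return()
      worst <- offending[order(-r2[offending], pairs[1, offending], pairs[2, offending])][1]
      alive[max(pairs[, worst])] <<- FALSE
    }
  }
  repeat {
    before <- sum(alive)
    step <- max(1, floor(window_bp / 2))
    w_start <- min(pos)
    while (w_start <= max(pos)) {
      widx <- which(pos >= w_start & pos < w_start + window_bp)
      if (length(widx) > 1) prune_window(widx)
      w_start <- w_start + step
    }
    if (sum(alive) == before) break
  }
  kept <- ids[alive]
  rsids[rsids %in% kept]
}

#' Harmonize summary-statistic alleles against a catalog
#'
#' Rows whose effect/other alleles are swapped relative to the catalog get
#' their beta sign flipped; strand-ambiguous (A/T, C/G) rows that do not
#' match either orientation are dropped with a message. Rows for SNPs
#' without catalog alleles pass through unchanged.
#'
#' @param sumstats Summary-statistic tibble (see [read_sumstats()]).
#' @param catalog SNP catalog tibble with `site_id`, `a1` (effect), `a2`.
#' @return Harmonized sumstats tibble.
#' @export
harmonize_alleles <- function(sumstats, catalog) {
  if (!all(c("a1", "a2") %in% names(catalog))) return(sumstats)
  ref <- catalog[!is.na(catalog$a1) & !is.na(catalog$a2),
                 c("site_id", "a1", "a2")]
  idx <- match(sumstats$rsid, ref$site_id)
  has <- !is.na(idx) & !is.na(sumstats$effect_allele) & !is.na(sumstats$other_allele)
  ea <- toupper(sumstats$effect_allele)
  oa <- toupper(sumstats$other_allele)
  a1 <- toupper(ref$a1[idx])
  a2 <- toupper(ref$a2[idx])
  same <- has & ea == a1 & oa == a2
  flipped <- has & ea == a2 & oa == a1
  ambiguous_pair <- function(x, y) (x == "A" & y == "T") | (x == "T" & y == "A") |
    (x == "C" & y == "G") | (x == "G" & y == "C")
  mismatch <- has & !same & !flipped
  drop <- mismatch & ambiguous_pair(ea, oa)
  if (any(drop)) {
    message("harmonize_alleles: dropping ", sum(drop),
            " strand-ambiguous mismatched row(s)")
  }
  out <- sumstats
  out$beta[flipped] <- -out$beta[flipped]
  tmp <- out$effect_allele[flipped]
  out$effect_allele[flipped] <- out$other_allele[flipped]
  out$other_allele[flipped] <- tmp
  out[!drop, , drop = FALSE]
}

#' Test annotated SNPs against GWAS summary statistics
#'
#' Inner join of site annotations with summary statistics on rsID; each
#' (SNP, miRNA, trait) row is flagged significant when its p-value is below
#' the Bonferroni threshold of the GWAS's imputation panel. SNPs absent from
#' a trait's GWAS are simply untested for that trait (no row emitted).
#'
#' @param annotations Output of [map_sites_to_regions()] (optionally with
#'   [eqtl_annotations()] rows appended).
#' @param sumstats Summary statistics for one or more traits, with a `panel`
#'   column.
#' @param panel_thresholds Named numeric vector of p-value thresholds per
#'   panel, e.g. `c(hapmap = 2.12e-5, "1000g" = 5.78e-6)`.
#' @param catalog Optional SNP catalog with alleles; triggers
#'   [harmonize_alleles()].
#' @return Association-result tibble (layer `"snp"`), one row per
#'   (rsid, miRNA, trait), with `chrom`/`pos` carried from the annotation.
#' @export
test_gwas_associations <- function(annotations, sumstats, panel_thresholds,
                                   catalog = NULL) {
  dup <- sumstats |>
    dplyr::count(.data$rsid, .data$trait) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate (rsid, trait) rows in summary statistics: ",
         paste(utils::head(paste(dup$rsid, dup$trait, sep = "/"), 10),
               collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(catalog)) sumstats <- harmonize_alleles(sumstats, catalog)
  snp_ann <- annotations[annotations$site_kind == "snp", , drop = FALSE]
  joined <- dplyr::inner_join(
    dplyr::select(snp_ann, "site_id", "chrom", "pos", "mirna_id", "region_class"),
    dplyr::select(sumstats, "rsid", "trait", "beta", "se", "p", "n", "panel"),
    by = c(site_id = "rsid")
  )
  if (nrow(joined) == 0) {
    out <- association_result(character(0), character(0), character(0), "snp",
                              numeric(0), numeric(0), numeric(0), integer(0),
                              numeric(0))
    out$chrom <- character(0); out$pos <- integer(0)
    out$region_class <- character(0)
    return(out)
  }
  thr <- unname(panel_thresholds[joined$panel])
  if (anyNA(thr)) {
    stop("panel_thresholds missing entries for panel(s): ",
         paste(setdiff(unique(joined$panel), names(panel_thresholds)),
               collapse = ", "),
         call. = FALSE)
  }
  out <- association_result(
    feature_id = joined$site_id, mirna_id = joined$mirna_id,
    trait = joined$trait, layer = "snp",
    beta = joined$beta, se = joined$se, p = joined$p, n = joined$n,
    threshold = thr
  )
  out$chrom <- joined$chrom
  out$pos <- joined$pos
  out$region_class <- joined$region_class
  out
}

#' Per-(miRNA, trait) locus summary
#'
#' Groups significant SNP-layer results by (miRNA, trait) and keeps the row
#' with the smallest p-value as the locus representative; p-value ties break
#' on the smaller genomic position. A SNP annotated to several miRNAs
#' represents each of them.
#'
#' @param results SNP-layer association tibble from
#'   [test_gwas_associations()].
#' @return Tibble of locus representatives, one row per (miRNA, trait).
#' @export
summarize_by_mirna <- function(results) {
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0) return(sig)
  sig |>
    dplyr::arrange(.data$p, .data$pos) |>
    dplyr::group_by(.data$mirna_id, .data$trait) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Floor zero p-values for log-scale plotting
#'
#' Significance testing always uses raw p-values; this helper only protects
#' `-log10(p)` displays from infinities.
#'
#' @param p Numeric vector of p-values.
#' @param floor Smallest representable p (default 1e-300).
#' @return p with zeros replaced by `floor`.
#' @export
floor_pvalues <- function(p, floor = 1e-300) {
  p[!is.na(p) & p < floor] <- floor
  p
}

#' Manhattan-plot-ready table
#'
#' @param results SNP-layer association tibble.
#' @return Tibble `chrom, pos, neg_log10_p, mirna_id, trait, significant`.
#' @export
manhattan_table <- function(results) {
  tibble::tibble(
    chrom = results$chrom, pos = results$pos,
    neg_log10_p = -log10(floor_pvalues(results$p)),
    mirna_id = results$mirna_id, trait = results$trait,
    significant = results$significant
  )
}
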