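#' Classify SNP-CpG pairs as cis or trans
#'
#' A pair is cis when both sites lie on the same chromosome no further than
#' 250 kb apart (the boundary at exactly 250,000 bp counts as cis); anything
#' else, including cross-chromosome pairs, is trans.
#'
#' @param snp_chr,snp_pos SNP chromosome labels and 1-based positions.
#' @param cpg_chr,cpg_pos CpG chromosome labels and positions.
#' @param max_bp Cis distance bound (default 250000).
#' @return Character vector of `"cis"`/`"trans"`.
#' @export
classify_cis_trans <- function(snp_chr, snp_pos, cpg_chr, cpg_pos,
                               max_bp = 250000L) {
  if (any(is.na(snp_chr)) || any(is.na(cpg_chr))) {
    stop("unknown chromosome in cis/trans classification", call. = FALSE)
  }
  ifelse(snp_chr == cpg_chr & abs(snp_pos - cpg_pos) <= max_bp,
         "cis", "trans")
}

#' Cross-reference trait-associated SNPs with an me-QTL catalog
#'
#' For every trait-significant SNP-layer result whose rsID appears in the
#' me-QTL reference table, emits one record per SNP-CpG pair carrying the
#' SNP's associated traits and the traits (if any) the EWAS layer found for
#' the partner CpG. Records whose CpG has no trait association are retained
#' but flagged (`cpg_trait_support = FALSE`).
#'
#' @param snp_results SNP-layer association tibble; only `significant` rows
#'   are used.
#' @param meqtl me-QTL tibble (`rsid, cpg, cis_trans`, see [read_meqtl()]).
#' @param cpg_results CpG-layer association tibble; only `significant` rows
#'   contribute CpG traits.
#' @return Tibble `mirna_id, rsid, cpg, cis_trans, snp_traits, cpg_traits,
#'   cpg_trait_support` (trait sets comma-collapsed).
#' @export
crossref_meqtl <- function(snp_results, meqtl, cpg_results = NULL) {
  sig <- snp_results[snp_results$significant, , drop = FALSE]
  if (nrow(sig) == 0 || nrow(meqtl) == 0) {
    return(tibble::tibble(
      mirna_id = character(0), rsid = character(0), cpg = character(0),
      cis_trans = character(0), snp_traits = character(0),
      cpg_traits = character(0), cpg_trait_support = logical(0)
    ))
  }
  snp_traits <- sig |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      mirna_id = paste(sort(unique(.data$mirna_id)), collapse = ","),
      snp_traits = paste(sort(unique(.data$trait)), collapse = ","),
      .groups = "drop"
    )
  cpg_traits <- if (!is.null(cpg_results)) {
    cpg_results[cpg_results$significant, , drop = FALSE] |>
      dplyr::group_by(.data$feature_id) |>
      dplyr::summarise(
        cpg_traits = paste(sort(unique(.data$trait)), collapse = ","),
        .groups = "drop"
      )
  } else {
    tibble::tibble(feature_id = character(0), cpg_traits = character(0))
  }
  meqtl |>
    dplyr::inner_join(snp_traits, by = c(rsid = "feature_id")) |>
    dplyr::left_join(cpg_traits, by = c(cpg = "feature_id")) |>
    dplyr::mutate(
      cpg_trait_support = !is.na(.data$cpg_traits) & nzchar(.data$cpg_traits),
      cpg_traits = dplyr::coalesce(.data$cpg_traits, "")
    ) |>
    dplyr::select("mirna_id", "rsid", "cpg", "cis_trans", "snp_traits",
                  "cpg_traits", "cpg_trait_support")
}

#' Cross-reference trait-associated CpGs with a miR-eQTM catalog
#'
#' Inner join on CpG id between the EWAS layer's significant CpGs and an
#' FDR-filtered miR-eQTM reference; a CpG linked to several miRNAs yields
#' one record per miRNA.
#'
#' @param cpg_results CpG-layer association tibble.
#' @param eqtm miR-eQTM tibble (`cpg, mirna, direction, fdr`), pre-filtered
#'   at FDR < 0.01 (see [read_eqtm()]).
#' @return Tibble `cpg, mirna, direction, cpg_traits`.
#' @export
crossref_eqtm <- function(cpg_results, eqtm) {
  sig <- cpg_results[cpg_results$significant, , drop = FALSE]
  if (nrow(sig) == 0 || nrow(eqtm) == 0) {
    return(tibble::tibble(cpg = character(0), mirna = character(0),
                          direction = numeric(0), cpg_traits = character(0)))
  }
  cpg_traits <- sig |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      cpg_traits = paste(sort(unique(.data$trait)), collapse = ","),
      .groups = "drop"
    )
  eqtm[, intersect(c("cpg", "mirna", "direction"), names(eqtm))] |>
    dplyr::inner_join(cpg_traits, by = c(cpg = "feature_id")) |>
    dplyr::select("cpg", "mirna", dplyr::any_of("direction"), "cpg_traits")
}
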