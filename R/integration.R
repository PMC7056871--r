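#' Build the per-miRNA three-layer evidence matrix
#'
#' One entry per miRNA implicated by the SNP layer (the candidate set).
#' MiRNA ids from all layers are matched on the precursor-level family key
#' ([mirna_family()]). For the CpG and expression layers each miRNA is
#' marked `"supported"` (significant association present), `"null"` (tested,
#' nothing significant) or `"unavailable"` (not tested in that layer: no
#' probes / not well-expressed / phenotype missing) — keeping untested
#' distinct from tested-negative. Prioritization flags (miR-eQTL evidence,
#' relevant-tissue expression, structure change) are external annotations
#' supplied as input, defaulting to `FALSE`.
#'
#' @param snp_results SNP-layer association tibble; significant rows define
#'   each miRNA's SNP trait set and best p-value.
#' @param cpg_results CpG-layer association tibble (with `mirna_id`), or
#'   `NULL` if the layer was not run.
#' @param expr_results Expression-layer association tibble, or `NULL`.
#' @param eqtm Optional [crossref_eqtm()] output; sets `eqtm_support`.
#' @param flags Optional tibble `mirna, eqtl_evidence, tissue_expression,
#'   structure_change` (ids matched on family key).
#' @param cpg_tested,expr_tested Optional character vectors of miRNA ids the
#'   layer actually tested; default: ids appearing in that layer's results.
#' @return Tibble, one row per SNP-layer miRNA family: `mirna`,
#'   `snp_traits`/`cpg_traits`/`expr_traits` (list-columns of trait codes),
#'   `best_snp_p`, `cpg_status`, `expr_status`, `eqtm_support`, and the
#'   three flag columns.
#' @export
build_evidence_matrix <- function(snp_results, cpg_results = NULL,
                                  expr_results = NULL, eqtm = NULL,
                                  flags = NULL, cpg_tested = NULL,
                                  expr_tested = NULL) {
  sig <- snp_results[snp_results$significant, , drop = FALSE]
  sig$family <- mirna_family(sig$mirna_id)
  universe <- sort(unique(sig$family))

  layer_traits <- function(results) {
    if (is.null(results) || nrow(results) == 0) {
      return(tibble::tibble(family = character(0), traits = list()))
    }
    r <- results[results$significant & !is.na(results$mirna_id), , drop = FALSE]
    r$family <- mirna_family(r$mirna_id)
    extra <- setdiff(unique(r$family), universe)
    if (length(extra) > 0) {
      stop("downstream layer contains miRNA(s) absent from the SNP layer: ",
           paste(utils::head(extra, 10), collapse = ", "), call. = FALSE)
    }
    r |>
      dplyr::group_by(.data$family) |>
      dplyr::summarise(traits = list(sort(unique(.data$trait))),
                       .groups = "drop")
  }
  tested_set <- function(results, tested) {
    if (!is.null(tested)) return(unique(mirna_family(tested)))
    if (is.null(results) || nrow(results) == 0) return(character(0))
    unique(mirna_family(stats::na.omit(results$mirna_id)))
  }

  snp_tab <- sig |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      snp_traits = list(sort(unique(.data$trait))),
      best_snp_p = min(.data$p),
      .groups = "drop"
    )
  cpg_tab <- layer_traits(cpg_results)
  expr_tab <- layer_traits(expr_results)
  cpg_avail <- tested_set(cpg_results, cpg_tested)
  expr_avail <- tested_set(expr_results, expr_tested)

  ev <- tibble::tibble(mirna = universe) |>
    dplyr::left_join(dplyr::rename(snp_tab, mirna = "family"), by = "mirna") |>
    dplyr::left_join(dplyr::rename(cpg_tab, mirna = "family",
                                   cpg_traits = "traits"), by = "mirna") |>
    dplyr::left_join(dplyr::rename(expr_tab, mirna = "family",
                                   expr_traits = "traits"), by = "mirna")
  fill_empty <- function(x) lapply(x, function(v) if (is.null(v)) character(0) else v)
  ev$cpg_traits <- fill_empty(ev$cpg_traits)
  ev$expr_traits <- fill_empty(ev$expr_traits)
  status <- function(avail, traits) {
    ifelse(!(ev$mirna %in% avail), "unavailable",
           ifelse(lengths(traits) > 0, "supported", "null"))
  }
  ev$cpg_status <- status(cpg_avail, ev$cpg_traits)
  ev$expr_status <- status(expr_avail, ev$expr_traits)

  eqtm_families <- if (!is.null(eqtm) && nrow(eqtm) > 0) {
    unique(mirna_family(eqtm$mirna))
  } else character(0)
  ev$eqtm_support <- ev$mirna %in% eqtm_families

  for (fl in c("eqtl_evidence", "tissue_expression", "structure_change")) {
    ev[[fl]] <- FALSE
    if (!is.null(flags) && fl %in% names(flags)) {
      idx <- match(ev$mirna, mirna_family(flags$mirna))
      ev[[fl]] <- !is.na(idx) & as.logical(flags[[fl]][idx])
      ev[[fl]][is.na(ev[[fl]])] <- FALSE
    }
  }
  ev
}

#' Select miRNAs supported by all three omics layers
#'
#' The trait-compatibility rule: a miRNA is selected when its SNP trait set
#' is nonempty, at least one CpG-layer trait lies in the SNP trait set, and
#' at least one expression-layer trait lies in the SNP trait set. The
#' CpG-matched and expression-matched traits need not coincide with each
#' other — this is the weakest rule consistent with published multi-omics
#' overlaps, where e.g. a miRNA's CpG matches LDL and its expression matches
#' TC while the SNP layer carries both.
#'
#' @param evidence Output of [build_evidence_matrix()].
#' @return Integration-record tibble: `mirna`, `snp_traits`,
#'   `cpg_shared_traits`, `expr_shared_traits` (list-columns),
#'   `layers_supporting` (comma-collapsed), `selected`, `best_snp_p`, and
#'   the flag columns carried over.
#' @export
select_multiomics <- function(evidence) {
  shared <- function(a, b) mapply(function(x, y) list(intersect(x, y)),
                                  a, b, SIMPLIFY = TRUE)
  cpg_shared <- shared(evidence$cpg_traits, evidence$snp_traits)
  expr_shared <- shared(evidence$expr_traits, evidence$snp_traits)
  layers <- mapply(function(s, cs, es) {
    paste(c("snp"[length(s) > 0], "cpg"[length(cs) > 0],
            "expression"[length(es) > 0]), collapse = ",")
  }, evidence$snp_traits, cpg_shared, expr_shared)
  tibble::tibble(
    mirna = evidence$mirna,
    snp_traits = evidence$snp_traits,
    cpg_shared_traits = cpg_shared,
    expr_shared_traits = expr_shared,
    layers_supporting = layers,
    selected = lengths(evidence$snp_traits) > 0 &
      lengths(cpg_shared) > 0 & lengths(expr_shared) > 0,
    best_snp_p = evidence$best_snp_p,
    eqtm_support = evidence$eqtm_support,
    eqtl_evidence = evidence$eqtl_evidence,
    tissue_expression = evidence$tissue_expression,
    structure_change = evidence$structure_change
  )
}

#' Prioritize selected miRNAs by functional evidence
#'
#' A selected miRNA is prioritized when its miR-eQTL evidence flag is true
#' (the variant is known to change the miRNA's expression). Output is
#' sorted ascending by the best SNP-layer p-value.
#'
#' @param records Output of [select_multiomics()].
#' @return The records with a `prioritized` column, sorted by `best_snp_p`.
#' @export
prioritize <- function(records) {
  records$prioritized <- records$selected & records$eqtl_evidence
  dplyr::arrange(records, .data$best_snp_p)
}

#' Write the integration report
#'
#' Emits a machine-readable JSON report (per-miRNA evidence, thresholds,
#' per-stage counts, run metadata) and a TSV of the integration records
#' (list-columns comma-collapsed). Re-running on identical inputs produces
#' byte-identical files.
#'
#' @param records Output of [prioritize()] (or [select_multiomics()]).
#' @param evidence Output of [build_evidence_matrix()].
#' @param json_path,tsv_path Output paths.
#' @param meta Named list of run metadata (seed, thresholds, config hash...).
#' @return Invisibly, the list written to JSON.
#' @export
write_report <- function(records, evidence, json_path, tsv_path, meta = list()) {
  flat <- records
  for (col in c("snp_traits", "cpg_shared_traits", "expr_shared_traits")) {
    flat[[col]] <- vapply(flat[[col]], paste, character(1), collapse = ",")
  }
  readr::write_tsv(flat, tsv_path)
  report <- list(
    meta = meta,
    counts = list(
      snp_layer_mirnas = nrow(evidence),
      cpg_tested = sum(evidence$cpg_status != "unavailable"),
      cpg_supported = sum(evidence$cpg_status == "supported"),
      expr_tested = sum(evidence$expr_status != "unavailable"),
      expr_supported = sum(evidence$expr_status == "supported"),
      selected = sum(records$selected),
      prioritized = if ("prioritized" %in% names(records))
        sum(records$prioritized) else NA_integer_
    ),
    mirnas = lapply(seq_len(nrow(records)), function(i) {
      list(
        mirna = records$mirna[i],
        snp_traits = records$snp_traits[[i]],
        cpg_shared_traits = records$cpg_shared_traits[[i]],
        expr_shared_traits = records$expr_shared_traits[[i]],
        selected = records$selected[i],
        prioritized = if ("prioritized" %in% names(records))
          records$prioritized[i] else NA
      )
    })
  )
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(report)
}
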