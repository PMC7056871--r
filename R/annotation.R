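#' Build miRNA-related genomic regions
#'
#' For each precursor miRNA, emits three classes of region: a symmetric,
#' strand-agnostic flank window (precursor extended by `flank_bp` on both
#' sides, clipped at the chromosome start), the precursor interval itself,
#' and one region per mature interval. Coordinates in the returned table are
#' 0-based half-open (`start0`, `end0`); input annotation coordinates are
#' 1-based inclusive as read from GFF3.
#'
#' Records whose interval is malformed (start > end) are dropped with a
#' warning rather than aborting the run.
#'
#' @param annotation A miRNA annotation as returned by [read_mirna_gff()] or
#'   [simulate_cohort()]: a list with tibbles `precursors` (`mirna_id`,
#'   `chrom`, `start`, `end`, `strand`) and `matures` (`mature_id`,
#'   `mirna_id`, `chrom`, `start`, `end`, `strand`), 1-based inclusive.
#' @param flank_bp Non-negative flank size in bp (default 2000, the +/-2kb
#'   regulatory window).
#' @return Tibble with columns `mirna_id`, `region_class` (`flank`,
#'   `precursor`, `mature`), `mature_id` (NA except for mature regions),
#'   `chrom`, `start0`, `end0`, `strand`.
#' @export
build_mirna_regions <- function(annotation, flank_bp = 2000L) {
  stopifnot(flank_bp >= 0)
  prec <- annotation$precursors
  mat <- annotation$matures
  bad <- prec$start > prec$end
  if (any(bad)) {
    warning("dropping ", sum(bad), " precursor record(s) with malformed intervals: ",
            paste(prec$mirna_id[bad], collapse = ", "))
    prec <- prec[!bad, , drop = FALSE]
    mat <- mat[mat$mirna_id %in% prec$mirna_id, , drop = FALSE]
  }
  if (!is.null(mat) && nrow(mat) > 0) {
    badm <- mat$start > mat$end
    if (any(badm)) {
      warning("dropping ", sum(badm), " mature record(s) with malformed intervals: ",
              paste(mat$mature_id[badm], collapse = ", "))
      mat <- mat[!badm, , drop = FALSE]
    }
  }
  p0 <- to0(prec$start, prec$end)
  flank <- tibble::tibble(
    mirna_id = prec$mirna_id, region_class = "flank", mature_id = NA_character_,
    chrom = prec$chrom,
    start0 = pmax(p0$start0 - as.integer(flank_bp), 0L),
    end0 = p0$end0 + as.integer(flank_bp),
    strand = prec$strand
  )
  precursor <- tibble::tibble(
    mirna_id = prec$mirna_id, region_class = "precursor", mature_id = NA_character_,
    chrom = prec$chrom, start0 = p0$start0, end0 = p0$end0, strand = prec$strand
  )
  out <- dplyr::bind_rows(flank, precursor)
  if (!is.null(mat) && nrow(mat) > 0) {
    m0 <- to0(mat$start, mat$end)
    mature <- tibble::tibble(
      mirna_id = mat$mirna_id, region_class = "mature", mature_id = mat$mature_id,
      chrom = mat$chrom, start0 = m0$start0, end0 = m0$end0, strand = mat$strand
    )
    out <- dplyr::bind_rows(out, mature)
  }
  out
}

#' Map SNPs/CpGs into miRNA regions
#'
#' A site at 1-based position `pos` maps into a region iff
#' `start0 <= pos - 1 < end0` (half-open: a site on a flank's outer end
#' boundary is excluded, on its start boundary included). Each site receives
#' the most specific region class per miRNA (mature > precursor > flank) and
#' a signed distance to the precursor (0 inside; negative upstream with
#' respect to the precursor strand). Sites hitting no region are omitted.
#'
#' @param sites Tibble with `site_id`, `site_kind` (`snp`/`cpg`), `chrom`,
#'   `pos` (1-based), optionally `source`.
#' @param regions Output of [build_mirna_regions()].
#' @return Tibble with `site_id`, `site_kind`, `chrom`, `pos`, `mirna_id`,
#'   `region_class`, `distance` (bp to precursor, signed).
#' @export
map_sites_to_regions <- function(sites, regions) {
  if (nrow(sites) == 0 || nrow(regions) == 0) {
    return(tibble::tibble(
      site_id = character(0), site_kind = character(0), chrom = character(0),
      pos = integer(0), mirna_id = character(0), region_class = character(0),
      distance = integer(0)
    ))
  }
  shared <- intersect(unique(sites$chrom), unique(regions$chrom))
  if (length(shared) == 0) {
    stop("no shared chromosome labels between sites and regions; sites use {",
         paste(utils::head(unique(sites$chrom), 5), collapse = ", "),
         "} but regions use {",
         paste(utils::head(unique(regions$chrom), 5), collapse = ", "), "}",
         call. = FALSE)
  }
  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(start = sites$pos, width = 1L)
  )
  region_gr <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(start = regions$start0 + 1L, end = regions$end0)
  )
  hits <- GenomicRanges::findOverlaps(site_gr, region_gr)
  if (length(hits) == 0) {
    return(map_sites_to_regions(sites[0, , drop = FALSE], regions))
  }
  ann <- tibble::tibble(
    site_id = sites$site_id[S4Vectors::queryHits(hits)],
    site_kind = sites$site_kind[S4Vectors::queryHits(hits)],
    chrom = sites$chrom[S4Vectors::queryHits(hits)],
    pos = sites$pos[S4Vectors::queryHits(hits)],
    mirna_id = regions$mirna_id[S4Vectors::subjectHits(hits)],
    region_class = regions$region_class[S4Vectors::subjectHits(hits)]
  )
  class_rank <- c(mature = 3L, precursor = 2L, flank = 1L)
  ann <- ann |>
    dplyr::mutate(.rank = class_rank[.data$region_class]) |>
    dplyr::group_by(.data$site_id, .data$mirna_id) |>
    dplyr::slice_max(.data$.rank, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-".rank")
  prec <- regions[regions$region_class == "precursor", , drop = FALSE]
  ann <- dplyr::left_join(
    ann,
    tibble::tibble(mirna_id = prec$mirna_id, .ps = prec$start0,
                   .pe = prec$end0, .strand = prec$strand),
    by = "mirna_id"
  )
  pos0 <- ann$pos - 1L
  d <- integer(nrow(ann))
  known <- !is.na(ann$.ps)
  up <- known & pos0 < ann$.ps
  down <- known & pos0 >= ann$.pe
  d[up] <- (pos0 - ann$.ps)[up]
  d[down] <- (pos0 - (ann$.pe - 1L))[down]
  minus <- known & !is.na(ann$.strand) & ann$.strand == "-"
  d[minus] <- -d[minus]
  d[!known] <- NA_integer_ # regions without a precursor (e.g. gene intervals)
  ann$distance <- d
  dplyr::arrange(
    dplyr::select(ann, -".ps", -".pe", -".strand"),
    .data$chrom, .data$pos, .data$mirna_id
  )
}

#' Annotate an eQTL SNP catalog
#'
#' miR-eQTL SNPs are assigned to their target miRNA by the source catalog,
#' not by genomic proximity (most reported cis-miR-eQTLs are distal
#' regulators); they receive region class `eqtl` and no distance.
#'
#' @param eqtl_snps Tibble with `site_id`, `chrom`, `pos`, `mirna_id`.
#' @return Annotation tibble in the [map_sites_to_regions()] layout.
#' @export
eqtl_annotations <- function(eqtl_snps) {
  tibble::tibble(
    site_id = eqtl_snps$site_id, site_kind = "snp",
    chrom = eqtl_snps$chrom, pos = eqtl_snps$pos,
    mirna_id = eqtl_snps$mirna_id, region_class = "eqtl",
    distance = NA_integer_
  )
}

#' Merge two SNP catalogs by rsID
#'
#' Union keyed on rsID: a SNP present in both catalogs appears once, carrying
#' both source tags (comma-separated), so `|A union B| = |A| + |B| - |A
#' intersect B|`. Conflicting genomic positions for one rsID abort with the
#' offending ids.
#'
#' @param region_snps,eqtl_snps Tibbles with `site_id`, `chrom`, `pos`,
#'   optional `a1`, `a2`, `source`, `mirna_id`.
#' @return Merged catalog tibble, one row per unique rsID.
#' @export
merge_snp_catalogs <- function(region_snps, eqtl_snps) {
  both <- dplyr::bind_rows(region_snps, eqtl_snps)
  conflict <- both |>
    dplyr::distinct(.data$site_id, .data$chrom, .data$pos) |>
    dplyr::count(.data$site_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflict) > 0) {
    stop("conflicting positions for rsID(s): ",
         paste(utils::head(conflict$site_id, 10), collapse = ", "),
         call. = FALSE)
  }
  both |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      site_kind = dplyr::first(.data$site_kind),
      chrom = dplyr::first(.data$chrom),
      pos = dplyr::first(.data$pos),
      a1 = if ("a1" %in% names(both)) dplyr::first(stats::na.omit(.data$a1)) else NA_character_,
      a2 = if ("a2" %in% names(both)) dplyr::first(stats::na.omit(.data$a2)) else NA_character_,
      source = paste(sort(unique(stats::na.omit(.data$source))), collapse = ","),
      .groups = "drop"
    )
}

#' Write a site annotation table to TSV
#'
#' Columns: `site_id, site_kind, chrom, pos, mirna_id, region_class,
#' distance`, positions 1-based.
#'
#' @param annotations Output of [map_sites_to_regions()].
#' @param path Output file path.
#' @export
write_annotation <- function(annotations, path) {
  readr::write_tsv(annotations, path)
  invisible(path)
}
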