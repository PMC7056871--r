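#' @importFrom rlang .data
#' @importFrom stats pnorm pt qnorm rnorm rbinom rpois runif setNames
#'   complete.cases lm glm coef vcov var sd median quantile binomial isoreg
#'   plogis qlogis
#' @importFrom utils head
NULL

# 1-based inclusive -> 0-based half-open and back. All internal interval
# arithmetic is 0-based half-open; conversion happens exactly once at I/O.
to0 <- function(start1, end1) list(start0 = start1 - 1L, end0 = end1)
to1 <- function(start0, end0) list(start1 = start0 + 1L, end1 = end0)

#' Collapse a mature/precursor miRNA id to its precursor-level family key
#'
#' Mature arms (`-3p`/`-5p`) and the `hsa-` prefix are stripped and the id is
#' lower-cased, so `miR-148a-3p`, `hsa-miR-148a` and `mir-148a` all map to
#' `mir-148a`. Used to match miRNAs across the SNP, CpG and expression
#' layers, which mix precursor and mature naming.
#'
#' @param id Character vector of miRNA ids.
#' @return Character vector of family keys.
#' @export
mirna_family <- function(id) {
  key <- tolower(id)
  key <- sub("^hsa-", "", key)
  key <- sub("-(3p|5p)$", "", key)
  key
}

#' Construct a unified association-result table
#'
#' The common record shared by the SNP, CpG and expression layers: one row
#' per (feature, miRNA, trait) with effect size, standard error, p-value,
#' sample size and a significance flag taken at the layer's threshold.
#'
#' @param feature_id rsID, CpG probe id, or mature miRNA id.
#' @param mirna_id Annotated miRNA id (precursor or mature).
#' @param trait Trait code.
#' @param layer `"snp"`, `"cpg"` or `"expression"`.
#' @param beta,se,p,n Effect estimate, standard error, p-value, sample size.
#' @param threshold Significance threshold applied to `p`.
#' @param note Optional free-text note (e.g. fit fallbacks).
#' @return A tibble with a `significant` logical column (`p < threshold`).
#' @export
association_result <- function(feature_id, mirna_id, trait, layer,
                               beta, se, p, n, threshold, note = NA_character_) {
  stopifnot(layer %in% c("snp", "cpg", "expression"))
  tibble::tibble(
    feature_id = as.character(feature_id),
    mirna_id = as.character(mirna_id),
    trait = as.character(trait),
    layer = layer,
    beta = as.numeric(beta),
    se = as.numeric(se),
    p = as.numeric(p),
    n = as.integer(n),
    threshold = as.numeric(threshold),
    significant = !is.na(p) & p < threshold,
    note = as.character(note)
  )
}

# two-sided Wald p from an estimate and its standard error (normal reference)
wald_p <- function(beta, se) 2 * pnorm(-abs(beta / se))
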