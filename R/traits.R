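#' Cardiometabolic trait vocabulary
#'
#' The 18 GWAS trait codes studied by the pipeline, partitioned into four
#' groups (anthropometric, glycemic, lipid, cardiovascular). `CHD` is an
#' additional disease-prevalence code used only by the plasma expression
#' layer (the GWAS layer uses `CAD`); it belongs to the cardiovascular group.
#'
#' @return Character vector of trait codes.
#' @export
trait_vocabulary <- function() {
  unname(unlist(trait_groups()))
}

#' Trait groups
#'
#' @param include_chd Include the expression-layer disease code `CHD` in the
#'   cardiovascular group (default `TRUE`).
#' @return Named list of character vectors partitioning the trait codes.
#' @export
trait_groups <- function(include_chd = TRUE) {
  g <- list(
    anthropometric = c("BMI", "WHR", "WC"),
    glycemic = c("FG", "G2H", "FI", "Pro-Ins", "HbA1c", "HOMA-IR", "HOMA-B", "T2D"),
    lipid = c("LDL", "HDL", "TC", "TG"),
    cardiovascular = c("CAD", "DBP", "SBP")
  )
  if (include_chd) g$cardiovascular <- c(g$cardiovascular, "CHD")
  g
}

#' Group membership of a trait
#' @param trait Trait code.
#' @return One of `"anthropometric"`, `"glycemic"`, `"lipid"`, `"cardiovascular"`.
#' @export
trait_group <- function(trait) {
  groups <- trait_groups()
  hit <- vapply(groups, function(g) trait %in% g, logical(1))
  if (!any(hit)) {
    stop("unknown trait code: ", trait, call. = FALSE)
  }
  names(groups)[hit][1]
}

#' Disease (prevalence) traits modelled with a binomial link
#' @return Character vector.
#' @export
disease_traits <- function() c("T2D", "CHD")

#' Covariate specification for a trait
#'
#' Returns the fixed covariates and random grouping factors used when testing
#' a trait in the methylation (EWAS) or plasma expression layer. The base set
#' is age, sex and current smoking; the methylation layer adds blood cell
#' count fractions (monocytes, granulocytes, lymphocytes) and a technical
#' batch random intercept. Group-specific additions: anthropometric traits
#' adjust WC and WHR (but not BMI itself) for BMI; glycemic traits add BMI
#' and diabetic medication; lipid traits add BMI and lipid-lowering
#' medication; cardiovascular traits add BMI, blood-pressure-lowering and
#' lipid-lowering medication.
#'
#' @param trait Trait code from [trait_vocabulary()].
#' @param layer `"cpg"` (methylation EWAS) or `"expression"`.
#' @return List with elements `trait`, `group`, `fixed` (character vector of
#'   covariate column names) and `random` (character vector of grouping
#'   factors, possibly empty).
#' @export
covariates_for_trait <- function(trait, layer = c("cpg", "expression")) {
  layer <- match.arg(layer)
  group <- trait_group(trait)
  fixed <- c("age", "sex", "current_smoking")
  if (layer == "cpg") {
    fixed <- c(fixed, "monocytes", "granulocytes", "lymphocytes")
  }
  extra <- switch(group,
    anthropometric = if (trait %in% c("WC", "WHR")) "bmi" else character(0),
    glycemic = c("bmi", "diabetic_med"),
    lipid = c("bmi", "lipid_med"),
    cardiovascular = c("bmi", "bp_med", "lipid_med")
  )
  # a trait never adjusts for itself
  extra <- setdiff(extra, tolower(trait))
  list(
    trait = trait,
    group = group,
    fixed = c(fixed, extra),
    random = if (layer == "cpg") "batch" else character(0)
  )
}
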