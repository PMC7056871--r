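#' Fit one CpG ~ trait mixed model
#'
#' Models methylation beta-values as the dependent variable:
#' `methylation ~ trait + fixed covariates + (1 | batch)`, fitted by
#' restricted maximum likelihood. When the batch variance estimate is
#' degenerate (singular fit), the model falls back to ordinary least squares
#' with batch as a fixed factor, and the fallback is recorded in the result's
#' `note`. The trait coefficient, its standard error and a two-sided Wald
#' p-value (normal reference) are returned.
#'
#' @param probe_values Numeric vector of beta-values, one per sample.
#' @param trait_values Numeric vector of trait values (same order).
#' @param covariates Data frame of fixed covariates (same order); may have
#'   zero columns.
#' @param batch Factor/character vector of technical batch labels.
#' @param min_n Minimum complete-case sample size (default 30).
#' @return One-row tibble: `beta, se, p, n, method` (`"lmm"` or
#'   `"ols_fallback"`).
#' @export
fit_cpg_trait_model <- function(probe_values, trait_values, covariates = NULL,
                                batch = NULL, min_n = 30L) {
  if (is.null(covariates)) covariates <- data.frame(row.names = seq_along(probe_values))
  dat <- data.frame(.y = probe_values, .trait = trait_values, covariates,
                    check.names = TRUE)
  if (!is.null(batch)) dat$.batch <- factor(batch)
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  if (nrow(dat) < min_n) {
    stop("fewer than ", min_n, " complete-case samples", call. = FALSE)
  }
  if (stats::sd(dat$.y) == 0 || stats::sd(dat$.trait) == 0) {
    stop("degenerate input: constant probe or trait", call. = FALSE)
  }
  cov_names <- setdiff(names(dat), c(".y", ".trait", ".batch"))
  fixed_rhs <- paste(c(".trait", cov_names), collapse = " + ")
  X <- stats::model.matrix(
    stats::as.formula(paste("~", fixed_rhs)), data = dat
  )
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("singular design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  use_lmm <- !is.null(batch) && length(unique(dat$.batch)) > 1
  method <- "ols"
  fit <- NULL
  if (use_lmm) {
    form <- stats::as.formula(paste(".y ~", fixed_rhs, "+ (1 | .batch)"))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = dat, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    ))
    if (lme4::isSingular(fit, tol = 1e-5)) {
      fit <- NULL
      method <- "ols_fallback"
    } else {
      method <- "lmm"
    }
  }
  if (is.null(fit)) {
    rhs <- fixed_rhs
    if (use_lmm || (!is.null(batch) && length(unique(dat$.batch)) > 1)) {
      rhs <- paste(rhs, "+ .batch")
    }
    fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
  }
  est <- if (inherits(fit, "merMod")) lme4::fixef(fit)[".trait"] else stats::coef(fit)[".trait"]
  se <- sqrt(diag(as.matrix(stats::vcov(fit)))[".trait"])
  # Wald test with a t reference on the residual df (normal reference is
  # anticonservative at cohort-scale n)
  p <- 2 * stats::pt(-abs(est / se), df = stats::df.residual(fit))
  tibble::tibble(
    beta = unname(est), se = unname(se), p = unname(p),
    n = nrow(dat), method = method
  )
}

#' Candidate-based EWAS over miRNA-annotated CpGs
#'
#' Fits [fit_cpg_trait_model()] for every (candidate probe, trait) pair using
#' the covariate ledger of [covariates_for_trait()] (complete cases per fit).
#' Significance is nominal, p < 0.05, as appropriate for a candidate-based
#' stage. Probe/trait fits that error (degenerate input, too few samples)
#' are skipped and counted in the attached log.
#'
#' @param meth Methylation matrix, probes x samples (beta-values in `[0,1]`),
#'   with dimnames.
#' @param phenotypes Phenotype tibble with `sample_id`, covariate columns and
#'   one column per tested trait; technical batch in `batch`.
#' @param probes Character vector of candidate probe ids (subset of
#'   rownames).
#' @param traits Character vector of trait codes.
#' @param annotations Optional CpG annotation table (from
#'   [map_sites_to_regions()]) used to attach `mirna_id`s to each probe.
#' @param alpha Nominal significance level (default 0.05).
#' @return Association-result tibble (layer `"cpg"`); attribute `ewas_log`
#'   holds per-fit sample sizes, fallback counts and skips.
#' @export
run_ewas <- function(meth, phenotypes, probes, traits, annotations = NULL,
                     alpha = 0.05) {
  probes <- intersect(probes, rownames(meth))
  if (length(probes) == 0) {
    out <- association_result(character(0), character(0), character(0), "cpg",
                              numeric(0), numeric(0), numeric(0), integer(0),
                              numeric(0))
    attr(out, "ewas_log") <- list(n_fits = 0L, n_fallback = 0L, n_skipped = 0L)
    return(out)
  }
  shared <- intersect(colnames(meth), phenotypes$sample_id)
  if (length(shared) == 0) {
    stop("no overlapping samples between methylation matrix and phenotypes",
         call. = FALSE)
  }
  ph <- phenotypes[match(shared, phenotypes$sample_id), , drop = FALSE]
  meth <- meth[, shared, drop = FALSE]

  rows <- list()
  n_fallback <- 0L
  n_skipped <- 0L
  for (trait in traits) {
    spec <- covariates_for_trait(trait, layer = "cpg")
    covs <- ph[, intersect(spec$fixed, names(ph)), drop = FALSE]
    tvals <- ph[[trait]]
    if (is.null(tvals)) {
      n_skipped <- n_skipped + length(probes)
      next
    }
    for (probe in probes) {
      res <- tryCatch(
        fit_cpg_trait_model(meth[probe, ], tvals, as.data.frame(covs),
                            batch = ph$batch),
        error = function(e) NULL
      )
      if (is.null(res)) {
        n_skipped <- n_skipped + 1L
        next
      }
      if (res$method == "ols_fallback") n_fallback <- n_fallback + 1L
      rows[[length(rows) + 1L]] <- association_result(
        feature_id = probe, mirna_id = NA_character_, trait = trait,
        layer = "cpg", beta = res$beta, se = res$se, p = res$p, n = res$n,
        threshold = alpha, note = res$method
      )
    }
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    association_result(character(0), character(0), character(0), "cpg",
                       numeric(0), numeric(0), numeric(0), integer(0),
                       numeric(0))
  if (!is.null(annotations) && nrow(out) > 0) {
    ann <- annotations[annotations$site_kind == "cpg",
                       c("site_id", "mirna_id"), drop = FALSE]
    out <- out |>
      dplyr::select(-"mirna_id") |>
      dplyr::left_join(ann, by = c(feature_id = "site_id"),
                       relationship = "many-to-many") |>
      dplyr::relocate("mirna_id", .after = "feature_id")
  }
  attr(out, "ewas_log") <- list(
    n_fits = nrow(out), n_fallback = n_fallback, n_skipped = n_skipped,
    n_samples = length(shared)
  )
  out
}
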