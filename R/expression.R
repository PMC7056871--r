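#' Counts per million
#'
#' @param counts Non-negative integer matrix, miRNAs x samples.
#' @return CPM matrix: each column rescaled to sum to 1e6.
#' @export
cpm <- function(counts) {
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    stop("all-zero sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
  }
  sweep(counts, 2, totals, "/") * 1e6
}

#' Log2 counts per million
#'
#' `log2(CPM + 1)` with a pseudocount of 1, so zero counts map to 0 on the
#' log2-CPM scale (consistent with an expression floor of 1.0 log2-CPM being
#' meaningful). Per-sample CPM columns sum to 1e6 before the pseudocount.
#'
#' @inheritParams cpm
#' @return log2-CPM matrix.
#' @export
cpm_log2 <- function(counts) {
  log2(cpm(counts) + 1)
}

#' Antitonic mean-SD fit and the lower limit of quantification
#'
#' Fits a non-increasing curve SD = f(mean) by antitonic regression (isotonic
#' regression of the negated SDs on the means), lightly smoothed by a short
#' running mean with monotonicity re-imposed, and returns the smallest mean
#' `m*` whose fitted SD falls to or below the cut `c`. By default `c` is the
#' midpoint of the fitted curve's range, a scale-free rule. Low-expression
#' miRNAs have noisy, high SDs; the LLOQ marks where the mean-SD profile has
#' decayed halfway to its stable floor.
#'
#' @param means,sds Per-miRNA means and SDs of log2-CPM (equal length,
#'   >= 10 finite points).
#' @param cut Absolute SD cut `c`; `NULL` (default) uses the midpoint of the
#'   fitted range.
#' @param smooth_k Running-mean window (odd, default 5); 1 disables
#'   smoothing.
#' @return List with `lloq` (scalar mean, on the log2-CPM scale), `cut`,
#'   `fit` (tibble `mean`, `sd_fit` sorted by mean), and `degenerate`
#'   (logical).
#' @export
fit_lloq <- function(means, sds, cut = NULL, smooth_k = 5L) {
  ok <- is.finite(means) & is.finite(sds)
  means <- means[ok]
  sds <- sds[ok]
  if (length(means) < 10) {
    stop("fit_lloq needs at least 10 miRNAs with finite mean and SD",
         call. = FALSE)
  }
  ord <- order(means)
  x <- means[ord]
  y <- sds[ord]
  # antitonic: isotonic regression on the negated response
  iso <- stats::isoreg(x, -y)
  f <- -iso$yf
  if (smooth_k > 1) {
    k <- min(as.integer(smooth_k), length(f))
    if (k %% 2 == 0) k <- k - 1L
    if (k > 1) {
      sm <- stats::filter(f, rep(1 / k, k), sides = 2)
      f <- ifelse(is.na(sm), f, as.numeric(sm))
      f <- rev(cummax(rev(f))) # re-impose non-increasing shape
    }
  }
  rng <- range(f)
  if (diff(rng) == 0) {
    message("LLOQ degenerate: flat SD profile; returning minimum mean")
    return(list(lloq = min(x), cut = rng[1],
                fit = tibble::tibble(mean = x, sd_fit = f), degenerate = TRUE))
  }
  if (is.null(cut)) cut <- mean(rng)
  idx <- which(f <= cut)
  lloq <- if (length(idx) == 0) max(x) else x[min(idx)]
  list(lloq = lloq, cut = cut,
       fit = tibble::tibble(mean = x, sd_fit = f), degenerate = FALSE)
}

#' Expression floor filter
#'
#' miRNAs whose mean log2-CPM falls below the floor are flagged as not
#' expressed and removed before LLOQ-based selection.
#'
#' @param log2cpm log2-CPM matrix.
#' @param floor Expression floor on the log2-CPM scale (default 1.0).
#' @return Character vector of miRNA ids at or above the floor.
#' @export
expressed_mirnas <- function(log2cpm, floor = 1.0) {
  rownames(log2cpm)[rowMeans(log2cpm) >= floor]
}

#' Well-expressed miRNA selection
#'
#' A miRNA is well expressed when strictly more than `min_frac` of its
#' samples lie strictly above the LLOQ (a miRNA with exactly 50% of samples
#' above is excluded).
#'
#' @param log2cpm log2-CPM matrix.
#' @param lloq LLOQ on the log2-CPM scale.
#' @param min_frac Required fraction of samples above LLOQ (default 0.5).
#' @return Character vector of well-expressed miRNA ids.
#' @export
well_expressed <- function(log2cpm, lloq, min_frac = 0.5) {
  stopifnot(is.finite(lloq))
  frac <- rowMeans(log2cpm > lloq)
  rownames(log2cpm)[frac > min_frac]
}

#' Normalize and filter a miRNA count matrix
#'
#' Full expression QC: log2-CPM transform, per-miRNA mean/SD, expression
#' floor, antitonic LLOQ fit (housekeeping probes excluded from the fit) and
#' well-expressed selection (floor filter applied first, then the LLOQ
#' rule).
#'
#' @param counts Count matrix, miRNAs x samples.
#' @param housekeeping Character vector of housekeeping probe ids; carried
#'   through normalization but excluded from LLOQ fitting and association
#'   testing.
#' @param expr_floor Expression floor, log2-CPM (default 1.0).
#' @param lloq_frac `min_frac` for [well_expressed()] (default 0.5).
#' @param lloq_cut Optional absolute SD cut for [fit_lloq()].
#' @return List: `log2cpm`, `qc` (tibble `mirna_id, mean, sd, expressed,
#'   well_expressed, housekeeping`), `lloq`, `lloq_fit`, `well_expressed`
#'   (ids, never housekeeping).
#' @export
normalize_expression <- function(counts, housekeeping = character(0),
                                 expr_floor = 1.0, lloq_frac = 0.5,
                                 lloq_cut = NULL) {
  lc <- cpm_log2(counts)
  means <- rowMeans(lc)
  sds <- apply(lc, 1, stats::sd)
  is_hk <- rownames(lc) %in% housekeeping
  fit <- fit_lloq(means[!is_hk], sds[!is_hk], cut = lloq_cut)
  expressed <- expressed_mirnas(lc, floor = expr_floor)
  we <- well_expressed(lc[expressed[!(expressed %in% housekeeping)], ,
                          drop = FALSE],
                       fit$lloq, min_frac = lloq_frac)
  qc <- tibble::tibble(
    mirna_id = rownames(lc), mean = means, sd = sds,
    expressed = rownames(lc) %in% expressed,
    well_expressed = rownames(lc) %in% we,
    housekeeping = is_hk
  )
  list(log2cpm = lc, qc = qc, lloq = fit$lloq, lloq_fit = fit,
       well_expressed = we)
}

#' Test one miRNA's plasma expression against a trait
#'
#' The cardiometabolic trait is the dependent variable and the miRNA's
#' log2-CPM the explanatory variable. Continuous traits use a linear model;
#' disease-prevalence traits (T2D, CHD) use a binomial (logistic) model, so
#' the returned coefficient is on the log-odds scale. Covariates follow
#' [covariates_for_trait()] with the expression-layer base set (age, sex,
#' current smoking). Complete separation in the logistic fit yields a
#' flagged result with missing p.
#'
#' @param mirna_values Numeric vector, one log2-CPM value per sample.
#' @param trait Trait code.
#' @param phenotypes Phenotype tibble (rows aligned with `mirna_values`)
#'   containing the trait column and covariates.
#' @param mirna_id Id recorded in the result.
#' @param alpha Nominal significance level (default 0.05).
#' @return One-row association-result tibble (layer `"expression"`).
#' @export
test_expression_association <- function(mirna_values, trait, phenotypes,
                                        mirna_id = NA_character_,
                                        alpha = 0.05) {
  spec <- covariates_for_trait(trait, layer = "expression")
  covs <- phenotypes[, intersect(spec$fixed, names(phenotypes)), drop = FALSE]
  dat <- data.frame(.y = phenotypes[[trait]], .mirna = mirna_values,
                    as.data.frame(covs))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  rhs <- paste(c(".mirna", setdiff(names(dat), c(".y", ".mirna"))),
               collapse = " + ")
  form <- stats::as.formula(paste(".y ~", rhs))
  note <- NA_character_
  if (trait %in% disease_traits()) {
    fit <- suppressWarnings(stats::glm(form, data = dat, family = stats::binomial()))
    mu <- stats::fitted(fit)
    separated <- !fit$converged || any(mu < 1e-8) || any(mu > 1 - 1e-8)
    est <- stats::coef(fit)[".mirna"]
    se <- sqrt(diag(stats::vcov(fit))[".mirna"])
    if (separated) {
      message("test_expression_association: separation in logistic fit for ",
              mirna_id, "/", trait)
      return(association_result(mirna_id, mirna_id, trait, "expression",
                                est, se, NA_real_, nrow(dat), alpha,
                                note = "separation"))
    }
    p <- wald_p(est, se)
  } else {
    fit <- stats::lm(form, data = dat)
    est <- stats::coef(fit)[".mirna"]
    se <- sqrt(diag(stats::vcov(fit))[".mirna"])
    # t reference on residual df for the linear model
    p <- 2 * stats::pt(-abs(est / se), df = stats::df.residual(fit))
  }
  association_result(mirna_id, mirna_id, trait, "expression",
                     est, se, p, nrow(dat), alpha, note = note)
}

#' Candidate-based expression association scan
#'
#' Tests each well-expressed candidate miRNA against each trait for which
#' the phenotype table has data.
#'
#' @param log2cpm log2-CPM matrix (miRNAs x samples).
#' @param phenotypes Phenotype tibble with `sample_id`.
#' @param mirnas Candidate mature miRNA ids (rows of `log2cpm`).
#' @param traits Trait codes to test.
#' @param alpha Nominal level (default 0.05).
#' @return Association-result tibble (layer `"expression"`).
#' @export
run_expression_assoc <- function(log2cpm, phenotypes, mirnas, traits,
                                 alpha = 0.05) {
  mirnas <- intersect(mirnas, rownames(log2cpm))
  shared <- intersect(colnames(log2cpm), phenotypes$sample_id)
  if (length(shared) == 0) {
    stop("no overlapping samples between expression matrix and phenotypes",
         call. = FALSE)
  }
  ph <- phenotypes[match(shared, phenotypes$sample_id), , drop = FALSE]
  rows <- list()
  for (trait in intersect(traits, names(ph))) {
    for (m in mirnas) {
      rows[[length(rows) + 1L]] <- test_expression_association(
        log2cpm[m, shared], trait, ph, mirna_id = m, alpha = alpha
      )
    }
  }
  if (length(rows) == 0) {
    return(association_result(character(0), character(0), character(0),
                              "expression", numeric(0), numeric(0),
                              numeric(0), integer(0), numeric(0)))
  }
  dplyr::bind_rows(rows)
}

#' Target-gene SNP lookup
#'
#' Reuses the annotation and GWAS stages on validated target-gene intervals:
#' SNPs falling in a miRNA's target genes are tested against the summary
#' statistics with a per-miRNA Bonferroni threshold of `alpha / (number of
#' SNPs tested in that miRNA's target genes)`.
#'
#' @param gene_intervals Tibble `mirna_id, gene, chrom, start0, end0` (see
#'   [read_target_genes_bed()]).
#' @param snp_sites SNP site tibble (`site_id, site_kind, chrom, pos`).
#' @param sumstats Summary statistics (any panels; the per-miRNA threshold
#'   replaces panel thresholds here).
#' @param alpha Family-wise level per miRNA (default 0.05).
#' @return Association-result tibble (layer `"snp"`); `threshold` is the
#'   per-miRNA Bonferroni cut.
#' @export
target_gene_lookup <- function(gene_intervals, snp_sites, sumstats,
                               alpha = 0.05) {
  if (nrow(gene_intervals) == 0) {
    out <- association_result(character(0), character(0), character(0), "snp",
                              numeric(0), numeric(0), numeric(0), integer(0),
                              numeric(0))
    out$chrom <- character(0)
    out$pos <- integer(0)
    return(out)
  }
  regions <- tibble::tibble(
    mirna_id = gene_intervals$mirna_id, region_class = "flank",
    mature_id = NA_character_, chrom = gene_intervals$chrom,
    start0 = gene_intervals$start0, end0 = gene_intervals$end0, strand = "+"
  )
  ann <- map_sites_to_regions(snp_sites, regions)
  if (nrow(ann) == 0) return(target_gene_lookup(gene_intervals[0, ], snp_sites, sumstats))
  joined <- dplyr::inner_join(
    dplyr::select(ann, "site_id", "chrom", "pos", "mirna_id"),
    dplyr::select(sumstats, "rsid", "trait", "beta", "se", "p", "n"),
    by = c(site_id = "rsid")
  )
  # per-miRNA test count: SNPs with summary statistics in that miRNA's genes
  m_per <- joined |>
    dplyr::group_by(.data$mirna_id) |>
    dplyr::summarise(m = dplyr::n_distinct(.data$site_id), .groups = "drop")
  joined <- dplyr::left_join(joined, m_per, by = "mirna_id")
  out <- association_result(
    joined$site_id, joined$mirna_id, joined$trait, "snp",
    joined$beta, joined$se, joined$p, joined$n,
    threshold = alpha / joined$m
  )
  out$chrom <- joined$chrom
  out$pos <- joined$pos
  out
}
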