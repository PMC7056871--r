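test_that("log2-CPM transform conserves library size and handles edge counts", {
  # a single miRNA holding the whole library
  m1 <- matrix(5L, 1, 1, dimnames = list("miR-x", "s1"))
  expect_equal(cpm(m1)[1, 1], 1e6)
  expect_equal(cpm_log2(m1)[1, 1], log2(1e6 + 1), tolerance = 1e-12)

  # pseudocount floor: zero counts map to 0
  m2 <- matrix(c(0L, 10L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(cpm_log2(m2)["a", 1], 0)

  set.seed(8)
  m <- matrix(rpois(50 * 20, 40), 50, 20,
              dimnames = list(sprintf("m%02d", 1:50), sprintf("s%02d", 1:20)))
  expect_true(all(abs(colSums(cpm(m)) - 1e6) < 1e-6 * 1e6))

  # library-size invariance: scaling one sample's counts leaves log2-CPM unchanged
  m_scaled <- m
  m_scaled[, 3] <- m[, 3] * 7L
  expect_equal(cpm_log2(m_scaled)[, 3], cpm_log2(m)[, 3], tolerance = 1e-12)

  m_zero <- m
  m_zero[, 2] <- 0L
  expect_error(cpm_log2(m_zero), "s02")
})

test_that("antitonic fit reproduces monotone input and detects flat profiles", {
  x <- seq(0, 10, length.out = 50)
  y <- 3 - 0.2 * x # strictly decreasing, noiseless
  fit <- fit_lloq(x, y, smooth_k = 1L)
  expect_equal(fit$fit$sd_fit, y, tolerance = 1e-12)

  expect_message(flat <- fit_lloq(x, rep(1, 50)), "degenerate")
  expect_true(flat$degenerate)
  expect_equal(flat$lloq, min(x))

  expect_error(fit_lloq(1:5, 5:1), "at least 10")
})

test_that("the fitted mean-SD curve is non-increasing and order-invariant", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(20:300, 1)
    means <- runif(n, -2, 12)
    sds <- 2 * exp(-means / 3) + 0.2 + abs(rnorm(n, 0, 0.1))
    fit <- fit_lloq(means, sds)
    expect_true(all(diff(fit$fit$sd_fit) <= 1e-12))
    shuffle <- sample.int(n)
    fit2 <- fit_lloq(means[shuffle], sds[shuffle])
    expect_equal(fit2$lloq, fit$lloq)
  }
})

test_that("LLOQ recovers the analytic crossing of the generating curve", {
  set.seed(10)
  n <- 500
  means <- runif(n, 0, 12)
  curve <- function(m) 2 * exp(-m / 3) + 0.2
  sds <- curve(means) + rnorm(n, 0, 0.03)
  fit <- fit_lloq(means, sds)
  # analytic midpoint cut of the noiseless curve over the sampled range,
  # inverted analytically: m* = -3 log((c - 0.2) / 2)
  c_true <- (curve(min(means)) + curve(max(means))) / 2
  m_star <- -3 * log((c_true - 0.2) / 2)
  expect_lt(abs(fit$lloq - m_star), 0.25)
})

test_that("well-expressed selection uses strict inequalities and is monotone in LLOQ", {
  lc <- matrix(c(5, 5, 5, 5,   # always above lloq 4
                 5, 5, 3, 3,   # exactly 50% above
                 3, 3, 3, 3),  # never above
               3, 4, byrow = TRUE,
               dimnames = list(c("hi", "half", "lo"), sprintf("s%d", 1:4)))
  expect_equal(well_expressed(lc, 4), "hi")
  # monotone: raising lloq never adds miRNAs
  prev <- well_expressed(lc, 0)
  for (lloq in c(2, 3, 4, 5, 6)) {
    cur <- well_expressed(lc, lloq)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("selection recovers exactly the planted high-expressers", {
  set.seed(12)
  n_mirnas <- 200
  n_hi <- 60
  n_samp <- 80
  mu <- c(rep(8, n_hi), rep(-1, n_mirnas - n_hi))
  sd <- 2 * exp(-mu / 3) + 0.2
  ids <- sprintf("miR-t%03d", seq_len(n_mirnas))
  x <- matrix(rnorm(n_mirnas * n_samp, mu, sd), n_mirnas, n_samp,
              dimnames = list(ids, sprintf("s%03d", 1:n_samp)))
  lib <- 2e6
  counts <- matrix(rpois(length(x), pmax(2^x - 1, 0) * lib / 1e6),
                   n_mirnas, n_samp, dimnames = dimnames(x))
  # generator truth: the 60 planted high-expressers, and only they, clear an
  # LLOQ placed between the two expression strata
  lc <- cpm_log2(counts)
  expect_setequal(well_expressed(lc, lloq = 4), ids[1:n_hi])

  # full normalization: nothing outside the planted stratum survives, and
  # the planted stratum is (up to the miRNA sitting exactly at the fitted
  # LLOQ) retained
  norm <- normalize_expression(counts)
  expect_true(all(norm$well_expressed %in% ids[1:n_hi]))
  expect_gte(length(norm$well_expressed), n_hi - 2)
  expect_true(all(!norm$qc$housekeeping))
})

test_that("housekeeping probes are excluded from LLOQ fitting and selection", {
  set.seed(13)
  ids <- c(sprintf("miR-%02d", 1:30), "HK-1")
  mu <- c(runif(30, 0, 10), 11)
  x <- matrix(rnorm(31 * 40, mu, 2 * exp(-mu / 3) + 0.2), 31, 40,
              dimnames = list(ids, sprintf("s%d", 1:40)))
  counts <- matrix(rpois(length(x), pmax(2^x - 1, 0)), 31, 40,
                   dimnames = dimnames(x))
  counts <- counts + 1L # avoid all-zero samples in this tiny fixture
  norm <- normalize_expression(counts, housekeeping = "HK-1")
  expect_false("HK-1" %in% norm$well_expressed)
  expect_true(norm$qc$housekeeping[norm$qc$mirna_id == "HK-1"])
})

expr_phenotypes <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    sample_id = sprintf("s%04d", 1:n),
    age = rnorm(n, 65, 8), sex = rbinom(n, 1, 0.5),
    current_smoking = rbinom(n, 1, 0.2),
    bmi = rnorm(n, 27, 4), lipid_med = rbinom(n, 1, 0.2),
    diabetic_med = rbinom(n, 1, 0.1), bp_med = rbinom(n, 1, 0.2)
  )
}

test_that("linear expression association recovers a planted continuous effect", {
  n <- 800
  ph <- expr_phenotypes(n, seed = 14)
  mirna <- rnorm(n, 6, 1)
  ph$TC <- 0.3 * mirna + rnorm(n)
  res <- test_expression_association(mirna, "TC", ph, mirna_id = "miR-x")
  expect_lt(abs(res$beta - 0.3), 3 * res$se)
  expect_true(res$significant)
})

test_that("logistic expression association recovers a planted log-odds ratio", {
  n <- 1000
  ph <- expr_phenotypes(n, seed = 15)
  mirna <- rnorm(n, 6, 1)
  eta <- qlogis(0.15) + 0.5 * (mirna - 6)
  ph$T2D <- rbinom(n, 1, plogis(eta))
  res <- test_expression_association(mirna, "T2D", ph, mirna_id = "miR-x")
  expect_lt(abs(res$beta - 0.5), 3 * res$se)
})

test_that("complete separation in the logistic fit is flagged, not crashed", {
  n <- 60
  ph <- expr_phenotypes(n, seed = 16)
  mirna <- c(rnorm(30, 0), rnorm(30, 20))
  ph$CHD <- rep(c(0L, 1L), each = 30)
  expect_message(
    res <- test_expression_association(mirna, "CHD", ph, mirna_id = "miR-x"),
    "separation"
  )
  expect_true(is.na(res$p))
  expect_equal(res$note, "separation")
})

test_that("a permuted null keeps the nominal false-positive rate", {
  set.seed(17)
  n <- 150
  ph <- expr_phenotypes(n, seed = 17)
  ph$TC <- rnorm(n)
  hits <- 0L
  n_perm <- 400
  mirna <- rnorm(n, 6, 1)
  for (i in seq_len(n_perm)) {
    res <- test_expression_association(sample(mirna), "TC", ph)
    hits <- hits + res$significant
  }
  ci <- qbinom(c(0.005, 0.995), n_perm, 0.05)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})

test_that("the printed expression-association table passes the nominal filter", {
  fx <- expression_fixture()
  row <- fx[fx$mirna == "miR-10b-5p", ]
  expect_equal(row$beta, 0.352)
  expect_equal(row$p, 3.30e-11)
  res <- association_result(fx$mirna, fx$mirna, fx$trait, "expression",
                            fx$beta, NA_real_, fx$p, NA_integer_,
                            threshold = 0.05)
  expect_true(all(res$significant))
})

test_that("target-gene lookup applies per-miRNA Bonferroni thresholds", {
  genes <- tibble::tibble(mirna_id = "mir-x", gene = "GENE1", chrom = "1",
                          start0 = 1000L, end0 = 5000L)
  empty <- target_gene_lookup(genes[0, ],
                              tibble::tibble(site_id = character(0),
                                             site_kind = character(0),
                                             chrom = character(0),
                                             pos = integer(0)),
                              tibble::tibble(rsid = character(0)))
  expect_equal(nrow(empty), 0)

  snps <- tibble::tibble(site_id = sprintf("rs%02d", 1:10), site_kind = "snp",
                         chrom = "1", pos = as.integer(seq(1100, 4900, length.out = 10)))
  ss <- tibble::tibble(rsid = snps$site_id, trait = "TC",
                       beta = c(0.5, rep(0.01, 9)), se = 0.05,
                       p = c(1e-12, runif(9, 0.1, 1)), n = 5000)
  res <- target_gene_lookup(genes, snps, ss)
  expect_equal(unique(res$threshold), 0.05 / 10)
  expect_equal(res$feature_id[res$significant], "rs01")
})
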