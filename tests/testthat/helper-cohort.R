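# shared fixtures and independent oracles used across test files

small_sim_config <- function(seed = 42L, ...) {
  defaults <- list(
    seed = seed, n_gwas = 800L, n_meth = 250L, n_expr = 300L,
    n_mirnas = 40L, n_snps = 400L, n_cpgs = 200L, n_eqtl_snps = 40L,
    n_planted = 4L
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# O(n * m) point-in-interval oracle for site-to-region mapping: returns the
# (site_id, mirna_id, region_class) triples by exhaustive scan, applying the
# same specificity order mature > precursor > flank
brute_force_map <- function(sites, regions) {
  rank <- c(mature = 3L, precursor = 2L, flank = 1L)
  out <- list()
  for (i in seq_len(nrow(sites))) {
    pos0 <- sites$pos[i] - 1L
    best <- list()
    for (j in seq_len(nrow(regions))) {
      if (sites$chrom[i] != regions$chrom[j]) next
      if (pos0 >= regions$start0[j] && pos0 < regions$end0[j]) {
        m <- regions$mirna_id[j]
        cls <- regions$region_class[j]
        if (is.null(best[[m]]) || rank[cls] > rank[best[[m]]]) best[[m]] <- cls
      }
    }
    for (m in names(best)) {
      out[[length(out) + 1L]] <- data.frame(
        site_id = sites$site_id[i], mirna_id = m,
        region_class = best[[m]], stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(site_id = character(0), mirna_id = character(0),
                      region_class = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$site_id, res$mirna_id), , drop = FALSE]
}

# brute-force verification that a pruned SNP set satisfies the windowed
# pairwise constraint: no surviving pair that co-occurs in any window
# (constructed as in ld_prune: width window_bp, step half a window) has
# r2 > r2_max
prune_is_valid <- function(kept, ld, r2_max, window_bp, positions, rsids) {
  pos <- positions[match(kept, rsids)]
  step <- max(1, floor(window_bp / 2))
  w <- min(positions)
  while (w <= max(positions)) {
    idx <- which(pos >= w & pos < w + window_bp)
    if (length(idx) > 1) {
      pr <- utils::combn(idx, 2)
      for (k in seq_len(ncol(pr))) {
        a <- kept[pr[1, k]]; b <- kept[pr[2, k]]
        r2 <- if (a %in% rownames(ld) && b %in% colnames(ld)) ld[a, b] else 0
        if (r2 > r2_max) return(FALSE)
      }
    }
    w <- w + step
  }
  TRUE
}

# random symmetric pairwise r2 table (not necessarily PSD; the pruning
# algorithm only consumes pairwise values)
random_r2_matrix <- function(ids) {
  n <- length(ids)
  m <- matrix(runif(n * n), n, n)
  r2 <- (m + t(m)) / 2
  r2[r2 > 1] <- 1
  diag(r2) <- 1
  dimnames(r2) <- list(ids, ids)
  r2
}
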