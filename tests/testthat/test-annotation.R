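mini_annotation <- function() {
  list(
    precursors = tibble::tibble(
      mirna_id = c("mir-a", "mir-b"),
      chrom = c("7", "7"),
      start = c(25989538L, 25990100L),
      end = c(25989605L, 25990190L),
      strand = c("+", "-")
    ),
    matures = tibble::tibble(
      mature_id = c("miR-a-5p", "miR-a-3p"),
      mirna_id = c("mir-a", "mir-a"),
      chrom = "7",
      start = c(25989546L, 25989576L),
      end = c(25989567L, 25989597L),
      strand = "+"
    )
  )
}

test_that("flank regions are the precursor extended symmetrically by flank_bp", {
  regions <- build_mirna_regions(mini_annotation(), flank_bp = 2000L)
  fl <- regions[regions$mirna_id == "mir-a" & regions$region_class == "flank", ]
  # 1-based [25,989,538; 25,989,605] +/- 2kb -> 1-based [25,987,538; 25,991,605]
  expect_equal(fl$start0 + 1L, 25987538L)
  expect_equal(fl$end0, 25991605L)
  pr <- regions[regions$mirna_id == "mir-a" & regions$region_class == "precursor", ]
  expect_equal(pr$start0, 25989537L)
  expect_equal(pr$end0, 25989605L)
})

test_that("zero flank collapses the flank onto the precursor and clipping stops at zero", {
  ann <- mini_annotation()
  r0 <- build_mirna_regions(ann, flank_bp = 0L)
  fl <- r0[r0$region_class == "flank", ]
  pr <- r0[r0$region_class == "precursor", ]
  expect_equal(fl$start0, pr$start0)
  expect_equal(fl$end0, pr$end0)

  ann$precursors$start[1] <- 500L
  ann$precursors$end[1] <- 600L
  ann$matures <- ann$matures[0, ]
  rc <- build_mirna_regions(ann, flank_bp = 2000L)
  expect_equal(min(rc$start0), 0L)
})

test_that("malformed precursor intervals are dropped with a warning, not an error", {
  ann <- mini_annotation()
  ann$precursors$start[2] <- ann$precursors$end[2] + 10L
  expect_warning(regions <- build_mirna_regions(ann), "malformed")
  expect_false("mir-b" %in% regions$mirna_id)
  expect_true("mir-a" %in% regions$mirna_id)
})

test_that("every emitted region contains its precursor interval", {
  cfg <- small_sim_config()
  co <- simulate_cohort(cfg)
  regions <- build_mirna_regions(co$annotation, flank_bp = 2000L)
  prec <- regions[regions$region_class == "precursor", ]
  fl <- regions[regions$region_class == "flank", ]
  fl <- fl[match(prec$mirna_id, fl$mirna_id), ]
  expect_true(all(fl$start0 <= prec$start0 & fl$end0 >= prec$end0))
  # mature regions sit inside their precursor
  mat <- regions[regions$region_class == "mature", ]
  pidx <- match(mat$mirna_id, prec$mirna_id)
  expect_true(all(mat$start0 >= prec$start0[pidx] & mat$end0 <= prec$end0[pidx]))
})

test_that("site mapping matches the brute-force point-in-interval oracle", {
  set.seed(101)
  cfg <- small_sim_config(seed = 101L)
  co <- simulate_cohort(cfg)
  regions <- build_mirna_regions(co$annotation)
  sites <- dplyr::bind_rows(co$region_snps, co$cpg_manifest)
  sites <- sites[sample.int(nrow(sites), 300), ]
  got <- map_sites_to_regions(sites, regions)
  got_key <- got[order(got$site_id, got$mirna_id),
                 c("site_id", "mirna_id", "region_class")]
  want <- brute_force_map(sites, regions)
  expect_equal(as.data.frame(got_key), want, ignore_attr = TRUE)
})

test_that("half-open boundary semantics: start included, outer flank end excluded", {
  ann <- mini_annotation()
  ann$precursors <- ann$precursors[1, ]
  ann$matures <- ann$matures[0, ]
  regions <- build_mirna_regions(ann, flank_bp = 2000L)
  sites <- tibble::tibble(
    site_id = c("at_prec_start", "at_flank_last", "past_flank"),
    site_kind = "snp", chrom = "7",
    pos = c(25989538L, 25991605L, 25991606L)
  )
  got <- map_sites_to_regions(sites, regions)
  expect_equal(got$region_class[got$site_id == "at_prec_start"], "precursor")
  expect_equal(got$region_class[got$site_id == "at_flank_last"], "flank")
  expect_false("past_flank" %in% got$site_id)
})

test_that("a site in two overlapping flanks is annotated to both miRNAs", {
  ann <- mini_annotation() # flanks of mir-a and mir-b overlap
  regions <- build_mirna_regions(ann, flank_bp = 2000L)
  sites <- tibble::tibble(site_id = "shared", site_kind = "snp",
                          chrom = "7", pos = 25990000L)
  got <- map_sites_to_regions(sites, regions)
  expect_setequal(got$mirna_id, c("mir-a", "mir-b"))
})

test_that("empty site lists and chromosome scheme mismatches are handled", {
  regions <- build_mirna_regions(mini_annotation())
  empty <- map_sites_to_regions(
    tibble::tibble(site_id = character(0), site_kind = character(0),
                   chrom = character(0), pos = integer(0)),
    regions
  )
  expect_equal(nrow(empty), 0)
  chr_sites <- tibble::tibble(site_id = "s", site_kind = "snp",
                              chrom = "chr7", pos = 25990000L)
  expect_error(map_sites_to_regions(chr_sites, regions), "chromosome")
})

test_that("distance to precursor is signed and strand-aware", {
  ann <- mini_annotation()
  regions <- build_mirna_regions(ann, flank_bp = 2000L)
  sites <- tibble::tibble(
    site_id = c("up_a", "down_b"), site_kind = "snp", chrom = "7",
    pos = c(25989438L, 25990290L) # 100 bp upstream of a; 100 bp right of b
  )
  got <- map_sites_to_regions(sites, regions)
  d_a <- got$distance[got$site_id == "up_a" & got$mirna_id == "mir-a"]
  expect_equal(d_a, -100L) # upstream on + strand: negative
  d_b <- got$distance[got$site_id == "down_b" & got$mirna_id == "mir-b"]
  expect_equal(d_b, -100L) # right of a minus-strand precursor = upstream
  inside <- tibble::tibble(site_id = "in_a", site_kind = "snp",
                           chrom = "7", pos = 25989550L)
  expect_equal(
    map_sites_to_regions(inside, regions)$distance[1], 0L
  )
})

test_that("catalog union behaves as a set union keyed on rsID", {
  a <- tibble::tibble(site_id = c("rs1", "rs2", "rs3"), site_kind = "snp",
                      chrom = "1", pos = c(10L, 20L, 30L), source = "region_scan")
  b <- tibble::tibble(site_id = c("rs4", "rs5"), site_kind = "snp",
                      chrom = "1", pos = c(40L, 50L), source = "eqtl_catalog")
  expect_equal(nrow(merge_snp_catalogs(a, b)), 5)
  expect_equal(nrow(merge_snp_catalogs(a, a)), 3)
  shared <- merge_snp_catalogs(a, dplyr::mutate(a, source = "eqtl_catalog"))
  expect_true(all(shared$source == "eqtl_catalog,region_scan"))

  conflicting <- dplyr::mutate(a, pos = pos + 1L)
  expect_error(merge_snp_catalogs(a, conflicting), "rs1")
})

test_that("union cardinality identity holds for random synthetic catalogs", {
  set.seed(7)
  for (i in 1:20) {
    na <- sample(5:200, 1)
    nb <- sample(5:200, 1)
    nov <- sample(0:min(na, nb), 1)
    ids_a <- sprintf("rs%04d", seq_len(na))
    ids_b <- c(ids_a[seq_len(nov)], sprintf("rs%04d", na + seq_len(nb - nov)))
    mk <- function(ids, src) tibble::tibble(
      site_id = ids, site_kind = "snp", chrom = "1",
      pos = as.integer(match(ids, sprintf("rs%04d", 1:(na + nb))) * 10L),
      source = src
    )
    merged <- merge_snp_catalogs(mk(ids_a, "region_scan"), mk(ids_b, "eqtl_catalog"))
    expect_equal(nrow(merged), na + nb - nov)
  }
})
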