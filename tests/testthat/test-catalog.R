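validated_catalog <- function(read_count = 0L) {
  group_by_bsj(hela_validated_variants(read_count), provenance = "validated")
}

test_that("grouping reproduces the validated splice-variant families", {
  cat0 <- validated_catalog()
  asph <- dplyr::filter(tibble::as_tibble(cat0),
                        bsj_key == "chr8|61680967|61684188|-")
  expect_equal(nrow(asph), 4)
  expect_setequal(asph$mature_length, c(219L, 264L, 266L, 333L))
  # within-group ordering: descending mature length
  expect_equal(asph$mature_length, sort(asph$mature_length, decreasing = TRUE))
  expect_equal(glance(cat0)$n_unique_bsj, 15)
  expect_equal(glance(cat0)$n_genes, 15)
})

test_that("grouping matches a nested-loop oracle on random variants", {
  v <- random_variants(1000, n_keys = 50, seed = 7)
  cat0 <- group_by_bsj(v)
  oracle <- oracle_group(v)
  expect_equal(dplyr::n_distinct(cat0$bsj_key), length(oracle))
  got_sizes <- table(cat0$bsj_key)
  expect_equal(
    sort(as.integer(got_sizes)),
    sort(unname(vapply(oracle, length, integer(1))))
  )
  # same membership: isoform multiset per key
  for (k in names(oracle)) {
    expect_setequal(cat0$isoform[cat0$bsj_key == k],
                    v$isoform[oracle[[k]]])
  }
})

test_that("grouping conserves the variant multiset and collapse sums reads", {
  v <- random_variants(200, n_keys = 20, seed = 9)
  cat0 <- group_by_bsj(v)
  expect_setequal(cat0$isoform, v$isoform)
  expect_equal(nrow(cat0), nrow(v))

  # duplicate a row; collapse merges identical (key, blocks) rows,
  # summing read_count per signature
  dup <- v[1, ]
  dup$read_count <- 7L
  dup$isoform <- "dup_copy"
  v2 <- dplyr::bind_rows(v, dup)
  sig <- function(df) paste(
    df$bsj_key,
    purrr::map_chr(df$exon_sizes, paste, collapse = ","),
    purrr::map_chr(df$exon_offsets, paste, collapse = ",")
  )
  collapsed <- group_by_bsj(v2, collapse_identical = TRUE)
  expect_equal(nrow(collapsed), dplyr::n_distinct(sig(v2)))
  want_reads <- tapply(v2$read_count, sig(v2), sum)
  merged <- collapsed$read_count[sig(collapsed) == sig(v[1, ])]
  expect_equal(merged, unname(want_reads[[sig(v[1, ])]]))
})

test_that("summary histograms satisfy their counting identities", {
  cat0 <- group_by_bsj(random_variants(500, n_keys = 80, seed = 13))
  s <- catalog_summary(cat0)
  expect_equal(sum(s$variants_per_bsj$size * s$variants_per_bsj$n_bsj),
               s$n_variants)
  expect_equal(sum(s$type_counts$n), s$n_variants)
  expect_equal(sum(s$length_classes$n), s$n_variants)
  expect_error(catalog_summary(cat0, length_bins = c(800, 400)),
               "increasing")
})

test_that("summary exon stats and fixture counts are exact", {
  single <- group_by_bsj(make_variant("chr1", 0L, sizes = c(140L, 160L),
                                      offsets = c(0L, 400L)))
  s <- catalog_summary(single)
  expect_equal(s$exon_stats$exon_count, 2L)
  expect_equal(s$exon_stats$mean_exon_length, 150)

  sv <- catalog_summary(validated_catalog())
  expect_equal(sv$n_unique_bsj, 15)
  expect_equal(sv$n_genes, 15)

  singles <- group_by_bsj(random_variants(30, n_keys = 30, seed = 2) |>
                            dplyr::distinct(bsj_key, .keep_all = TRUE))
  ss <- catalog_summary(singles)
  expect_equal(ss$variants_per_bsj$size, 1L)
  expect_equal(ss$variants_per_bsj$n_bsj, ss$n_unique_bsj)
})

test_that("splice-variant families respect the membership threshold", {
  cat0 <- validated_catalog()
  expect_length(splice_variant_families(cat0), 15)
  big <- splice_variant_families(cat0, min_members = 8)
  expect_equal(big, "chr9|135881632|135883078|-")  # the CAMSAP1 junction

  singles <- group_by_bsj(
    random_variants(30, n_keys = 30, seed = 2) |>
      dplyr::distinct(bsj_key, .keep_all = TRUE)
  )
  expect_equal(splice_variant_families(singles), character())
  expect_error(splice_variant_families(cat0, min_members = 0), "min_members")
})

test_that("candidate filter uses a strict read threshold and pre-filter families", {
  fam_key <- make_variant("chr1", 0L, sizes = c(100L, 100L),
                          offsets = c(0L, 300L), gene = "A",
                          isoform = "A_1", read_count = 21L)
  fam_sib <- make_variant("chr1", 0L, sizes = 400L, gene = "A",
                          isoform = "A_2", read_count = 5L)
  stopifnot(fam_sib$bsj_key == fam_key$bsj_key)
  boundary <- make_variant("chr2", 0L, sizes = c(100L, 100L),
                           offsets = c(0L, 300L), gene = "B",
                           isoform = "B_1", read_count = 20L)
  v <- dplyr::bind_rows(fam_key, fam_sib, boundary)
  cat0 <- group_by_bsj(v)
  kept <- filter_candidates(cat0, require_variants = FALSE)
  # exactly 20 reads is excluded ("more than 20"); 21 passes
  expect_setequal(kept$isoform, "A_1")
  kept2 <- filter_candidates(cat0, require_variants = TRUE)
  expect_setequal(kept2$isoform, "A_1")  # family status judged pre-filter
})

test_that("candidate filter matches a brute-force predicate scan", {
  v <- random_variants(100, n_keys = 25, seed = 21)
  cat0 <- group_by_bsj(v)
  for (req in c(TRUE, FALSE)) {
    kept <- filter_candidates(cat0, min_reads = 40, max_length = 2000,
                              max_exons = 3, require_variants = req)
    keep <- oracle_filter(v, 40, 2000, 3, req)
    expect_setequal(kept$isoform, v$isoform[keep])
  }
})

test_that("relaxing any filter threshold never shrinks the survivor set", {
  cat0 <- group_by_bsj(random_variants(300, n_keys = 60, seed = 5))
  base <- filter_candidates(cat0, min_reads = 30, max_length = 1500,
                            max_exons = 3)
  relaxed <- list(
    filter_candidates(cat0, min_reads = 10, max_length = 1500, max_exons = 3),
    filter_candidates(cat0, min_reads = 30, max_length = 4000, max_exons = 3),
    filter_candidates(cat0, min_reads = 30, max_length = 1500, max_exons = 5),
    filter_candidates(cat0, min_reads = 30, max_length = 1500, max_exons = 3,
                      require_variants = FALSE)
  )
  for (r in relaxed) {
    expect_true(all(base$isoform %in% r$isoform))
  }
})

test_that("validated set with uniform high read counts passes the filter intact", {
  cat0 <- validated_catalog(read_count = 100L)
  kept <- filter_candidates(cat0)
  expect_equal(nrow(kept), nrow(cat0))
})

test_that("known/novel partition is exact and recovers planted splits", {
  cat0 <- group_by_bsj(random_variants(200, n_keys = 40, seed = 31))
  keys <- unique(cat0$bsj_key)
  all_known <- overlap_known(cat0, keys)
  expect_equal(all_known$n_known, length(keys))
  expect_equal(all_known$n_novel, 0)
  none <- overlap_known(cat0, character())
  expect_equal(none$n_known, 0)
  expect_equal(none$n_novel, length(keys))

  set.seed(8)
  planted <- sample(keys, length(keys) %/% 2)
  got <- overlap_known(cat0, planted)
  expect_equal(got$n_known, length(planted))
  expect_equal(got$n_known + got$n_novel, got$n_unique_bsj)
})
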