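#' Group circRNA isoforms into splice-variant families
#'
#' circRNA isoforms sharing an identical backsplice junction but differing
#' in internal exon/intron composition are splice variants of one another.
#' `group_by_bsj()` keys every isoform by its canonical BSJ and returns a
#' `circ_catalog`: a tibble ordered by key and, within each family, by
#' descending mature length (ties broken by exon count, then isoform
#' label).
#'
#' @param variants Tibble of circRNA isoforms as returned by
#'   [read_circexplorer()] (a `bsj_key` column is added if absent).
#' @param collapse_identical If `TRUE`, rows with identical BSJ key and
#'   identical exon blocks are merged into one, summing `read_count`.
#'   Useful when the same isoform was called in several libraries.
#' @param provenance Free-text label recording where the records came from.
#' @return A `circ_catalog`: a tibble carrying all variant columns plus
#'   `bsj_key`, with attribute `provenance`.
#' @examples
#' cat <- hela_validated_variants() |> group_by_bsj()
#' glance(cat)
#' @export
group_by_bsj <- function(variants, collapse_identical = FALSE,
                         provenance = "unspecified") {
  if (!"bsj_key" %in% names(variants) && nrow(variants) > 0) {
    variants$bsj_key <- bsj_key(
      variants$chrom, variants$start, variants$end, variants$strand
    )
  }
  if (nrow(variants) == 0) {
    if (!"bsj_key" %in% names(variants)) variants$bsj_key <- character()
    return(new_circ_catalog(variants, provenance))
  }
  if (collapse_identical) {
    variants <- variants |>
      dplyr::mutate(
        .block_sig = paste(
          .data$bsj_key,
          purrr::map_chr(.data$exon_sizes, paste, collapse = ","),
          purrr::map_chr(.data$exon_offsets, paste, collapse = ","),
          sep = ";"
        )
      ) |>
      dplyr::group_by(.data$.block_sig) |>
      dplyr::mutate(read_count = sum(.data$read_count)) |>
      dplyr::slice(1) |>
      dplyr::ungroup() |>
      dplyr::select(-".block_sig")
  }
  variants <- variants |>
    dplyr::arrange(
      .data$bsj_key, dplyr::desc(.data$mature_length),
      .data$exon_count, .data$isoform
    )
  new_circ_catalog(variants, provenance)
}

new_circ_catalog <- function(variants, provenance) {
  out <- as_tibble(variants)
  attr(out, "provenance") <- provenance
  class(out) <- c("circ_catalog", class(out))
  out
}

#' @export
print.circ_catalog <- function(x, ...) {
  cat(sprintf(
    "<circ_catalog> %d variants over %d backsplice junctions (provenance: %s)\n",
    nrow(x), dplyr::n_distinct(x$bsj_key), attr(x, "provenance")
  ))
  NextMethod()
}

#' @describeIn group_by_bsj One row per splice-variant family: `bsj_key`,
#'   `gene`, `n_variants`, and the sorted mature lengths as a list column.
#' @param x A `circ_catalog`.
#' @param ... Unused.
#' @export
tidy.circ_catalog <- function(x, ...) {
  as_tibble(x) |>
    dplyr::group_by(.data$bsj_key) |>
    dplyr::summarise(
      gene = .data$gene[1],
      n_variants = dplyr::n(),
      mature_lengths = list(sort(.data$mature_length)),
      total_reads = sum(.data$read_count),
      .groups = "drop"
    )
}

#' @describeIn group_by_bsj One-row overview: variant, junction and gene
#'   counts plus the multi-variant family count.
#' @export
glance.circ_catalog <- function(x, ...) {
  fam <- tidy(x)
  tibble(
    n_variants = nrow(x),
    n_unique_bsj = nrow(fam),
    n_genes = dplyr::n_distinct(x$gene),
    n_families = sum(fam$n_variants >= 2)
  )
}

#' Summary statistics of a circRNA catalog
#'
#' Computes the descriptive statistics used to characterize a circRNA
#' annotation set: total and unique-junction counts, gene count, the
#' variants-per-junction histogram, mature-length class counts over
#' user-supplied bins, exonic/intronic composition, and the mean exon
#' length per exon-count class (`mature_length / exon_count`, averaged over
#' isoforms with that exon count).
#'
#' @param catalog A `circ_catalog`.
#' @param length_bins Increasing positive bin edges for the length classes;
#'   classes are `(0, b1], (b1, b2], ..., (bk, Inf)`. The default
#'   `c(400, 800, 1200, 1600, 2000)` gives a final open class above
#'   2000 nt, where few circRNAs fall.
#' @return A `circ_summary` object (list) with elements `n_variants`,
#'   `n_unique_bsj`, `n_genes`, `variants_per_bsj`, `length_classes`,
#'   `type_counts`, `exon_stats`. `tidy()` returns the histogram pieces as
#'   a long tibble; `glance()` the scalar counts; `autoplot()` a panel of
#'   the distributions.
#' @export
catalog_summary <- function(catalog, length_bins = c(400, 800, 1200, 1600, 2000)) {
  stopifnot(inherits(catalog, "circ_catalog"))
  if (is.unsorted(length_bins, strictly = TRUE) || any(length_bins <= 0)) {
    abort("length_bins must be strictly increasing positive edges")
  }
  x <- as_tibble(catalog)
  fam_sizes <- x |> dplyr::count(.data$bsj_key, name = "size")
  vpb <- fam_sizes |> dplyr::count(.data$size, name = "n_bsj")
  edges <- c(0, length_bins, Inf)
  lower <- c(0, length_bins[-length(length_bins)])
  labels <- c(
    sprintf("(%d,%d]", lower, length_bins),
    sprintf(">%d", length_bins[length(length_bins)])
  )
  cls <- cut(x$mature_length, breaks = edges, labels = labels, right = TRUE)
  length_classes <- tibble(length_class = labels) |>
    dplyr::left_join(
      tibble(length_class = as.character(cls)) |>
        dplyr::count(.data$length_class, name = "n"),
      by = "length_class"
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  type_counts <- x |> dplyr::count(.data$circ_type, name = "n")
  exon_stats <- x |>
    dplyr::group_by(.data$exon_count) |>
    dplyr::summarise(
      mean_exon_length = mean(.data$mature_length / .data$exon_count),
      n = dplyr::n(), .groups = "drop"
    )
  structure(
    list(
      n_variants = nrow(x),
      n_unique_bsj = nrow(fam_sizes),
      n_genes = dplyr::n_distinct(x$gene),
      variants_per_bsj = vpb,
      length_classes = length_classes,
      type_counts = type_counts,
      exon_stats = exon_stats,
      length_bins = length_bins
    ),
    class = "circ_summary"
  )
}

#' @export
print.circ_summary <- function(x, ...) {
  cat(sprintf(
    "<circ_summary> %d variants | %d unique BSJs | %d genes\n",
    x$n_variants, x$n_unique_bsj, x$n_genes
  ))
  cat("variants per BSJ:\n")
  print(x$variants_per_bsj, n = Inf)
  invisible(x)
}

#' @export
tidy.circ_summary <- function(x, ...) {
  dplyr::bind_rows(
    x$variants_per_bsj |>
      dplyr::transmute(statistic = "variants_per_bsj",
                       level = as.character(.data$size), n = .data$n_bsj),
    x$length_classes |>
      dplyr::transmute(statistic = "length_class",
                       level = .data$length_class, n = .data$n),
    x$type_counts |>
      dplyr::transmute(statistic = "circ_type",
                       level = .data$circ_type, n = .data$n)
  )
}

#' @export
glance.circ_summary <- function(x, ...) {
  tibble(
    n_variants = x$n_variants,
    n_unique_bsj = x$n_unique_bsj,
    n_genes = x$n_genes,
    pct_exonic = 100 * sum(x$type_counts$n[x$type_counts$circ_type == "exonic"]) /
      max(x$n_variants, 1L)
  )
}

#' Backsplice junctions with two or more splice variants
#'
#' @param catalog A `circ_catalog`.
#' @param min_members Minimum family size (default 2, the usual definition
#'   of a splice-variant family).
#' @return Character vector of BSJ keys sorted by (chrom, start).
#' @export
splice_variant_families <- function(catalog, min_members = 2) {
  stopifnot(inherits(catalog, "circ_catalog"))
  if (min_members < 1) abort("min_members must be >= 1")
  fam <- tidy(catalog) |> dplyr::filter(.data$n_variants >= min_members)
  if (nrow(fam) == 0) return(character())
  coords <- parse_bsj_key(fam$bsj_key)
  fam$bsj_key[order(coords$chrom, coords$start)]
}

#' Select candidate circRNAs for experimental validation
#'
#' Applies the abundance/size/complexity filter used to pick circRNAs for
#' divergent-primer RT-PCR and rolling-circle-amplification validation:
#' supporting read count strictly greater than `min_reads` ("more than 20
#' reads" is `> 20`, so a variant with exactly 20 reads is dropped), mature
#' length at most `max_length`, at most `max_exons` exons, and — when
#' `require_variants` is `TRUE` — membership in a splice-variant family of
#' the *unfiltered* catalog (family status is decided before abundance
#' filtering).
#'
#' @param catalog A `circ_catalog`.
#' @param min_reads Read-count threshold (exclusive). Default 20.
#' @param max_length Maximum mature length in nt. Default 1500.
#' @param max_exons Maximum exon count. Default 5.
#' @param require_variants Keep only members of multi-variant families.
#' @return A filtered `circ_catalog` with the grouping rebuilt.
#' @export
filter_candidates <- function(catalog, min_reads = 20, max_length = 1500,
                              max_exons = 5, require_variants = TRUE) {
  stopifnot(inherits(catalog, "circ_catalog"))
  x <- as_tibble(catalog)
  fam_keys <- splice_variant_families(catalog, min_members = 2)
  keep <- x$read_count > min_reads &
    x$mature_length <= max_length &
    x$exon_count <= max_exons
  if (require_variants) keep <- keep & x$bsj_key %in% fam_keys
  group_by_bsj(x[keep, , drop = FALSE],
               provenance = attr(catalog, "provenance"))
}

#' Known versus novel backsplice junctions
#'
#' Partitions the catalog's unique BSJ keys by exact membership in a
#' user-supplied list of known junctions (e.g. a circAtlas-style export).
#'
#' @param catalog A `circ_catalog`.
#' @param known_keys Character vector of canonical BSJ keys.
#' @return A one-row tibble with `n_known`, `n_novel`, `n_unique_bsj`.
#' @export
overlap_known <- function(catalog, known_keys) {
  stopifnot(inherits(catalog, "circ_catalog"))
  keys <- unique(catalog$bsj_key)
  n_known <- sum(keys %in% known_keys)
  tibble(
    n_known = n_known,
    n_novel = length(keys) - n_known,
    n_unique_bsj = length(keys)
  )
}
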