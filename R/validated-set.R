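#' RT-PCR/RCA-validated HeLa circRNA splice variants
#'
#' A packaged reference set of 15 backsplice junctions from HeLa cells
#' whose splice variants were validated by divergent-primer RT-PCR,
#' rolling-circle amplification and Sanger sequencing. Each junction lists
#' its splice-variant mature lengths (nt) with exon counts, the host gene
#' and the circAtlas identifier — e.g. circASPH at
#' `chr8|61680967|61684188|-` with variants of 219, 264, 266 and 333 nt.
#'
#' The source table records only variant lengths and exon counts, not the
#' exon block coordinates, so this loader constructs *schematic* exon
#' blocks: blocks that satisfy every structural invariant (first block at
#' the junction start, last block flush with the junction end, sizes
#' summing to the mature length, inter-block gaps spread evenly). Lengths,
#' exon counts, junctions, genes and grouping are faithful; block
#' placements are not real annotations and must not be used to retrieve
#' hg38 sequence.
#'
#' @param read_count Read count assigned to every variant (the source
#'   table does not report per-variant counts). Default 0.
#' @return A variant tibble (see [read_circexplorer()] for the columns)
#'   with one row per splice variant (59 rows over 15 junctions) plus a
#'   `circatlas_id` column.
#' @examples
#' hela_validated_variants() |> group_by_bsj() |> glance()
#' @export
hela_validated_variants <- function(read_count = 0L) {
  path <- system.file("extdata", "hela_validated_circrnas.tsv",
                      package = "circvariants", mustWork = TRUE)
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  coords <- parse_bsj_key(raw$bsj_key)
  rows <- purrr::pmap(
    list(raw$bsj_key, coords$chrom, coords$start, coords$end, coords$strand,
         raw$gene, raw$variants, raw$circatlas_id),
    function(key, chrom, start, end, strand, gene, variants, atlas) {
      entries <- strsplit(variants, ",\\s*")[[1]]
      m <- stringr::str_match(entries, "^(\\d+)\\((\\d+)\\)$")
      lens <- as.integer(m[, 2])
      exons <- as.integer(m[, 3])
      blocks <- purrr::map2(lens, exons, .schematic_blocks,
                            span = end - start)
      tibble(
        chrom = chrom, start = start, end = end,
        name = paste0("circ", gene, "_", lens),
        read_count = as.integer(read_count), strand = strand,
        exon_count = exons,
        exon_sizes = purrr::map(blocks, "sizes"),
        exon_offsets = purrr::map(blocks, "offsets"),
        circ_type = "exonic", gene = gene,
        isoform = paste0(gene, "_", lens),
        mature_length = lens, bsj_key = key, circatlas_id = atlas
      )
    }
  )
  dplyr::bind_rows(rows)
}

# invariant-satisfying schematic exon blocks: k sizes summing to m, first
# offset 0, last block flush with the span end, gaps spread evenly
.schematic_blocks <- function(m, k, span) {
  stopifnot(m <= span, k >= 1)
  sizes <- rep(m %/% k, k)
  if (m %% k > 0) sizes[seq_len(m %% k)] <- sizes[seq_len(m %% k)] + 1L
  if (k == 1) {
    if (m != span) abort("single-exon variant must span the whole junction")
    return(list(sizes = as.integer(m), offsets = 0L))
  }
  gap_total <- span - m
  gaps <- rep(gap_total %/% (k - 1), k - 1)
  if (gap_total %% (k - 1) > 0) {
    gaps[seq_len(gap_total %% (k - 1))] <-
      gaps[seq_len(gap_total %% (k - 1))] + 1L
  }
  offsets <- cumsum(c(0L, sizes[-k] + gaps))
  list(sizes = as.integer(sizes), offsets = as.integer(offsets))
}
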