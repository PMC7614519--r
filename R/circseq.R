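#' Circular mature sequences
#'
#' A `circ_seq` holds the mature spliced sequence of a circRNA with
#' circular indexing. Position 0 is the first base of the mature transcript
#' immediately downstream of the backsplice junction (acceptor side) and
#' position `L - 1` the last base before the junction (donor side); all
#' position arithmetic is modulo `L`. For minus-strand variants position 0
#' corresponds to the genomic *end* coordinate, which makes "the junction
#' sits between `L - 1` and 0" strand-independent.
#'
#' @param bases DNA string over `ACGTN`.
#' @param bsj_key Canonical junction key of the source variant (optional).
#' @param isoform Isoform label of the source variant (optional).
#' @return A `circ_seq` object.
#' @export
circ_seq <- function(bases, bsj_key = NA_character_, isoform = NA_character_) {
  bases <- chartr("U", "T", toupper(bases))
  if (nchar(bases) < 1) abort("circular sequence must have length >= 1")
  if (grepl("[^ACGTN]", bases)) abort("alphabet must be ACGTN")
  structure(
    list(bases = bases, length = nchar(bases),
         bsj_key = bsj_key, isoform = isoform),
    class = "circ_seq"
  )
}

#' @export
print.circ_seq <- function(x, ...) {
  shown <- if (x$length > 40) paste0(substr(x$bases, 1, 40), "...") else x$bases
  cat(sprintf("<circ_seq> %d nt [%s | %s] %s\n",
              x$length, x$bsj_key, x$isoform, shown))
  invisible(x)
}

.revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Reconstruct the mature spliced circRNA sequence
#'
#' Concatenates the exon-block slices of the genome in offset order; for
#' minus-strand variants the concatenation is reverse-complemented, which
#' also reverses block order in mature orientation. The result has length
#' `sum(exon_sizes)` and is anchored at the backsplice junction (see
#' [circ_seq()] for the anchor convention). `N` bases propagate unchanged.
#'
#' @param genome Named character vector of chromosome sequences, as
#'   returned by [read_fasta()].
#' @param variant One-row variant tibble (or a list with the same fields).
#' @return A `circ_seq`.
#' @examples
#' g <- c(chr1 = "AAAACCCCGGGGTTTT")
#' v <- tibble::tibble(
#'   chrom = "chr1", start = 0L, end = 12L, name = "toy", read_count = 0L,
#'   strand = "+", exon_count = 2L, exon_sizes = list(c(4L, 4L)),
#'   exon_offsets = list(c(0L, 8L)), circ_type = "exonic", gene = "toy",
#'   isoform = "toy", mature_length = 8L
#' )
#' build_mature_sequence(g, v)$bases  # "AAAAGGGG"
#' @export
build_mature_sequence <- function(genome, variant) {
  v <- as.list(variant[1, ])
  if (!v$chrom %in% names(genome)) {
    abort(paste0("chromosome not in genome: ", v$chrom))
  }
  chrom_seq <- genome[[v$chrom]]
  sizes <- v$exon_sizes[[1]]
  offsets <- v$exon_offsets[[1]]
  if (v$end > nchar(chrom_seq)) {
    abort("variant end beyond chromosome length")
  }
  slices <- substring(chrom_seq, v$start + offsets + 1,
                      v$start + offsets + sizes)
  plus <- paste(slices, collapse = "")
  bases <- if (v$strand == "-") .revcomp(plus) else plus
  key <- if (!is.null(v$bsj_key)) v$bsj_key else {
    bsj_key(v$chrom, v$start, v$end, v$strand)
  }
  circ_seq(bases, bsj_key = key, isoform = v$isoform)
}

#' Mature sequences for every variant in a table
#'
#' @param genome Named character vector of chromosome sequences.
#' @param variants Variant tibble.
#' @return The input tibble with a `mature_seq` character column appended.
#' @export
mature_sequences <- function(genome, variants) {
  variants$mature_seq <- purrr::map_chr(
    seq_len(nrow(variants)),
    function(i) build_mature_sequence(genome, variants[i, ])$bases
  )
  variants
}

#' Sequence window across the backsplice junction
#'
#' Returns the `2k`-nt linear window centred on the junction: the last `k`
#' bases of the mature sequence followed by the first `k`. This is the
#' stretch a Sanger read of a divergent-primer BSJ amplicon traverses; the
#' junction sits between output positions `k - 1` and `k` (0-based).
#'
#' @param seq A `circ_seq`.
#' @param k Flank size in nt, `1 <= k <= L`.
#' @return A character scalar of length `2k`.
#' @export
junction_window <- function(seq, k) {
  stopifnot(inherits(seq, "circ_seq"))
  L <- seq$length
  if (k < 1 || k > L) abort("k must satisfy 1 <= k <= L")
  paste0(substr(seq$bases, L - k + 1, L), substr(seq$bases, 1, k))
}

#' Rotate a circular sequence
#'
#' Cyclically shifts the anchor so that old position `offset` becomes new
#' position 0. Rotating by any multiple of `L` (including 0) is the
#' identity; `rotate_circ(rotate_circ(s, r), -r)` recovers `s`.
#'
#' @param seq A `circ_seq`.
#' @param offset Any integer.
#' @return A `circ_seq`.
#' @export
rotate_circ <- function(seq, offset) {
  stopifnot(inherits(seq, "circ_seq"))
  L <- seq$length
  r <- ((offset %% L) + L) %% L
  if (r == 0) return(seq)
  circ_seq(
    paste0(substr(seq$bases, r + 1, L), substr(seq$bases, 1, r)),
    bsj_key = seq$bsj_key, isoform = seq$isoform
  )
}
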