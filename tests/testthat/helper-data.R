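# Programmatic fixtures: random-but-valid variant tables and
# CIRCexplorer2-dialect files built in code at test time.

make_variant <- function(chrom = "chr1", start = 0L, sizes = 100L,
                         offsets = 0L, strand = "+", gene = "G1",
                         isoform = paste0(gene, "_", sum(sizes)),
                         read_count = 0L, circ_type = "exonic",
                         name = isoform) {
  end <- start + offsets[length(offsets)] + sizes[length(sizes)]
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    name = name, read_count = as.integer(read_count), strand = strand,
    exon_count = length(sizes), exon_sizes = list(as.integer(sizes)),
    exon_offsets = list(as.integer(offsets)), circ_type = circ_type,
    gene = gene, isoform = isoform, mature_length = as.integer(sum(sizes)),
    bsj_key = circvariants::bsj_key(chrom, start, end, strand)
  )
}

# random sizes/offsets with the last block flush with the span end
rand_blocks <- function(span, k) {
  if (k == 1) return(list(sizes = as.integer(span), offsets = 0L))
  m <- sample(seq(k, max(k, span - (k - 1))), 1)
  cuts <- sort(sample(seq_len(m - 1), k - 1))
  sizes <- diff(c(0, cuts, m))
  gap_total <- span - m
  gcuts <- sort(sample(0:gap_total, k - 2, replace = TRUE))
  gaps <- diff(c(0, gcuts, gap_total))
  offsets <- cumsum(c(0L, sizes[-k] + gaps))
  list(sizes = as.integer(sizes), offsets = as.integer(offsets))
}

random_variants <- function(n, n_keys = 50, seed = 1) {
  set.seed(seed)
  keys <- tibble::tibble(
    chrom = sample(paste0("chr", 1:5), n_keys, replace = TRUE),
    start = sample.int(1e6, n_keys),
    strand = sample(c("+", "-"), n_keys, replace = TRUE),
    span = sample(300:4000, n_keys, replace = TRUE)
  )
  rows <- lapply(seq_len(n), function(i) {
    ki <- sample.int(n_keys, 1)
    k <- sample(1:5, 1)
    b <- rand_blocks(keys$span[ki], k)
    make_variant(
      chrom = keys$chrom[ki], start = keys$start[ki], sizes = b$sizes,
      offsets = b$offsets, strand = keys$strand[ki],
      gene = paste0("G", ki), isoform = paste0("iso", i),
      read_count = sample(0:100, 1)
    )
  })
  dplyr::bind_rows(rows)
}

# serialize a variant table to the 18-column CIRCexplorer2 dialect
write_ce_file <- function(variants, path, n_cols = 18) {
  lines <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    f <- c(
      v$chrom, v$start, v$end, v$name, 0, v$strand, v$start, v$end,
      "0,0,0", v$exon_count,
      paste(v$exon_sizes[[1]], collapse = ","),
      paste(v$exon_offsets[[1]], collapse = ","),
      v$read_count,
      if (v$circ_type == "exonic") "circRNA" else "ciRNA",
      v$gene, v$isoform, i, "None"
    )
    paste(f[seq_len(n_cols)], collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}

# stop-free frame-0 circle of length L (divisible by 3) with ATG at 0
stop_free_circle <- function(L) {
  stopifnot(L %% 3 == 0)
  sense <- setdiff(
    apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                      c("A", "C", "G", "T")), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA", "ATG")
  )
  circvariants::circ_seq(
    paste(c("ATG", sample(sense, L / 3 - 1, replace = TRUE)), collapse = "")
  )
}
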