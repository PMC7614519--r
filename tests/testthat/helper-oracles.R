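# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths: plain loops,
# character vectors, and seqinr for translation.

oracle_stops <- c("TAA", "TAG", "TGA")

# circular ORF reader over an explicitly repeated string
oracle_circ_orfs <- function(bases) {
  L <- nchar(bases)
  cycle <- if (L %% 3 == 0) L %/% 3 else L
  reps <- ceiling((3 * cycle + 2) / L) + 1
  ch <- strsplit(strrep(bases, reps), "")[[1]]
  res <- list()
  for (s in 0:(L - 1)) {
    if (paste(ch[(s + 1):(s + 3)], collapse = "") != "ATG") next
    found <- FALSE
    for (j in seq_len(cycle)) {
      p <- s + 3 * (j - 1)
      cod <- paste(ch[(p + 1):(p + 3)], collapse = "")
      if (cod %in% oracle_stops) {
        pep <- paste(
          toupper(seqinr::translate(ch[(s + 1):(s + 3 * (j - 1))])),
          collapse = ""
        )
        res[[length(res) + 1]] <- tibble::tibble(
          start = s, length_nt = 3L * j, peptide = pep, is_infinite = FALSE
        )
        found <- TRUE
        break
      }
    }
    if (!found) {
      pep <- paste(
        toupper(seqinr::translate(ch[(s + 1):(s + 3 * cycle)])),
        collapse = ""
      )
      res[[length(res) + 1]] <- tibble::tibble(
        start = s, length_nt = NA_integer_, peptide = pep, is_infinite = TRUE
      )
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble(start = integer(), length_nt = integer(),
                          peptide = character(), is_infinite = logical()))
  }
  dplyr::arrange(dplyr::bind_rows(res), start)
}

# nucleotide-by-nucleotide mature sequence reconstruction
oracle_build_seq <- function(genome, variant) {
  v <- as.list(variant[1, ])
  chrom <- strsplit(genome[[v$chrom]], "")[[1]]
  out <- character(0)
  for (e in seq_len(v$exon_count)) {
    o <- v$exon_offsets[[1]][e]
    s <- v$exon_sizes[[1]][e]
    for (i in seq_len(s)) out <- c(out, chrom[v$start + o + i])
  }
  if (v$strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    out <- rev(unname(comp[out]))
  }
  paste(out, collapse = "")
}

# hash-free nested-loop grouping: list of row-index vectors per key
oracle_group <- function(variants) {
  keys <- character(0)
  members <- list()
  for (i in seq_len(nrow(variants))) {
    k <- variants$bsj_key[i]
    found <- FALSE
    for (g in seq_along(keys)) {
      if (keys[g] == k) {
        members[[g]] <- c(members[[g]], i)
        found <- TRUE
        break
      }
    }
    if (!found) {
      keys <- c(keys, k)
      members[[length(members) + 1]] <- i
    }
  }
  names(members) <- keys
  members
}

# row-wise predicate scan for the candidate filter
oracle_filter <- function(variants, min_reads, max_length, max_exons,
                          require_variants) {
  fam <- table(variants$bsj_key)
  keep <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    keep[i] <- v$read_count > min_reads &&
      v$mature_length <= max_length &&
      v$exon_count <= max_exons &&
      (!require_variants || fam[[v$bsj_key]] >= 2)
  }
  keep
}

# linear scan of the doubled string, starts restricted to [0, L)
oracle_scan <- function(bases, pattern_regex, len) {
  L <- nchar(bases)
  doubled <- strrep(bases, max(2, ceiling((L - 1 + len) / L)))
  hits <- integer(0)
  for (s in 0:(L - 1)) {
    w <- substr(doubled, s + 1, s + len)
    if (grepl(pattern_regex, w)) hits <- c(hits, s)
  }
  hits
}

# step-by-step circular walk from the forward primer start to the far end
# of the reverse primer site
oracle_amplicon <- function(L, f_start, r_start, r_len) {
  target <- (r_start + r_len - 1) %% L
  pos <- f_start %% L
  steps <- 1
  while (pos != target) {
    pos <- (pos + 1) %% L
    steps <- steps + 1
    if (steps > 2 * L) stop("walk did not terminate")
  }
  steps
}

random_dna <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}
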