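.stop_codons <- c("TAA", "TAG", "TGA")

# translate a character vector of codons with the standard code; codons
# containing N (absent from the code table) render as 'X', stops as '*'
.translate_codons <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# all L circular codons, codon i (0-based) starting at position i
.circ_codons <- function(bases) {
  L <- nchar(bases)
  reps <- max(2L, ceiling((L + 2) / L))
  ext <- strrep(bases, reps)
  substring(ext, seq_len(L), seq_len(L) + 2L)
}

#' Translate codons on a circular template
#'
#' Reads `n_codons` codons starting at circular position `start` (0-based),
#' wrapping modulo `L`, under the standard genetic code. Stop codons render
#' as `*`; codons containing `N` render as `X`.
#'
#' @param seq A `circ_seq`.
#' @param start 0-based start position, `0 <= start < L`.
#' @param n_codons Number of codons to read (>= 1).
#' @return Amino-acid string of length `n_codons`.
#' @examples
#' translate_circular(circ_seq("ATGAAA"), 0, 2)  # "MK"
#' @export
translate_circular <- function(seq, start, n_codons) {
  stopifnot(inherits(seq, "circ_seq"))
  L <- seq$length
  if (start < 0 || start >= L) abort("start must satisfy 0 <= start < L")
  if (n_codons < 1) abort("n_codons must be >= 1")
  codons <- .circ_codons(seq$bases)
  pos <- (start + 3 * (seq_len(n_codons) - 1)) %% L
  .translate_codons(codons[pos + 1])
}

#' Enumerate ORFs on circular topology
#'
#' Exact circular enumeration: from every `ATG` on the circle (start codons
#' may straddle the backsplice junction), codons are read modulo `L` until
#' either a stop codon is met (a *finite* ORF) or the codon-start cycle
#' closes without one (an *infinite* ORF, translated indefinitely by
#' rolling-circle translation). The cycle visits `L/3` codon starts when
#' `L` is divisible by 3 and all `L` otherwise, so an infinite ORF's repeat
#' unit is `L/3` amino acids when `3 | L` and `L` amino acids otherwise.
#'
#' Finite ORFs satisfy `peptide_aa == length_nt/3 - 1` (the stop codon is
#' counted in `length_nt`, not the peptide) and cross the junction
#' `floor((start + length_nt - 1)/L)` times. Infinite ORFs always count as
#' junction-spanning. Finite ORFs sharing a stop position where the shorter
#' peptide is the C-terminal suffix of the longer (downstream in-frame
#' ATGs) are marked `nested`; with `include_nested = FALSE` they are
#' suppressed.
#'
#' @param seq A `circ_seq` with `L >= 3`.
#' @param min_peptide_aa Minimum peptide length reported (repeat-unit
#'   length for infinite ORFs). Default 20 — permissive relative to the
#'   smallest validated circRNA-derived polypeptides (~47 aa).
#' @param require_junction_spanning Keep only ORFs whose codon path
#'   crosses the junction (infinite ORFs always qualify). A
#'   junction-spanning peptide is unique to the circular form.
#' @param include_nested Keep nested downstream-ATG ORFs (default TRUE).
#' @return A tibble with one row per ORF start: `start`, `length_nt`
#'   (`NA` for infinite), `peptide_aa`, `n_junction_crossings` (for
#'   infinite ORFs, crossings per repeat unit), `peptide` (repeat unit for
#'   infinite), `is_infinite`, `repeat_unit_aa`, `stop_pos` (circular
#'   position of the stop codon's first base; `NA` for infinite),
#'   `nested`, plus `bsj_key`/`isoform` carried from the sequence. Ordered
#'   by descending peptide length, then start.
#' @seealso [find_orfs_tripled()] for the linearized triple-concatenation
#'   method, which this exact scanner subsumes.
#' @export
find_circ_orfs <- function(seq, min_peptide_aa = 20,
                           require_junction_spanning = FALSE,
                           include_nested = TRUE) {
  stopifnot(inherits(seq, "circ_seq"))
  L <- seq$length
  if (L < 3) abort("circular ORF scan requires L >= 3")
  codons <- .circ_codons(seq$bases)
  atg <- which(codons == "ATG") - 1L
  cycle_len <- if (L %% 3 == 0) L %/% 3 else L
  rows <- purrr::map(atg, function(s) {
    pos <- (s + 3 * (seq_len(cycle_len) - 1L)) %% L
    cods <- codons[pos + 1L]
    stop_idx <- which(cods %in% .stop_codons)[1]
    if (!is.na(stop_idx)) {
      j <- stop_idx
      tibble(
        start = s, length_nt = 3L * j, peptide_aa = j - 1L,
        n_junction_crossings = (s + 3L * j - 1L) %/% L,
        peptide = .translate_codons(cods[seq_len(j - 1L)]),
        is_infinite = FALSE, repeat_unit_aa = NA_integer_,
        stop_pos = pos[j]
      )
    } else {
      tibble(
        start = s, length_nt = NA_integer_, peptide_aa = cycle_len,
        n_junction_crossings = (3L * cycle_len) %/% L,
        peptide = .translate_codons(cods),
        is_infinite = TRUE, repeat_unit_aa = cycle_len,
        stop_pos = NA_integer_
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(.empty_orf_tbl(seq))
  out <- .mark_nested(out)
  out <- out |>
    dplyr::filter(.data$peptide_aa >= min_peptide_aa)
  if (require_junction_spanning) {
    out <- out |>
      dplyr::filter(.data$is_infinite | .data$n_junction_crossings >= 1)
  }
  if (!include_nested) out <- out |> dplyr::filter(!.data$nested)
  out$bsj_key <- seq$bsj_key
  out$isoform <- seq$isoform
  dplyr::arrange(out, dplyr::desc(.data$peptide_aa), .data$start)
}

.empty_orf_tbl <- function(seq = NULL) {
  tibble(
    start = integer(), length_nt = integer(), peptide_aa = integer(),
    n_junction_crossings = integer(), peptide = character(),
    is_infinite = logical(), repeat_unit_aa = integer(),
    stop_pos = integer(), nested = logical(),
    bsj_key = character(), isoform = character()
  )
}

# nested = shorter finite ORF sharing a stop whose peptide is the
# C-terminal suffix of a longer one's
.mark_nested <- function(orfs) {
  orfs$nested <- FALSE
  fin <- which(!orfs$is_infinite)
  if (length(fin) > 1) {
    for (sp in unique(orfs$stop_pos[fin])) {
      grp <- fin[orfs$stop_pos[fin] == sp]
      if (length(grp) < 2) next
      grp <- grp[order(-orfs$peptide_aa[grp])]
      longest <- orfs$peptide[grp[1]]
      for (g in grp[-1]) {
        orfs$nested[g] <- endsWith(longest, orfs$peptide[g])
      }
    }
  }
  orfs
}

#' ORF scan by triple concatenation (linearized method)
#'
#' Concatenates the mature sequence three times, runs an ordinary linear
#' ATG-to-stop scan on the `3L`-nt string, maps starts modulo `L` and
#' deduplicates identical `(start, length_nt)` records, so that each ORF
#' is reported once regardless of which concatenation copy it fell in.
#' An ORF is flagged junction-spanning when its linear extent crosses a
#' multiple of `L`.
#'
#' This is a widely used approximation with two documented limitations
#' relative to [find_circ_orfs()]: it cannot report infinite (stop-free)
#' ORFs, and finite ORFs longer than `2L` nt may be truncated by the end
#' of the third copy (flagged `truncation_risk`). Every ORF it does report
#' is also reported by the exact scanner with an identical peptide; it is
#' retained as a cross-check mode, not the default engine.
#'
#' @inheritParams find_circ_orfs
#' @return A tibble with columns `start`, `length_nt`, `peptide_aa`,
#'   `junction_spanning`, `truncation_risk`, `peptide`, `bsj_key`,
#'   `isoform`.
#' @export
find_orfs_tripled <- function(seq, min_peptide_aa = 20) {
  stopifnot(inherits(seq, "circ_seq"))
  L <- seq$length
  if (L < 3) abort("ORF scan requires L >= 3")
  triple <- strrep(seq$bases, 3)
  n <- 3L * L
  cods <- substring(triple, seq_len(n - 2L), seq_len(n - 2L) + 2L)
  atg <- which(cods == "ATG") - 1L  # 0-based linear positions
  stop_pos0 <- which(cods %in% .stop_codons) - 1L
  stops_by_frame <- split(stop_pos0, stop_pos0 %% 3)
  rows <- purrr::map(atg, function(p) {
    v <- stops_by_frame[[as.character(p %% 3)]]
    if (is.null(v)) return(NULL)
    q <- v[v > p][1]
    if (length(q) == 0 || is.na(q)) return(NULL)  # runs off the third copy
    len <- q + 3L - p
    start <- p %% L
    pep_cods <- cods[seq(p, q - 3L, by = 3L) + 1L]
    tibble(
      start = start, length_nt = len, peptide_aa = len %/% 3L - 1L,
      junction_spanning = (start + len - 1L) %/% L >= 1L,
      truncation_risk = len > 2L * L,
      peptide = .translate_codons(pep_cods)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(
      start = integer(), length_nt = integer(), peptide_aa = integer(),
      junction_spanning = logical(), truncation_risk = logical(),
      peptide = character(), bsj_key = character(), isoform = character()
    ))
  }
  out <- out |>
    dplyr::distinct(.data$start, .data$length_nt, .keep_all = TRUE) |>
    dplyr::filter(.data$peptide_aa >= min_peptide_aa)
  out$bsj_key <- seq$bsj_key
  out$isoform <- seq$isoform
  dplyr::arrange(out, dplyr::desc(.data$peptide_aa), .data$start)
}

#' Report ORF peptides as FASTA and TSV
#'
#' Writes the peptides of an ORF table (as produced by [find_circ_orfs()],
#' possibly row-bound over many sequences) in a deterministic order:
#' descending peptide length, ties by start. FASTA headers are
#' `bsj_key|isoform|start|peptide_aa|finite-or-infinite`; the TSV carries
#' every ORF column including the `nested` flag.
#'
#' @param orfs ORF tibble; must carry `bsj_key` and `isoform` columns.
#' @param fasta_path,tsv_path Output paths; either may be `NULL` to skip.
#' @return The ordered report tibble, invisibly.
#' @export
peptide_report <- function(orfs, fasta_path = NULL, tsv_path = NULL) {
  if (nrow(orfs) > 0) {
    orfs <- dplyr::arrange(orfs, dplyr::desc(.data$peptide_aa), .data$start)
  }
  if (!is.null(fasta_path)) {
    if (nrow(orfs) == 0) {
      writeLines(character(), fasta_path)
    } else {
      headers <- sprintf(
        "%s|%s|%d|%d|%s", orfs$bsj_key, orfs$isoform, orfs$start,
        orfs$peptide_aa, ifelse(orfs$is_infinite, "infinite", "finite")
      )
      write_fasta(setNames(orfs$peptide, headers), fasta_path)
    }
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(orfs, tsv_path)
  }
  invisible(orfs)
}
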