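.iupac_map <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

# IUPAC (RNA or DNA) -> anchored regex on the ACGT alphabet
.iupac_regex <- function(motif) {
  motif <- chartr("U", "T", toupper(motif))
  letters <- strsplit(motif, "", fixed = TRUE)[[1]]
  bad <- setdiff(letters, names(.iupac_map))
  if (length(bad) > 0) {
    abort(paste0("invalid IUPAC letter(s): ", paste(unique(bad), collapse = ", ")))
  }
  paste0("^", paste(.iupac_map[letters], collapse = ""), "$")
}

# wrap-aware fixed-length window scan: all L circular start positions
.scan_circular <- function(bases, len, regex) {
  L <- nchar(bases)
  reps <- ceiling((L - 1 + len) / L)
  ext <- strrep(bases, reps)
  windows <- substring(ext, seq_len(L), seq_len(L) + len - 1L)
  hit <- grepl(regex, windows)
  tibble(
    position = which(hit) - 1L,
    matched = windows[hit],
    wraps_junction = (which(hit) - 1L) + len > L
  )
}

#' Scan a circular sequence for DRACH m6A consensus sites
#'
#' The N6-methyladenosine consensus DRACH (`D = A/G/T`, `R = A/G`, then
#' `A`, `C`, `H = A/C/T`; the methylated adenosine is the central `A`) is
#' matched at every circular start position, so motifs spanning the
#' backsplice junction are found. This is a transparent consensus scan —
#' it enumerates candidate sites, it does not score them the way trained
#' m6A predictors (e.g. SRAMP) do, and reports should label it as such.
#'
#' @param seq A `circ_seq` with `L >= 5`.
#' @return A tibble of hits: `motif_id` (`"DRACH"`), `position` (0-based
#'   start of the D on the circle), `matched`, `wraps_junction`,
#'   `methyl_a_pos` (circular position of the methylated A, motif offset
#'   2), plus `bsj_key`/`isoform`.
#' @export
scan_drach <- function(seq) {
  stopifnot(inherits(seq, "circ_seq"))
  if (seq$length < 5) abort("DRACH scan requires L >= 5")
  hits <- .scan_circular(seq$bases, 5L, "^[AGT][AG]AC[ACT]$")
  hits |>
    dplyr::mutate(
      motif_id = "DRACH",
      methyl_a_pos = (.data$position + 2L) %% seq$length,
      bsj_key = seq$bsj_key, isoform = seq$isoform,
      .before = 1
    ) |>
    dplyr::relocate("motif_id")
}

#' Scan a circular sequence for user-defined IUPAC motifs
#'
#' Motifs may be given on the RNA alphabet (`U` is transcoded to `T`) and
#' may contain any IUPAC degeneracy code. Matching is wrap-aware and
#' single-strand: a mature circRNA is single-stranded sense RNA, so only
#' the sense strand is scanned. Useful for RNA-binding-protein site
#' stand-ins such as an HuR AU-rich element `"UUUUU"`.
#'
#' @param seq A `circ_seq`.
#' @param motifs Named character vector (or list) mapping motif id to
#'   IUPAC string.
#' @return A tibble of hits sorted by `(motif_id, position)` with columns
#'   as in [scan_drach()] (minus `methyl_a_pos`).
#' @export
scan_motifs <- function(seq, motifs) {
  stopifnot(inherits(seq, "circ_seq"))
  motifs <- unlist(motifs)
  if (is.null(names(motifs)) || any(!nzchar(names(motifs)))) {
    abort("motifs must be named")
  }
  out <- purrr::imap(motifs, function(m, id) {
    len <- nchar(chartr("U", "T", m))
    hits <- .scan_circular(seq$bases, len, .iupac_regex(m))
    hits$motif_id <- id
    hits
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(bsj_key = seq$bsj_key, isoform = seq$isoform) |>
    dplyr::relocate("motif_id") |>
    dplyr::arrange(.data$motif_id, .data$position)
}

#' Predict divergent-primer and rolling-circle amplicon sizes
#'
#' Models the two PCR readouts used to validate circRNAs and their splice
#' variants. A divergent primer pair (outward-facing on the linear gene)
#' yields a product only on the circular template; its size is the
#' circular distance from the forward primer's start, walking in the
#' direction of extension, to the far end of the reverse primer's binding
#' site — a product that necessarily reads through the backsplice
#' junction. Rolling-circle amplification of the circle produces tandem
#' full-length cDNA repeats, so PCR on RCA cDNA yields a concatamer
#' ladder: the monomer product plus `L` nt per additional lap,
#' `ladder[k] = bsj_amplicon_nt + (k - 1) * L`. With back-to-back primers
#' covering the full circle the ladder is `L, 2L, 3L, ...` — the printed
#' variant lengths themselves.
#'
#' @param seq A `circ_seq`.
#' @param primer_f Forward primer placement `c(start, length)` on the
#'   circle (0-based start).
#' @param primer_r Reverse primer placement `c(start, length)`,
#'   reverse-oriented (its binding site occupies
#'   `[start, start + length)` on the circle).
#' @param max_k Number of ladder rungs (laps) to report.
#' @return An `amplicon_plan` (list with `primer_f`, `primer_r`,
#'   `bsj_amplicon_nt`, `ladder`); `tidy()` returns the ladder as a
#'   tibble of `(k, product_nt)`.
#' @export
plan_amplicons <- function(seq, primer_f, primer_r, max_k = 3) {
  stopifnot(inherits(seq, "circ_seq"))
  L <- seq$length
  if (length(primer_f) != 2 || length(primer_r) != 2 ||
      primer_f[2] < 1 || primer_r[2] < 1) {
    abort("primers must be c(start, length) with length >= 1")
  }
  if (max_k < 1) abort("max_k must be >= 1")
  f_pos <- (primer_f[1] + seq_len(primer_f[2]) - 1L) %% L
  r_pos <- (primer_r[1] + seq_len(primer_r[2]) - 1L) %% L
  if (length(intersect(f_pos, r_pos)) > 0) {
    abort("primer binding sites overlap; no product exists")
  }
  far_end <- (primer_r[1] + primer_r[2] - 1L) %% L
  bsj_amplicon <- ((far_end - primer_f[1]) %% L) + 1L
  structure(
    list(
      primer_f = c(start = primer_f[1], length = primer_f[2]),
      primer_r = c(start = primer_r[1], length = primer_r[2]),
      circle_nt = L,
      bsj_amplicon_nt = as.integer(bsj_amplicon),
      ladder = as.integer(bsj_amplicon + (seq_len(max_k) - 1L) * L)
    ),
    class = "amplicon_plan"
  )
}

#' @export
print.amplicon_plan <- function(x, ...) {
  cat(sprintf(
    "<amplicon_plan> circle %d nt | BSJ amplicon %d nt | ladder: %s\n",
    x$circle_nt, x$bsj_amplicon_nt, paste(x$ladder, collapse = ", ")
  ))
  invisible(x)
}

#' @export
tidy.amplicon_plan <- function(x, ...) {
  tibble(k = seq_along(x$ladder), product_nt = x$ladder)
}
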