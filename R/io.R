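#' Read CIRCexplorer2-style circRNA annotations
#'
#' Parses the 18-column BED12+6 dialect written by the CIRCexplorer2
#' annotate/de-novo modules (chrom, start, end, name, score, strand,
#' thickStart, thickEnd, itemRgb, exonCount, exonSizes, exonOffsets,
#' readNumber, circType, geneName, isoformName, index, flankIntron).
#' Files trimmed to the first 12 BED columns are accepted; the missing
#' annotation columns then default to `read_count = 0`,
#' `circ_type = "exonic"`, `gene = name`, `isoform = name`.
#'
#' Coordinates are BED-convention 0-based half-open. `circType` values
#' `"circRNA"` map to `"exonic"` and `"ciRNA"` (intron-lariat-derived) to
#' `"intronic"`.
#'
#' @param path Path to a tab-delimited annotation file (no header).
#' @param mode `"strict"` (default) aborts on the first malformed row,
#'   naming it; `"lenient"` skips malformed rows with a warning.
#' @return A tibble with one row per circRNA isoform and columns
#'   `chrom`, `start`, `end`, `name`, `read_count`, `strand`,
#'   `exon_count`, `exon_sizes` (list), `exon_offsets` (list),
#'   `circ_type`, `gene`, `isoform`, `mature_length`, `bsj_key`.
#' @seealso [group_by_bsj()] to fold the result into splice-variant
#'   families.
#' @export
read_circexplorer <- function(path, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- vector("list", length(lines))
  bad <- logical(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    prob <- NULL
    if (length(f) < 12) {
      prob <- sprintf("expected >= 12 tab-delimited columns, found %d", length(f))
    } else {
      start <- suppressWarnings(as.integer(f[2]))
      end <- suppressWarnings(as.integer(f[3]))
      exon_count <- suppressWarnings(as.integer(f[10]))
      sizes <- .parse_block_ints(f[11])
      offsets <- .parse_block_ints(f[12])
      read_count <- if (length(f) >= 13) {
        suppressWarnings(as.integer(round(as.numeric(f[13]))))
      } else 0L
      circ_type <- if (length(f) >= 14) {
        switch(f[14], circRNA = "exonic", ciRNA = "intronic", f[14])
      } else "exonic"
      if (is.na(exon_count)) {
        prob <- "non-integer exonCount"
      } else {
        prob <- .variant_row_problem(
          f[1], start, end, f[6], exon_count, sizes, offsets,
          read_count, circ_type
        )
      }
      if (is.null(prob)) {
        rows[[i]] <- tibble(
          chrom = f[1], start = start, end = end, name = f[4],
          read_count = read_count, strand = f[6], exon_count = exon_count,
          exon_sizes = list(sizes), exon_offsets = list(offsets),
          circ_type = circ_type,
          gene = if (length(f) >= 15) f[15] else f[4],
          isoform = if (length(f) >= 16) f[16] else f[4],
          mature_length = sum(sizes)
        )
      }
    }
    if (!is.null(prob)) {
      if (mode == "strict") {
        abort(sprintf("parse error at row %d: %s", i, prob))
      }
      warn(sprintf("skipping row %d: %s", i, prob))
      bad[i] <- TRUE
    }
  }
  out <- dplyr::bind_rows(rows[!bad])
  if (nrow(out) == 0) {
    out <- tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), read_count = integer(), strand = character(),
      exon_count = integer(), exon_sizes = list(), exon_offsets = list(),
      circ_type = character(), gene = character(), isoform = character(),
      mature_length = integer()
    )
  }
  out$bsj_key <- if (nrow(out)) {
    bsj_key(out$chrom, out$start, out$end, out$strand)
  } else character()
  out
}

.parse_block_ints <- function(x) {
  parts <- strsplit(sub(",$", "", x), ",", fixed = TRUE)[[1]]
  suppressWarnings(as.integer(parts))
}

#' Write and re-read a splice-variant catalog as TSV
#'
#' The on-disk form is one row per isoform with exon block lists serialized
#' as comma-joined integers and the catalog provenance stored on a leading
#' `# provenance:` comment line. The round trip is lossless: reading back a
#' written catalog reproduces every variant field and the grouping.
#'
#' @param catalog A `circ_catalog` (see [group_by_bsj()]).
#' @param path Output/input file path.
#' @return `write_catalog_tsv()` returns `path` invisibly;
#'   `read_catalog_tsv()` returns a `circ_catalog`.
#' @export
write_catalog_tsv <- function(catalog, path) {
  stopifnot(inherits(catalog, "circ_catalog"))
  flat <- as_tibble(catalog) |>
    dplyr::mutate(
      exon_sizes = purrr::map_chr(.data$exon_sizes, paste, collapse = ","),
      exon_offsets = purrr::map_chr(.data$exon_offsets, paste, collapse = ",")
    )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# provenance: %s", attr(catalog, "provenance")), con)
  writeLines(paste(names(flat), collapse = "\t"), con)
  if (nrow(flat)) {
    body <- do.call(paste, c(lapply(flat, as.character), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname write_catalog_tsv
#' @export
read_catalog_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  first <- readLines(path, n = 1)
  provenance <- sub("^# provenance: ?", "", first)
  df <- readr::read_tsv(
    path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      chrom = "c", start = "i", end = "i", name = "c", read_count = "i",
      strand = "c", exon_count = "i", exon_sizes = "c", exon_offsets = "c",
      circ_type = "c", gene = "c", isoform = "c", mature_length = "i",
      bsj_key = "c"
    )
  )
  df <- df |>
    dplyr::mutate(
      exon_sizes = purrr::map(.data$exon_sizes, .parse_block_ints),
      exon_offsets = purrr::map(.data$exon_offsets, .parse_block_ints)
    )
  group_by_bsj(df, provenance = provenance)
}

#' Read and write FASTA
#'
#' Sequences are uppercased on read and any `U` is normalized to `T`: the
#' package works on the DNA alphabet `ACGTN` internally even for motifs
#' defined on RNA. Writing wraps sequence lines at 60 characters and
#' accepts either nucleotide or peptide records.
#'
#' @param path File path.
#' @return `read_fasta()` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  if (anyDuplicated(names(seqs))) {
    abort(paste0(
      "duplicate FASTA record name: ",
      names(seqs)[duplicated(names(seqs))][1]
    ))
  }
  if (any(!nzchar(seqs))) abort("empty sequence in FASTA")
  seqs
}

#' @rdname read_fasta
#' @param records Named character vector of sequences.
#' @export
write_fasta <- function(records, path) {
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    abort("records must be a named character vector")
  }
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read an RT-qPCR Ct table
#'
#' Expects delimited text (comma or tab, chosen by file extension) with
#' columns `target`, `sample` and `ct`. One measurement per row; Ct is the
#' PCR threshold cycle and must be a finite positive number.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @return A tibble with columns `target`, `sample`, `ct`.
#' @seealso [delta_ct()], [fraction_distribution()]
#' @export
read_qpcr <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  df <- reader(path, show_col_types = FALSE,
               col_types = readr::cols(.default = "c"))
  missing <- setdiff(c("target", "sample", "ct"), names(df))
  if (length(missing) > 0) {
    abort(paste0("qPCR table lacks columns: ", paste(missing, collapse = ", ")))
  }
  ct <- suppressWarnings(as.numeric(df$ct))
  bad <- which(is.na(ct) | !is.finite(ct) | ct <= 0)
  if (length(bad) > 0) {
    abort(sprintf("non-numeric or non-positive ct at row %d", bad[1]))
  }
  tibble(target = df$target, sample = df$sample, ct = ct)
}
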