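#' Configuration for the synthetic circRNA dataset generator
#'
#' Bundles every knob of [simulate_circ_dataset()]. Defaults emulate the
#' statistical structure of a de-novo circRNA annotation run on a
#' circRNA-enriched cell line: most backsplice junctions carry a single
#' isoform with a heavy multi-variant tail (~37% of junctions in 2+
#' families), ~97% exonic records, negative-binomially dispersed
#' BSJ-supporting read counts, and ~79% of junctions present in a known
#' (circAtlas-style) list.
#'
#' @param seed Integer RNG seed; the whole dataset is a deterministic
#'   function of the config.
#' @param n_chromosomes,chrom_length Toy genome dimensions (nt).
#' @param n_bsj Number of regular (non-plant) backsplice junctions.
#' @param variants_per_bsj_weights Named numeric weights over family sizes
#'   `"1", "2", ...` (normalized internally; mode must be at 1).
#' @param read_count_mean,read_count_dispersion Negative-binomial mean and
#'   size for BSJ-supporting read counts.
#' @param exon_count_range,exon_size_range Integer ranges for parent exon
#'   structure (counts; sizes in nt).
#' @param intron_size_range,locus_gap_range Integer ranges (nt) for
#'   introns between parent exons and gaps between gene loci.
#' @param frac_intronic Proportion of junctions emitted as single-interval
#'   intron-lariat-derived records (ciRNAs).
#' @param known_frac Proportion of junctions labelled "known".
#' @param plants List of planted features (see [default_plants()]); each
#'   gets a dedicated singleton host locus so plants cannot interfere
#'   with one another or with family loci.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 300000L,
                       n_bsj = 80L,
                       variants_per_bsj_weights =
                         c("1" = 0.63, "2" = 0.22, "3" = 0.09,
                           "4" = 0.04, "5" = 0.02),
                       read_count_mean = 15,
                       read_count_dispersion = 0.6,
                       exon_count_range = c(1L, 5L),
                       exon_size_range = c(60L, 400L),
                       intron_size_range = c(60L, 800L),
                       locus_gap_range = c(200L, 1500L),
                       frac_intronic = 0.03,
                       known_frac = 0.787,
                       plants = list()) {
  stopifnot(
    n_chromosomes >= 1, chrom_length >= 1000, n_bsj >= 1,
    all(variants_per_bsj_weights >= 0), sum(variants_per_bsj_weights) > 0,
    read_count_mean > 0, read_count_dispersion > 0,
    frac_intronic >= 0, frac_intronic <= 1,
    known_frac >= 0, known_frac <= 1
  )
  if (is.null(names(variants_per_bsj_weights))) {
    names(variants_per_bsj_weights) <-
      as.character(seq_along(variants_per_bsj_weights))
  }
  w <- variants_per_bsj_weights / sum(variants_per_bsj_weights)
  structure(
    list(
      seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
      chrom_length = as.integer(chrom_length), n_bsj = as.integer(n_bsj),
      variants_per_bsj_weights = w,
      read_count_mean = read_count_mean,
      read_count_dispersion = read_count_dispersion,
      exon_count_range = as.integer(exon_count_range),
      exon_size_range = as.integer(exon_size_range),
      intron_size_range = as.integer(intron_size_range),
      locus_gap_range = as.integer(locus_gap_range),
      frac_intronic = frac_intronic, known_frac = known_frac,
      plants = plants
    ),
    class = "sim_config"
  )
}

#' Planted sequence features for the simulator
#'
#' Each plant describes one feature written into the mature sequence of a
#' dedicated singleton host circRNA, together with the host's mature
#' length. `default_plants()` returns the standard validation set: a
#' 47-aa junction-spanning finite ORF in a 395-nt host, stop-free
#' infinite ORFs in 219- and 264-nt hosts (whose rolling-circle repeat
#' units of 73 and 88 aa differ by 15 aa), and a DRACH m6A consensus site
#' wrapping the backsplice junction of a 300-nt host.
#'
#' @param peptide_aa Peptide length of a finite ORF plant (aa, including
#'   the initiator methionine; the ORF occupies `3 * (peptide_aa + 1)` nt
#'   with its stop codon).
#' @param host_length Mature length (nt) of the dedicated host circRNA.
#'   Infinite-ORF hosts must be divisible by 3.
#' @return A plant description list; `default_plants()` a list of them.
#' @name plants
NULL

#' @rdname plants
#' @export
plant_finite_orf <- function(peptide_aa, host_length) {
  stopifnot(peptide_aa >= 1, host_length >= 3)
  if (3 * (peptide_aa + 1) > host_length) {
    abort("infeasible plant: peptide too long for host length and wrap budget")
  }
  list(type = "finite_orf", peptide_aa = as.integer(peptide_aa),
       host_length = as.integer(host_length))
}

#' @rdname plants
#' @export
plant_infinite_orf <- function(host_length) {
  if (host_length %% 3 != 0) {
    abort("infinite-ORF host length must be divisible by 3")
  }
  list(type = "infinite_orf", host_length = as.integer(host_length))
}

#' @rdname plants
#' @export
plant_drach_junction <- function(host_length = 300L) {
  stopifnot(host_length >= 5)
  list(type = "drach_junction", host_length = as.integer(host_length))
}

#' @rdname plants
#' @param motif IUPAC motif string (RNA or DNA alphabet).
#' @param position 0-based circular position for the motif plant.
#' @export
plant_motif <- function(motif, position, host_length = 300L) {
  stopifnot(nchar(motif) >= 1, position >= 0, position < host_length,
            nchar(motif) <= host_length)
  list(type = "motif", motif = motif, position = as.integer(position),
       host_length = as.integer(host_length))
}

#' @rdname plants
#' @export
default_plants <- function() {
  list(
    plant_finite_orf(peptide_aa = 47, host_length = 395),
    plant_infinite_orf(host_length = 219),
    plant_infinite_orf(host_length = 264),
    plant_drach_junction(host_length = 300)
  )
}

.sense_codons <- function() {
  all_codons <- as.vector(outer(
    as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
    c("A", "C", "G", "T"), paste0
  ))
  setdiff(all_codons, c(.stop_codons, "ATG"))
}

# genomic 1-based positions of each mature base, in mature order
.mature_positions <- function(variant) {
  v <- as.list(variant[1, ])
  plus <- unlist(purrr::map2(
    v$exon_offsets[[1]], v$exon_sizes[[1]],
    function(o, s) v$start + o + seq_len(s)
  ))
  if (v$strand == "+") plus else rev(plus)
}

# write mature-space bases into the chromosome character vector
.write_mature <- function(chrom_vec, variant, mature_pos0, bases_chr) {
  gpos <- .mature_positions(variant)[mature_pos0 + 1L]
  if (variant$strand[1] == "-") {
    bases_chr <- chartr("ACGTN", "TGCAN", bases_chr)
  }
  chrom_vec[gpos] <- bases_chr
  chrom_vec
}

#' Generate a synthetic circRNA dataset with ground truth
#'
#' Builds a toy genome (uniform ACGT background), gene loci with parent
#' exon structures, and CIRCexplorer2-dialect circRNA records. Splice
#' variants within a family are exon *subsets* of a shared parent block
#' set that always retain the first and last exon, so family members share
#' an exact backsplice junction while differing in exon composition and
#' mature length. Planted features (see [default_plants()]) are written
#' into dedicated singleton host loci at the codon level: finite ORF
#' plants lay down `ATG`, sense codons and a stop across the junction;
#' infinite-ORF plants rewrite the whole frame stop-free; DRACH plants
#' write the consensus across the junction. Every emitted record satisfies
#' the variant invariants, and the truth ledger records what was planted
#' where.
#'
#' @param config A [sim_config()].
#' @return A `circ_sim` list: `genome` (named character), `variants`
#'   (variant tibble), `known_keys` (character), `truth` (list with
#'   `families`, `plants`, `known` tibbles) and `config`. Deterministic:
#'   the same config (including seed) reproduces the output exactly.
#' @export
simulate_circ_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  alphabet <- c("A", "C", "G", "T")
  chroms <- lapply(seq_len(cfg$n_chromosomes), function(i) {
    sample(alphabet, cfg$chrom_length, replace = TRUE)
  })
  names(chroms) <- paste0("chr", seq_len(cfg$n_chromosomes))

  fam_sizes <- sample(
    as.integer(names(cfg$variants_per_bsj_weights)), cfg$n_bsj,
    replace = TRUE, prob = cfg$variants_per_bsj_weights
  )
  is_intronic <- stats::runif(cfg$n_bsj) < cfg$frac_intronic
  fam_sizes[is_intronic] <- 1L

  chrom_i <- 1L
  cursor <- 0L
  rows <- list()
  plant_rows <- list()

  advance <- function(span_needed) {
    gap <- sample(cfg$locus_gap_range[1]:cfg$locus_gap_range[2], 1)
    start <- cursor + gap
    if (start + span_needed > cfg$chrom_length) {
      chrom_i <<- chrom_i + 1L
      if (chrom_i > cfg$n_chromosomes) {
        abort("toy genome too small for requested loci; increase chrom_length")
      }
      cursor <<- 0L
      start <- sample(cfg$locus_gap_range[1]:cfg$locus_gap_range[2], 1)
    }
    cursor <<- start + span_needed
    start
  }

  make_variant <- function(chrom, start, sizes, offsets, strand, gene,
                           isoform, circ_type, read_count) {
    end <- start + offsets[length(offsets)] + sizes[length(sizes)]
    tibble(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      name = isoform, read_count = as.integer(read_count), strand = strand,
      exon_count = length(sizes), exon_sizes = list(as.integer(sizes)),
      exon_offsets = list(as.integer(offsets)), circ_type = circ_type,
      gene = gene, isoform = isoform,
      mature_length = as.integer(sum(sizes)),
      bsj_key = bsj_key(chrom, start, end, strand)
    )
  }

  # regular family loci
  for (b in seq_len(cfg$n_bsj)) {
    n_var <- fam_sizes[b]
    gene <- sprintf("GENE%04d", b)
    strand <- sample(c("+", "-"), 1)
    rc <- function(n) rnbinom(n, mu = cfg$read_count_mean,
                              size = cfg$read_count_dispersion)
    if (is_intronic[b]) {
      size <- sample(cfg$exon_size_range[1]:cfg$exon_size_range[2], 1) +
        sample(50:200, 1)
      start <- advance(size)
      rows[[length(rows) + 1]] <- make_variant(
        names(chroms)[chrom_i], start, size, 0L, strand, gene,
        paste0(gene, "_ci"), "intronic", rc(1)
      )
      next
    }
    m_needed <- if (n_var > 1) ceiling(log2(n_var)) else 0L
    m_extra <- sample(0:max(0L, cfg$exon_count_range[2] - 2L), 1)
    m <- max(m_needed, m_extra)
    k_parent <- if (n_var == 1 && m == 0) {
      sample(cfg$exon_count_range[1]:max(cfg$exon_count_range), 1)
    } else {
      2L + m
    }
    sizes <- sample(cfg$exon_size_range[1]:cfg$exon_size_range[2],
                    k_parent, replace = TRUE)
    if (k_parent == 1) {
      offsets <- 0L
    } else {
      introns <- sample(cfg$intron_size_range[1]:cfg$intron_size_range[2],
                        k_parent - 1, replace = TRUE)
      offsets <- cumsum(c(0L, sizes[-k_parent] + introns))
    }
    span <- offsets[k_parent] + sizes[k_parent]
    start <- advance(span)
    chrom <- names(chroms)[chrom_i]
    if (k_parent == 1 || n_var == 1) {
      masks <- if (k_parent <= 2) list(integer(0)) else {
        list(seq_len(k_parent - 2))  # parent keeps all middles
      }
      masks <- masks[1]
    } else {
      n_mid <- k_parent - 2L
      codes <- sample(0:(2^n_mid - 1), n_var)
      masks <- lapply(codes, function(cd) which(bitwAnd(cd, 2^(seq_len(n_mid) - 1)) > 0))
    }
    iso_lens <- character(0)
    for (vi in seq_along(masks)) {
      keep <- sort(unique(c(1L, masks[[vi]] + 1L, k_parent)))
      v_sizes <- sizes[keep]
      v_offsets <- offsets[keep]
      lab <- paste0(gene, "_", sum(v_sizes))
      if (lab %in% iso_lens) lab <- paste0(lab, letters[vi])
      iso_lens <- c(iso_lens, lab)
      rows[[length(rows) + 1]] <- make_variant(
        chrom, start, v_sizes, v_offsets, strand, gene, lab,
        "exonic", rc(1)
      )
    }
  }

  # dedicated plant hosts: one singleton locus each
  for (pi in seq_along(cfg$plants)) {
    p <- cfg$plants[[pi]]
    H <- p$host_length
    gene <- sprintf("PLANT%02d", pi)
    strand <- sample(c("+", "-"), 1)
    s1 <- H %/% 2
    sizes <- c(s1, H - s1)
    intron <- sample(cfg$intron_size_range[1]:cfg$intron_size_range[2], 1)
    offsets <- c(0L, s1 + intron)
    span <- offsets[2] + sizes[2]
    start <- advance(span)
    chrom <- names(chroms)[chrom_i]
    host <- make_variant(chrom, start, sizes, offsets, strand, gene,
                         paste0(gene, "_", H), "exonic",
                         rnbinom(1, mu = cfg$read_count_mean,
                                 size = cfg$read_count_dispersion))
    sense <- .sense_codons()
    truth <- switch(
      p$type,
      finite_orf = {
        len_nt <- 3L * (p$peptide_aa + 1L)
        if (len_nt > H) abort("infeasible plant: ORF longer than host circle")
        s <- H - len_nt %/% 2L  # start before the junction, stop after it
        codons <- c("ATG", sample(sense, p$peptide_aa - 1L, replace = TRUE),
                    sample(.stop_codons, 1))
        mat_pos <- (s + seq_len(len_nt) - 1L) %% H
        chroms[[chrom]] <- .write_mature(
          chroms[[chrom]], host, mat_pos,
          strsplit(paste(codons, collapse = ""), "")[[1]]
        )
        pep <- .translate_codons(codons[seq_len(p$peptide_aa)])
        tibble(plant_type = "finite_orf", bsj_key = host$bsj_key,
               isoform = host$isoform, host_length = H,
               orf_start = as.integer(s), peptide_aa = p$peptide_aa,
               peptide = pep, repeat_unit_aa = NA_integer_,
               motif = NA_character_, motif_position = NA_integer_)
      },
      infinite_orf = {
        codons <- c("ATG", sample(sense, H %/% 3L - 1L, replace = TRUE))
        chroms[[chrom]] <- .write_mature(
          chroms[[chrom]], host, 0:(H - 1L),
          strsplit(paste(codons, collapse = ""), "")[[1]]
        )
        tibble(plant_type = "infinite_orf", bsj_key = host$bsj_key,
               isoform = host$isoform, host_length = H,
               orf_start = 0L, peptide_aa = H %/% 3L,
               peptide = .translate_codons(codons),
               repeat_unit_aa = H %/% 3L,
               motif = NA_character_, motif_position = NA_integer_)
      },
      drach_junction = {
        mat_pos <- c(H - 3L, H - 2L, H - 1L, 0L, 1L)
        chroms[[chrom]] <- .write_mature(
          chroms[[chrom]], host, mat_pos, c("G", "G", "A", "C", "A")
        )
        tibble(plant_type = "drach_junction", bsj_key = host$bsj_key,
               isoform = host$isoform, host_length = H,
               orf_start = NA_integer_, peptide_aa = NA_integer_,
               peptide = NA_character_, repeat_unit_aa = NA_integer_,
               motif = "GGACA", motif_position = H - 3L)
      },
      motif = {
        inst <- .instantiate_iupac(p$motif)
        mat_pos <- (p$position + seq_len(nchar(inst)) - 1L) %% H
        chroms[[chrom]] <- .write_mature(
          chroms[[chrom]], host, mat_pos, strsplit(inst, "")[[1]]
        )
        tibble(plant_type = "motif", bsj_key = host$bsj_key,
               isoform = host$isoform, host_length = H,
               orf_start = NA_integer_, peptide_aa = NA_integer_,
               peptide = NA_character_, repeat_unit_aa = NA_integer_,
               motif = inst, motif_position = p$position)
      },
      abort(paste0("unknown plant type: ", p$type))
    )
    rows[[length(rows) + 1]] <- host
    plant_rows[[length(plant_rows) + 1]] <- truth
  }

  variants <- dplyr::bind_rows(rows)
  genome <- vapply(chroms, paste, character(1), collapse = "")
  keys <- unique(variants$bsj_key)
  known <- keys[stats::runif(length(keys)) < cfg$known_frac]
  catalog <- group_by_bsj(variants, provenance = "simulated")
  truth <- list(
    families = tidy(catalog),
    plants = dplyr::bind_rows(plant_rows),
    known = tibble(bsj_key = keys, known = keys %in% known)
  )
  structure(
    list(genome = genome, variants = variants, known_keys = known,
         truth = truth, config = cfg),
    class = "circ_sim"
  )
}

# pick a concrete instance of an IUPAC motif (random among allowed bases)
.instantiate_iupac <- function(motif) {
  motif <- chartr("U", "T", toupper(motif))
  letters <- strsplit(motif, "", fixed = TRUE)[[1]]
  paste(vapply(letters, function(l) {
    opts <- gsub("\\[|\\]", "", .iupac_map[[l]])
    opts <- strsplit(opts, "")[[1]]
    sample(opts, 1)
  }, character(1)), collapse = "")
}

#' @export
print.circ_sim <- function(x, ...) {
  cat(sprintf(
    "<circ_sim> seed %d | %d chromosomes | %d variants over %d BSJs | %d plants\n",
    x$config$seed, length(x$genome), nrow(x$variants),
    length(unique(x$variants$bsj_key)), nrow(x$truth$plants)
  ))
  invisible(x)
}

#' Simulate polysome-fraction RT-qPCR measurements
#'
#' Converts per-target fraction-distribution shapes into a Ct table: the
#' target Ct in fraction i is `ct_ref - log2(level_i)` plus Gaussian noise
#' on the Ct scale, with reference (GAPDH) rows at `ct_ref`. The returned
#' truth records the noise-free pooled percentages.
#'
#' @param shapes Named list: target -> numeric vector of 12 positive
#'   per-fraction relative levels (any scale; only proportions matter).
#' @param noise_sd Gaussian noise standard deviation on the Ct scale.
#' @param n_rep Number of replicates to emit.
#' @param ct_ref Reference Ct (constant across fractions).
#' @param seed Optional seed applied before drawing noise.
#' @return List with `measurements` (tibble: `target`, `sample`
#'   `"F1".."F12"`, `replicate`, `ct`; includes a `GAPDH` reference
#'   target) and `truth` (tibble: `target`, `pool`, `percent`).
#' @export
simulate_qpcr <- function(shapes, noise_sd = 0, n_rep = 1, ct_ref = 20,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(shapes) > 0, !is.null(names(shapes)))
  rows <- list()
  truth <- list()
  for (r in seq_len(n_rep)) {
    rows[[length(rows) + 1]] <- tibble(
      target = "GAPDH", sample = paste0("F", 1:12), replicate = r,
      ct = ct_ref + rnorm(12, sd = noise_sd)
    )
  }
  for (tg in names(shapes)) {
    sh <- shapes[[tg]]
    if (length(sh) != 12 || any(sh <= 0)) {
      abort("each shape must be 12 positive per-fraction levels")
    }
    lv <- sh / sum(sh)
    truth[[tg]] <- fraction_distribution(lv, target = tg) |>
      dplyr::transmute(target = tg, pool = .data$pool,
                       percent = .data$percent)
    for (r in seq_len(n_rep)) {
      ct <- ct_ref - log2(lv) + rnorm(12, sd = noise_sd)
      rows[[length(rows) + 1]] <- tibble(
        target = tg, sample = paste0("F", 1:12), replicate = r, ct = ct
      )
    }
  }
  list(measurements = dplyr::bind_rows(rows),
       truth = dplyr::bind_rows(truth))
}

#' Expand 6-pool shares into a 12-fraction shape
#'
#' Convenience for [simulate_qpcr()]: given the desired share of signal in
#' each of the 6 pools (any positive scale), returns 12 per-fraction
#' levels with each pool's share split equally between its two fractions.
#'
#' @param pool_shares Numeric vector of 6 positive pool shares.
#' @return Numeric vector of 12 per-fraction levels.
#' @export
fraction_shape <- function(pool_shares) {
  if (length(pool_shares) != 6 || any(pool_shares <= 0)) {
    abort("pool_shares must be 6 positive values")
  }
  rep(pool_shares / 2, each = 2)
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa`, `circles.bed` (18-column CIRCexplorer2 dialect),
#' `known.tsv` (one canonical BSJ key per line), `truth_families.tsv`,
#' `truth_plants.tsv` and a `manifest.txt` recording the seed.
#'
#' @param sim A `circ_sim` from [simulate_circ_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "circ_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  v <- sim$variants
  bed <- tibble(
    chrom = v$chrom, start = v$start, end = v$end, name = v$name,
    score = 0L, strand = v$strand, thickStart = v$start, thickEnd = v$end,
    itemRgb = "0,0,0", exonCount = v$exon_count,
    exonSizes = purrr::map_chr(v$exon_sizes, paste, collapse = ","),
    exonOffsets = purrr::map_chr(v$exon_offsets, paste, collapse = ","),
    readNumber = v$read_count,
    circType = ifelse(v$circ_type == "exonic", "circRNA", "ciRNA"),
    geneName = v$gene, isoformName = v$isoform,
    index = seq_len(nrow(v)), flankIntron = "None"
  )
  readr::write_tsv(bed, file.path(dir, "circles.bed"), col_names = FALSE)
  writeLines(sim$known_keys, file.path(dir, "known.tsv"))
  fam <- sim$truth$families |>
    dplyr::mutate(mature_lengths = purrr::map_chr(.data$mature_lengths,
                                                  paste, collapse = ","))
  readr::write_tsv(fam, file.path(dir, "truth_families.tsv"))
  readr::write_tsv(sim$truth$plants, file.path(dir, "truth_plants.tsv"))
  writeLines(
    c(sprintf("seed: %d", sim$config$seed),
      "files: genome.fa circles.bed known.tsv truth_families.tsv truth_plants.tsv"),
    file.path(dir, "manifest.txt")
  )
  invisible(dir)
}
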