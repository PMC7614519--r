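compare_to_oracle <- function(bases) {
  got <- find_circ_orfs(circ_seq(bases), min_peptide_aa = 0) |>
    dplyr::arrange(start)
  want <- oracle_circ_orfs(bases)
  expect_equal(got$start, want$start)
  expect_equal(got$length_nt, want$length_nt)
  expect_equal(got$peptide, want$peptide)
  expect_equal(got$is_infinite, want$is_infinite)
  invisible(got)
}

test_that("a linear ORF on the circle is found without junction crossing", {
  o <- find_circ_orfs(circ_seq("ATGAAATAA"), min_peptide_aa = 1)
  expect_equal(nrow(o), 1)
  expect_equal(o$peptide, "MK")
  expect_equal(o$length_nt, 9L)
  expect_equal(o$n_junction_crossings, 0L)
  expect_false(o$is_infinite)
  expect_error(find_circ_orfs(circ_seq("AC")), "L >= 3")
})

test_that("start codons may straddle the backsplice junction", {
  # ...AT | G...  : ATG split 2+1 across the junction
  bases <- paste0("G", "AAATAG", strrep("C", 20), "AT")
  L <- nchar(bases)
  sq <- circ_seq(bases)
  o <- find_circ_orfs(sq, min_peptide_aa = 0)
  straddle <- o[o$start == L - 2, ]
  expect_equal(nrow(straddle), 1)
  expect_gte(straddle$n_junction_crossings, 1)
  # brute-force confirmation from the tripled string
  triple <- strrep(bases, 3)
  expect_equal(substr(triple, L - 1, L + 1), "ATG")
})

test_that("stop-free frames yield infinite ORFs with repeat unit L/3", {
  set.seed(219)
  s219 <- stop_free_circle(219)
  o <- find_circ_orfs(s219, min_peptide_aa = 1)
  inf0 <- o[o$start == 0, ]
  expect_true(inf0$is_infinite)
  expect_equal(inf0$repeat_unit_aa, 73L)
  expect_equal(nchar(inf0$peptide), 73L)

  s264 <- stop_free_circle(264)
  o2 <- find_circ_orfs(s264, min_peptide_aa = 1)
  expect_equal(o2$repeat_unit_aa[o2$start == 0], 88L)
})

test_that("exact scanner equals the repeated-string brute-force reader", {
  set.seed(42)
  for (i in 1:30) {
    compare_to_oracle(random_dna(sample(30:300, 1)))
  }
  # lengths in each frame-divisibility class
  compare_to_oracle(random_dna(90))
  compare_to_oracle(random_dna(91))
  compare_to_oracle(random_dna(92))
})

test_that("codon-start visit set has size L/3 when 3 | L, else L", {
  set.seed(77)
  for (i in 1:25) {
    L <- sample(30:600, 1)
    s <- sample(0:(L - 1), 1)
    cycle <- if (L %% 3 == 0) L %/% 3 else L
    visits <- unique((s + 3 * (seq_len(cycle) - 1)) %% L)
    expect_length(visits, cycle)
    # and the cycle genuinely closes: the next codon start revisits s
    expect_equal((s + 3 * cycle) %% L, s)
  }
})

test_that("rotation shifts ORF starts and changes nothing else", {
  set.seed(101)
  bases <- random_dna(150)
  sq <- circ_seq(bases)
  o <- find_circ_orfs(sq, min_peptide_aa = 0) |> dplyr::arrange(peptide)
  for (r in c(1, 7, 149)) {
    rot <- find_circ_orfs(rotate_circ(sq, r), min_peptide_aa = 0) |>
      dplyr::arrange(peptide)
    expect_equal(rot$peptide, o$peptide)
    expect_equal(sort(rot$start), sort((o$start - r) %% 150))
    expect_equal(rot$length_nt[order(rot$peptide)],
                 o$length_nt[order(o$peptide)])
  }
})

test_that("finite peptides obey length_nt/3 - 1 and junction crossing counts", {
  set.seed(55)
  for (i in 1:10) {
    L <- sample(60:400, 1)
    o <- find_circ_orfs(circ_seq(random_dna(L)), min_peptide_aa = 0)
    fin <- o[!o$is_infinite, ]
    expect_equal(nchar(fin$peptide), fin$length_nt / 3 - 1)
    expect_equal(fin$n_junction_crossings,
                 (fin$start + fin$length_nt - 1) %/% L)
  }
})

test_that("circular translation wraps modulo L and matches concatenation", {
  expect_equal(translate_circular(circ_seq("ATGAAA"), 0, 2), "MK")
  # start 4 on ATGAAA: codon starts 4, 1, 4 -> AAA, TGA, AAA
  expect_equal(translate_circular(circ_seq("ATGAAA"), 4, 3), "K*K")
  set.seed(13)
  bases <- random_dna(100)
  sq <- circ_seq(bases)
  big <- strrep(bases, 4)
  for (s in c(0, 37, 99)) {
    k <- sample(3:30, 1)
    lin <- substr(big, s + 1, s + 3 * k)
    want <- paste(toupper(seqinr::translate(strsplit(lin, "")[[1]])),
                  collapse = "")
    expect_equal(translate_circular(sq, s, k), want)
  }
})

test_that("codons containing N are opaque: translated as X, never start/stop", {
  o <- find_circ_orfs(circ_seq("NTGAAATAA"), min_peptide_aa = 0)
  expect_equal(nrow(o), 0)  # NTG is not a start
  sq <- circ_seq("ATGANATAA")
  o2 <- find_circ_orfs(sq, min_peptide_aa = 0)
  expect_equal(o2$peptide, "MX")  # ANA -> X; TAA still stops
})

test_that("tripled-concatenation scan deduplicates copies and nests in the exact scan", {
  o <- find_orfs_tripled(circ_seq("ATGTAA"), min_peptide_aa = 1)
  expect_equal(nrow(o), 1)
  expect_equal(o$peptide, "M")

  set.seed(88)
  for (i in 1:20) {
    bases <- random_dna(sample(40:250, 1))
    sq <- circ_seq(bases)
    tri <- find_orfs_tripled(sq, min_peptide_aa = 0)
    exact <- find_circ_orfs(sq, min_peptide_aa = 0)
    key_tri <- paste(tri$start, tri$length_nt)
    key_ex <- paste(exact$start, exact$length_nt)
    expect_true(all(key_tri %in% key_ex))
    m <- match(key_tri, key_ex)
    expect_equal(tri$peptide, exact$peptide[m])
    expect_equal(tri$junction_spanning, exact$n_junction_crossings[m] >= 1)
  }
})

test_that("the linearized scan cannot see infinite ORFs (documented limitation)", {
  set.seed(219)
  s219 <- stop_free_circle(219)
  tri <- find_orfs_tripled(s219, min_peptide_aa = 0)
  expect_false(0 %in% tri$start)  # no stop ever found from the frame-0 ATG
  exact <- find_circ_orfs(s219, min_peptide_aa = 0)
  expect_true(any(exact$start == 0 & exact$is_infinite))
})

test_that("nested downstream-ATG ORFs are marked and suppressible", {
  # ATG aaa ATG aaa TAA: 4-aa ORF and nested 2-aa ORF sharing the stop
  sq <- circ_seq(paste0("ATGAAAATGAAATAA", "CCCCCC"))
  o <- find_circ_orfs(sq, min_peptide_aa = 0)
  long <- o[o$start == 0, ]
  short <- o[o$start == 6, ]
  expect_equal(long$peptide, "MKMK")
  expect_equal(short$peptide, "MK")
  expect_false(long$nested)
  expect_true(short$nested)
  expect_true(endsWith(long$peptide, short$peptide))
  o2 <- find_circ_orfs(sq, min_peptide_aa = 0, include_nested = FALSE)
  expect_false(6 %in% o2$start)
})

test_that("junction-spanning filter keeps wrapped and infinite ORFs only", {
  sq <- circ_seq("ATGAAATAACCCCCCCCC")
  expect_equal(nrow(find_circ_orfs(sq, min_peptide_aa = 0,
                                   require_junction_spanning = TRUE)), 0)
  set.seed(66)
  s219 <- stop_free_circle(219)
  o <- find_circ_orfs(s219, min_peptide_aa = 0,
                      require_junction_spanning = TRUE)
  expect_true(all(o$is_infinite | o$n_junction_crossings >= 1))
  expect_true(any(o$is_infinite))
})

test_that("peptide report orders by length, writes FASTA/TSV, flags nesting", {
  sq <- circ_seq(paste0("ATGAAAATGAAATAA", "CCCCCC"),
                 bsj_key = "chr1|0|21|+", isoform = "toy_21")
  orfs <- find_circ_orfs(sq, min_peptide_aa = 0)
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  rep <- peptide_report(orfs, fasta_path = fa, tsv_path = tsv)
  expect_equal(rep$peptide_aa, sort(rep$peptide_aa, decreasing = TRUE))
  recs <- read_fasta(fa)
  expect_equal(length(recs), nrow(orfs))
  expect_match(names(recs)[1], "^chr1\\|0\\|21\\|\\+\\|toy_21\\|0\\|4\\|finite$")
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_true("nested" %in% names(back))
  expect_equal(sum(back$nested), 1)

  empty <- peptide_report(orfs[0, ], fasta_path = fa, tsv_path = tsv)
  expect_equal(nrow(empty), 0)
  expect_length(read_fasta(fa), 0)
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)), 0)
})
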