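# circvariants

Downstream analysis of circular RNA (circRNA) splice variants in R.

Backsplicing joins a downstream splice donor to an upstream acceptor and
closes an RNA into a covalent circle. The backsplice junction (BSJ) is
the signature by which circRNAs are called from RNA-seq, but one BSJ can
be shared by several isoforms that retain different internal exons —
*splice variants*. Variant identity matters because everything a circRNA
does depends on its full mature sequence, and because circular topology
creates features linear transcripts cannot have:

- **junction-spanning ORFs**, whose peptides are unique to the circle;
- **infinite ORFs** — reading frames with no stop codon, translated
  indefinitely by rolling-circle translation into repetitive
  polypeptides with a repeat unit of `L/3` amino acids when the circle
  length `L` is divisible by 3 (and `L` amino acids otherwise, since the
  codon-start cycle then visits every position);
- **junction-wrapping motifs** (e.g. the m6A consensus DRACH,
  `[AGT][AG]AC[ACT]`);
- **concatamer ladders** in rolling-circle amplification (RCA), with PCR
  products at `bsj_amplicon + (k-1)·L`, so that full-length back-to-back
  primers read out variant lengths directly as `L, 2L, 3L, …`.

`circvariants` consumes CIRCexplorer2-style annotation records (18-column
BED12+6 dialect) plus a genome FASTA and provides, as tidy tibble-in /
tibble-out operations:

| layer | functions |
|---|---|
| parsing & formats | `read_circexplorer()`, `read_fasta()`, `read_qpcr()`, catalog TSV round-trip |
| splice-variant catalog | `group_by_bsj()`, `catalog_summary()`, `splice_variant_families()`, `filter_candidates()`, `overlap_known()` |
| circular sequences | `build_mature_sequence()`, `junction_window()`, `rotate_circ()` |
| ORF enumeration | `find_circ_orfs()` (exact), `find_orfs_tripled()` (linearized cross-check), `translate_circular()`, `peptide_report()` |
| motif / amplicon features | `scan_drach()`, `scan_motifs()`, `plan_amplicons()` |
| RT-qPCR arithmetic | `delta_ct()`, `fraction_distribution()`, `polysome_share()`, `ip_enrichment()` |
| synthetic data with truth | `sim_config()`, `simulate_circ_dataset()`, `simulate_qpcr()` |

Results carry broom-style `tidy()`/`glance()` methods and ggplot2
`autoplot()`s. A packaged reference set of 15 RT-PCR/RCA-validated HeLa
backsplice junctions and their variant lengths ships as
`hela_validated_variants()`.

## Worked example

```r
library(circvariants)
library(dplyr)

catalog <- hela_validated_variants() |>
  group_by_bsj(provenance = "HeLa validated set")
glance(catalog)
#> # A tibble: 1 × 4
#>   n_variants n_unique_bsj n_genes n_families
#>        <int>        <int>   <int>      <int>
#> 1         59           15      15         15

tidy(catalog) |> filter(gene %in% c("ASPH", "CORO1C"))
#> # A tibble: 2 × 5
#>   bsj_key                     gene   n_variants mature_lengths total_reads
#>   <chr>                       <chr>       <int> <list>               <int>
#> 1 chr12|108652271|108654410|- CORO1C          4 <int [4]>                0
#> 2 chr8|61680967|61684188|-    ASPH            4 <int [4]>                0
```

59 validated variants group into 15 splice-variant families; the circASPH
family (`chr8|61680967|61684188|-`) holds variants of 219, 264, 266 and
333 nt.

Circular ORF scanning on a synthetic dataset with a planted stop-free
219-nt variant (the rolling-circle translation case):

```r
sim  <- simulate_circ_dataset(sim_config(seed = 1, plants = default_plants()))
host <- sim$variants |> filter(isoform == "PLANT02_219")
sq   <- build_mature_sequence(sim$genome, host)
find_circ_orfs(sq, min_peptide_aa = 20) |>
  select(start, peptide_aa, is_infinite, repeat_unit_aa, n_junction_crossings)
#> # A tibble: 4 × 5
#>   start peptide_aa is_infinite repeat_unit_aa n_junction_crossings
#>   <int>      <dbl> <lgl>                <dbl>                <dbl>
#> 1     0         73 TRUE                    73                    1
#> 2    59         32 FALSE                   NA                    0
#> 3   157         30 FALSE                   NA                    1
#> 4   172         25 FALSE                   NA                    1
```

The stop-free frame at position 0 is reported as an infinite ORF with a
73-aa repeat unit (219/3); a 264-nt stop-free variant gives 88 aa — an
extra 15 residues per lap. RCA amplicon prediction on a 251-nt circle
with back-to-back full-length primers:

```r
plan_amplicons(circ_seq(strrep("A", 251)), c(0, 20), c(20, 231), max_k = 3)
#> <amplicon_plan> circle 251 nt | BSJ amplicon 251 nt | ladder: 251, 502, 753
```

Polysome-fraction RT-qPCR arithmetic (12 gradient fractions pooled
pairwise into 6; pools 1–3 monosomes, 4–6 polysomes):

```r
ct <- 20 - log2(fraction_shape(c(4, 6, 10, 20, 30, 30)))
polysome_share(fraction_distribution_ct(ct, ct_ref = 20))
#> # A tibble: 1 × 2
#>   monosome_pct polysome_pct
#>          <dbl>        <dbl>
#> 1         20.0           80
```

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "circvariants",
                               load_package = "installed")'
```

The suite pits every layer against independent oracles: a brute-force
repeated-string ORF reader, nested-loop grouping, per-base sequence
reconstruction, doubled-string motif scans and circular-walk amplicon
arithmetic, plus planted-truth recovery on the synthetic generator.

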