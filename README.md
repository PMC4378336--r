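# plantmir

Discovering microRNAs in a plant species from a single deep-sequenced
small-RNA library — including species without a sequenced genome, where
a related genome stands in as the mapping reference. `plantmir` is an
end-to-end, fully testable R implementation of the standard workflow:

1. **Read cleaning** — quality gate, classification into mutually
   exclusive contaminant categories (3' adapter null, insert null, 5'
   adapter contaminant, < 18 nt, poly-A), adapter trimming, and
   collapsing into unique tags with redundant counts.
2. **ncRNA exclusion** — tags matching rRNA/tRNA/snRNA/snoRNA/mRNA/repeat
   sequences are removed.
3. **Known miRNA assignment** — end-to-end alignment against a
   miRBase-style mature database with a combined budget of ≤ 3
   mismatches + gaps; family grouping by miR numeral; family expression
   as the summed counts of tags aligning to the family's most-expressed
   member; conservation status from cross-species presence (conserved =
   seen in ≥ 9 plants).
4. **Novel miRNA discovery** — unassigned tags are exact-mapped to the
   reference genome, precursor windows excised and folded with a
   nearest-neighbour single-stem model, and candidates accepted only if
   the mature sits in one arm of a hairpin with MFE ≤ −20 kcal/mol, a
   star partner with 2-nt 3' overhangs, ≥ 16 paired mature positions and
   no bulge > 4 nt in the duplex.
5. **Target prediction** — every transcript window is scored under the
   six classical plant rules: total weighted mismatches ≤ 4 (G:U = 0.5),
   ≤ 2 contiguous mismatches, a clean 5' region (positions 2–12),
   perfect match at positions 10–11, ≤ 2.5 weighted mismatches in
   positions 1–12, and duplex energy ≥ 74 % of the perfect-complement
   energy.
6. **Stem-loop RT-PCR primer design** — a 50-nt stem-loop RT primer
   ending in the DNA reverse complement of the miRNA's last 6 nt, a
   forward primer from the first 15 bases with a GC-rich 5' extension to
   a target Tm, and a universal reverse primer from the scaffold's 5'
   region (expected amplicons 60–70 bp).

A seeded synthetic-data module generates genomes with planted hairpins,
libraries with planted contaminants, and transcriptomes with planted
target sites — each with truth tables — so every stage is checkable
offline. A worked-example dataset of jute (*Corchorus olitorius*)
seedling miRNAs is bundled (`jute_mirnas()`).

## Worked example

```r
library(plantmir)

cfg <- simulation_config(seed = 1)        # 50,000 reads, 10 planted hairpins
db  <- simulate_known_db(cfg)
gh  <- simulate_genome_and_hairpins(cfg)
lib <- simulate_library(cfg, gh$truth, db)

cleaned <- clean_library(lib$reads)
cleaned$report
#>                      type count percent
#> 1             Total_reads 50000      NA
#> 2            High_quality 49751  100.00
#> 3         3' adapter_null    32    0.06
#> 4             Insert_null     7    0.01
#> 5 5' adapter_contaminants   257    0.52
#> 6      Smaller_than_18 nt   209    0.42
#> 7                  Poly A     3    0.01
#> 8             Clean_reads 49243   98.98
```

The percentages are of the high-quality reads; the five contaminant rows
plus the clean reads partition them exactly. Continuing:

```r
tags  <- filter_ncrna(cleaned$tags, lib$exclusion_set)
hits  <- assign_known(tags, db$db)
novel <- discover_novel(unassigned_tags(tags, hits), gh$genome)
head(novel$table[, c("name", "reads", "sequence", "length", "mfe")], 3)
#>           name reads               sequence length        mfe
#> 1 col-miRN1-5p 34555  AAAUAUUUUGUUUAUCCUAUA     21 -103.02998
#> 2 col-miRN2-3p  1721 GGGGUGUGAACUGAGAGUGAAC     22  -91.37677
#> 3 col-miRN3-3p   944  UCCGUAUCGGGCUCCUAUGAC     21  -86.44887
```

`reads` counts all tags matching the mature up to 3 nt of terminal
variation (middle region exact); `mfe` is the precursor hairpin's
folding energy in kcal/mol — every accepted candidate is at or below
−20. Aligning the most abundant known jute mature against its homolog
(they are sequence-identical) and designing its validation primers:

```r
align_with_budget("UUGACAGAAGAUAGAGAGCAC", "UUGACAGAAGAUAGAGAGCAC")
#> $matches    [1] 21
#> $mismatches [1] 0
#> $gaps       [1] 0

ps <- design_primer_set("UUGACAGAAGAUAGAGAGCAC", name = "col-miR157a")
ps$stemloop_rt        # 50 nt, ends with the revcomp of ...GAGCAC
#> "GTCGTATCCAGTGCAGGGTCCGAGGTATTCGCACTGGATACGACGTGCTC"
ps$forward            # GC extension + first 15 bases, Tm >= 60 C
#> "GCGCGTTGACAGAAGATAGA"
ps$expected_amplicon
#> 70
```

`run_pipeline()` chains all stages from a YAML configuration and writes
TSV reports (cleaning summary, size distribution, known/family/novel
tables, targets with bracketed energy ratios, primers), dot-bracket
structures, a GFF3 of precursor loci and a JSON run summary. The
`exec/plantmir` script exposes `simulate`, `clean`, `known`, `novel`,
`targets`, `primers` and `all` verbs.

See `vignettes/plant-mirna-discovery.Rmd` for the models, parameter
choices and limitations.

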