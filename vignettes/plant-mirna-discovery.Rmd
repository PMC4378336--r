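---
title: "Plant miRNA discovery from small-RNA libraries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plant miRNA discovery from small-RNA libraries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantmir)
```

# The analysis

`plantmir` implements the standard computational workflow for cataloguing
microRNAs in a plant species from a single deep-sequenced small-RNA
library, in the common situation where the species' own genome is not
available and a related genome serves as the mapping reference. The
stages are:

1. **Read cleaning.** Raw reads are gated on mean Phred quality, then
   classified into mutually exclusive contaminant categories (no 3'
   adapter, empty insert, 5' adapter within the insert, insert shorter
   than 18 nt, poly-A), trimmed, and collapsed into unique *tags* with
   redundant read counts.
2. **ncRNA exclusion.** Tags matching rRNA, tRNA, snRNA, snoRNA, mRNA or
   repeat sequences are removed before any miRNA call.
3. **Known miRNA assignment.** Each surviving tag is aligned end-to-end
   against a database of mature plant miRNAs; a hit requires at most 3
   combined mismatches and gaps. Hits are grouped into families by their
   miR numeral, each family is represented by its most-expressed member,
   and family expression sums the counts of member tags that align to
   the representative within the same budget.
4. **Conservation.** A family seen in at least 9 plant species is called
   conserved; nonconserved families split into "defined" (numeral known
   to the reference table) and "undefined".
5. **Novel miRNA discovery.** Unassigned tags are exact-mapped to the
   reference genome; candidate precursor windows are excised and folded,
   and a candidate is accepted only if the mature sits in one arm of a
   stable hairpin (MFE at or below -20 kcal/mol) whose miRNA/miRNA*
   duplex has a star partner with 2-nt 3' overhangs, enough pairing, and
   no large bulge.
6. **Target prediction.** Transcripts are scanned with each miRNA under
   the six classical plant-targeting rules (at most 4 weighted
   mismatches with G:U counting 0.5; no more than 2 contiguous
   mismatches; a clean 5' region; perfect match at positions 10-11; at
   most 2.5 weighted mismatches in positions 1-12; duplex energy at
   least 74% of the perfect-complement energy).
7. **Primer design.** For validation by stem-loop RT-PCR, each mature
   gets a 50-nt stem-loop RT primer whose 3' hexamer is the DNA reverse
   complement of the miRNA's last 6 nt, a forward primer built from the
   first 15 bases with a GC-rich 5' extension, and a universal reverse
   primer from the stem-loop scaffold's 5' region.

A seeded synthetic-data module (`simulation_config()` and the
`simulate_*()` generators) produces genomes with planted hairpins,
libraries with planted contaminants and expression levels, and
transcriptomes with planted target sites, together with truth tables, so
the whole pipeline is testable offline.

# Models and numerical choices

## Alignment with a combined edit budget

"Up to 3 mismatches or gaps" is implemented as a global alignment with
unit costs for substitutions and indels, terminal gaps included, and a
single combined budget of 3. Gaps are *not* free: published
homolog-assignment tables cap gaps at 3 alongside mismatches, which is
inconsistent with unpenalised gaps. Among minimum-cost alignments the
tie-break is (more matches, fewer gaps); all three quantities are
additive along an alignment, so the dynamic program can compare them
cell-locally and stays exact.

## Hairpin folding

`fold_hairpin()` minimises free energy over *multibranch-free* nested
structures: a single stem of stacked pairs with bulges and internal
loops (total size up to 30 nt between consecutive pairs) around one
terminal loop of at least 3 nt. Multibranch structures are excluded
deliberately — every pre-miRNA candidate is a single hairpin — and the
restriction keeps the search small enough to verify against exhaustive
enumeration in the test suite.

The energy model is a compact nearest-neighbour table: 36 stacking free
energies over the six allowed pairs (Watson-Crick plus G:U wobble,
values approximating published 37 °C stacking parameters, all negative),
with logarithmic loop penalties `a + b log(size/s0)` (hairpin: a = 5.4,
s0 = 3; bulge: a = 3.8, s0 = 1; internal: a = 4.0, s0 = 2; b = 1.08
kcal/mol throughout). The table ships as a TSV resource
(`system.file("extdata", "stack_energies.tsv", package = "plantmir")`).
Under this model random-armed hairpins at the 78-350 nt precursor scale
fold in the -20 to -110 kcal/mol range reported for plant pre-miRNAs;
no attempt is made to reproduce any particular published MFE value,
since those depend on the internals of the folding engine used.

Ties in the DP are broken toward fewer pairs, then the lexicographically
smallest pair choice, so folds are deterministic. `nussinov_maxpairs()`
(the classical max-pairing recursion, bifurcations included) is kept as
an independent cross-check: under the unit model (-1 per pair, no other
terms) the single-stem optimum can never exceed it.

## Duplex energies and the 74% rule

Target duplexes are ungapped and antiparallel: miRNA position *k* faces
site position *L - k + 1*. The duplex energy sums stacking terms over
consecutive paired positions plus 0.5 kcal/mol per interior mismatch;
the perfect reverse complement therefore attains the minimum, and the
energy ratio `100 * duplex / perfect` lies in [0, 100] for any site
(rule vi passes at ratio >= 74, inclusive).

The literal statements of rules (iii) ("no mismatches at positions
2-12") and (v) ("at most 2.5 weighted mismatches in 1-12") conflict: a
literal (iii) leaves (v) nothing to tolerate. The shipped default reads
(iii) as banning *full* mismatches in 2-12 while G:U wobbles there are
tolerated subject to (v)'s 2.5 cap; `target_thresholds(strict_seed =
TRUE)` restores the literal reading. Rule (iv) is intolerant of G:U at
positions 10-11, the stricter of the two possible readings, because
cleavage-site pairing is the one region plant-miRNA rule sets never
relax.

## Novel-candidate geometry

The excision windows are 20 nt proximal / 250 nt distal around each
genomic locus of the tag (both orientations), clipped at contig ends.
The star span is derived structurally from the predicted pairing with
the Dicer offset: star = [partner(mature_end - 2), partner(mature_start)
+ 2]. "Devoid of large internal loops or bulges" is quantified as at
least 16 paired mature positions and no unpaired run longer than 4 nt
within the mature or star span; both are configuration keys
(`novel_thresholds()`), since the criterion is qualitative in the
literature. Tags mapping to more than 20 loci are set aside as
repeat-like. Novel expression counts tags whose middle region (mature
positions 4 to L-3) matches exactly and whose termini shift or vary by
at most 3 nt at either end.

## Primer thermodynamics

Melting temperatures use unified nearest-neighbour enthalpies and
entropies with duplex initiation terms and the entropic salt correction
`0.368 (n-1) ln[Na+]`. The defaults are 250 nM primer and **250 mM
monovalent-equivalent salt**: the assay the primers serve is PCR in a
magnesium-containing buffer, whose stabilising effect is well
approximated by a few hundred mM monovalent. At a plain 50 mM Na+
setting nearly every forward primer would need the maximum GC extension
to reach the 60 °C target, pushing amplicons past the 60-70 bp assay
window; at the PCR-equivalent setting typical extensions are 3-6 nt and
amplicons land in-window. The GC extension is deterministic (alternating
G/C) rather than random so that designs are reproducible. The 44-nt
stem-loop scaffold is the widely used universal backbone; both it and
the span used as the universal reverse primer are configuration keys.

# What the synthetic data does and does not emulate

The generator's defaults mirror the structure of a real plant seedling
library: an 18-30 nt tag pool with the mode at 21 nt (42.19%), 24 nt
and 20 nt next (20-24 nt jointly ~93%); contaminant rates of order
10^-4 to 5×10^-3 per category; log-normal tag counts spanning orders of
magnitude (the real dynamic range runs from single reads to millions);
hairpin precursors of 78-240 nt embedded in a random background genome;
and known-miRNA variants within 3 substitutions of their database
homologs. Precursors are capped at 240 nt rather than the observed
349 nt maximum because the 250-nt distal excision flank cannot reach a
star sitting farther away — longer planted precursors would be
unrecoverable by construction, which would test the generator rather
than the method.

Planted "spoiler" hairpins each violate one acceptance criterion by
construction (mature straddling the loop; a 6-nt deletion opposite the
mature creating a large duplex bulge; A/U-only arms chopped into short
stacking runs that cannot reach -20 kcal/mol). Structural criteria are
coupled — a loop-straddling mature usually also loses its star — so
truth labels record the *intended* violation and tests assert rejection
plus that flag, not exclusivity.

Deliberately not emulated: sequencing errors beyond terminal isomiR
shifts, quality-score variation (constant Q40, with a planted
low-quality class), multi-locus miRNA genes, genome polymorphism
between the library's species and the mapping reference, and any
transcriptome annotation semantics (the annotation join is a generic
category count). Passing the planted-truth suites therefore shows the
*method* is implemented correctly, not that real libraries will be this
clean: in real data the proxy-genome mismatch alone removes tags that a
native genome would rescue.

# Problem sizes in the test suite

Unit tests run a scaled-down simulation (8,000 reads, 4 conforming and
3 spoiler hairpins, 8 known families, 20 kb genome). The acceptance
suite runs the default study scale: 50,000 reads, 10 conforming plus 3
spoiler hairpins in a 50 kb genome, 20 known families across up to 12
species, 10 transcripts of 2 kb with 10 compliant and 4 single-rule
violating target sites. Oracle equivalences use exhaustive enumeration
up to 18 nt for folding, 1,000 random pairs for alignment, and 10,000
random duplex configurations for the target rules. The full suite
completes in about a minute on one CPU.

# Known limitations

- The fold search excludes multibranch structures; a genomic window
  whose true optimum is multibranched is evaluated against its best
  single stem, which is conservative for hairpin calling but means the
  reported MFE is not a general-purpose folding energy.
- Known-miRNA assignment is mature-only; precursor-level evidence for
  known miRNAs is not used.
- Family grouping is by miR numeral (with the standard super-family
  aliases miR157→miR156, miR165→miR166); no sequence clustering is done
  beyond the assignment itself.
- Expression quantification assigns each tag to at most one family
  representative; isomiR sub-classification is out of scope.
- The ncRNA filter is an exact substring/equality match against the
  exclusion set, not a similarity search.

```{r example, eval = FALSE}
# end-to-end on synthetic data
cfg <- simulation_config(seed = 1)
db  <- simulate_known_db(cfg)
gh  <- simulate_genome_and_hairpins(cfg)
lib <- simulate_library(cfg, gh$truth, db)

cleaned <- clean_library(lib$reads)
tags    <- filter_ncrna(cleaned$tags, lib$exclusion_set)
hits    <- assign_known(tags, db$db)
fams    <- group_and_quantify(hits, tags)
novel   <- discover_novel(unassigned_tags(tags, hits), gh$genome)
```
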