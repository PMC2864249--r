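---
title: "Comparative plant miRNAome profiling: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plant miRNAome profiling: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnaome)
```

# The problem

Deep sequencing of the small RNA fraction of two related samples — here
generically "library A" and "library B", e.g. a wild-type fruit and a
mutant — yields millions of 18–30-nt reads. Turning them into a
comparative miRNAome takes five steps, each of which this package
implements as an explicit, testable operation:

1. **Read processing** — adapter-anchored trimming and collapsing into
   unique *signatures* with per-library counts.
2. **Annotation** — hierarchical classification against a non-coding RNA
   catalogue, a transcript set, and a mature miRNA catalogue.
3. **Novel miRNA discovery** — candidate precursor windows around perfect
   transcript matches, stem-loop folding, plant-miRNA structural
   criteria, and the decisive biogenesis evidence: the miRNA\* (the
   duplex partner of the mature) must itself be sequenced.
4. **Differential profiling** — TPM normalisation and a two-proportion
   Z test on raw tag counts.
5. **Target analysis** — plant-style complementarity scoring of miRNA
   sites on transcripts, and "hotspot" statistics of small RNAs arising
   from predicted target genes.

A synthetic-data generator produces all inputs with known ground truth,
so every stage can be scored for recovery.

# Read processing

Trimming anchors on the exact **last 7 nt of the 5' adapter** and the
exact **first 7 nt of the 3' adapter**; the insert is the substring
strictly between the first occurrence of the 5' anchor and the first
occurrence of the 3' anchor after it. Reads missing either anchor, or
with an empty insert, are rejected with a reason code. One consequence
worth knowing: an insert that happens to contain the 3' anchor heptamer
internally (about 0.1% of random 18–30-mers) is truncated at it. This
is inherent to anchored trimming, not a defect, and the tests assert it
explicitly.

Collapsing drops sequences with ambiguous characters, keeps lengths in
`[min_len, max_len]` (defaults 18 and 30), and retains a signature only
if its count reaches `min_count` (default 3) **in at least one
library**. The count rule is stated two ways in the field's
descriptions of this design ("below 3 in both libraries" removed versus
"more than 3 used"); we implement the at-least-one-library reading,
which describes the realised datasets, and make the threshold
configurable. Library sizes are recomputed after all filters and are the
denominators of every downstream normalisation.

The internal alphabet is DNA (U normalised to T); every report emits RNA
(U), following the mature-miRNA catalogue convention.

# Annotation hierarchy

Classification is sequential exclusion, in this order: **rRNA/tRNA/
snRNA/snoRNA → known miRNA → novel-miRNA discovery → coding
sense/antisense → other**. Non-coding classes match as exact substrings
of class-tagged reference records (precedence rRNA > tRNA > snRNA >
snoRNA when one signature hits several). Coding matches are exact
substrings of a transcript (sense) or its reverse complement
(antisense); a signature matching both orientations is tallied in both
but carries the sense primary category. The ordering when a signature
would match both an ncRNA and a known miRNA is not fixed by common
practice; we remove ncRNA first, which matches the usual workflow
narrative, and flag it as an interpretation.

Known-miRNA assignment uses an **ungapped sliding alignment over all
offsets**: the distance is the mismatch count in the overlap plus one
per unaligned overhang position, minimised over offsets; a signature is
assigned when the distance is at most `max_mm = 4` (the conventional
"identical or with four or fewer mismatches" homology bound). Ties break
by fewest mismatches, then lexicographically smallest reference id, so
the assignment is stable under reference reordering. Families are the
`miR<number>` token of the reference header.

The per-category summary reports, per library, distinct signatures,
total reads, percentages, and the mean frequency (total/distinct) — the
identity `mean frequency × distinct = total` is asserted in the tests
and reproduces the worked numbers of the published summary tables
(e.g. 61,993 reads over 667 distinct known-miRNA signatures give 92.94).

# Folding engine and hairpin criteria

The discovery stage only needs folding to test **stem-loop geometry**,
not free energies. We therefore use maximum-weight nested base pairing
(Nussinov-style dynamic programming): Watson–Crick pairs weigh 1, G:U
wobbles weigh `wobble_weight` (default 1), hairpin loops keep at least
`min_loop = 3` unpaired bases, and the traceback is deterministic — in
every subproblem the 5'-most base pairs its 3'-most admissible partner
whenever pairing achieves the optimum. The DP is exact: on sequences
short enough to enumerate every nested structure explicitly (≤ 14 nt)
its score equals the enumeration maximum, which the acceptance suite
checks on 200 random sequences. Thermodynamic ΔG values are **not**
estimated; an external thermodynamic folder can be used as an optional
cross-check but is never a dependency.

Candidate precursors are windows around each perfect transcript match
of an unannotated 20–24-nt signature (plant mature miRNA lengths;
configurable). Three flank configurations — (100, 20), (20, 100) and
(60, 60) nt — bracket matures sitting near either precursor end;
windows are clipped at transcript ends and deduplicated. Matches to the
reverse complement are evaluated on the reverse-complemented window,
with coordinates reported on the forward transcript.

**Duplex evaluation** works through a single geometric projection. In a
canonical miRNA/miRNA\* duplex both strands carry 2-nt 3' overhangs, so
every paired duplex position of the mature implies the star's two
boundaries. Each boundary takes the most frequent projection from the
half of the duplex nearest to it; the dominant side of the partners
defines the arm (5p/3p). A position's deviation from the dominant
register is precisely the asymmetric-bulge size at that point, so
positions with |deviation| > `max_asym_bulge` (default 2) — or unpaired
positions, or positions pairing outside the projected star — count as
duplex mismatches, bounded by `max_duplex_mm` (default 4, over the
mature minus its canonical overhang). The whole mature must keep a
paired-and-consistent fraction of at least `min_paired_frac` (default
0.60), and a projected star overlapping the mature marks a
loop-spanning mature, which is rejected. These thresholds encode the
community's structural conventions for plant miRNA annotation; they are
deliberately configurable because the conventions are stated
qualitatively in the literature.

This projection design is what makes evaluation robust on real windows:
a global pair-maximisation fold frays helix ends (dropping a terminal
duplex pair is profitable whenever both freed bases can pair
elsewhere), so requiring every mature partner to sit in one contiguous
block would misclassify good hairpins. On the generator's planted
genes, where the ground-truth star is constructed analytically, the
projected star equals the analytic star exactly — the test suite closes
this loop for every planted gene.

**Calling** requires the star sequence to be present in the signature
table (exact match, count ≥ 1 in either library — which, given the
collapse filter, means it was sequenced at least `min_count` times in
one library). One call is kept per distinct mature (best fold score).
Because a sequenced star is itself a perfect transcript match that
passes the same criteria with the roles swapped — and the reverse
complement of a hairpin region is the same locus — accepted calls that
overlap on a transcript (either strand) are collapsed to one call, and
the most abundant arm is reported as the mature, the standard
convention for miRNA/miRNA\* arm assignment. Masking candidate windows
that overlap known-miRNA loci (the matches of catalogue-assigned
signatures) precedes discovery, as in standard novel-miRNA pipelines.

# Differential profiling

Counts are compared with the classical two-library tag-proportion
Z statistic. With $\hat p_1 = x_1/N_1$, $\hat p_2 = x_2/N_2$ and pooled
$\hat p_0 = (x_1+x_2)/(N_1+N_2)$:

$$ z = \frac{\hat p_1 - \hat p_2}
  {\sqrt{\hat p_0 (1-\hat p_0)\left(\tfrac{1}{N_1} + \tfrac{1}{N_2}\right)}} $$

with a two-sided normal p value; $x_1 = x_2 = 0$ gives $z = 0, p = 1$
by convention. The test runs on **raw counts** — its variance model
requires them — while TPM ($x/N \times 10^6$) is used for reporting and
fold changes (max/min with a direction flag; one-decimal reports use
round-half-away-from-zero, which reproduces the published tables'
arithmetic, e.g. 1248.5/220.1 = 5.672 → 5.7). Significance defaults to
raw p < 0.01 with no multiple-testing correction, mirroring
single-library-pair practice in this design; a Benjamini–Hochberg
column is available behind a flag. Note that the statistic is not
scale-free: multiplying counts and library sizes by $c$ multiplies $z$
by exactly $\sqrt c$.

The count-level calibration simulator draws per-gene abundances
log-uniformly on 50–2000 TPM by default — chosen so expected counts per
million-read library stay ≥ 50, the regime where the normal
approximation underlying the test is trustworthy; at lower counts the
discreteness of the tails makes any nominal level claim fragile. Under
this null (1000 genes, fold effect 1, three seeds) the empirical
type-I rate at α = 0.01 sits within Monte-Carlo error of 0.01.

# Target scoring

Plant miRNA targets are near-perfect complements, so prediction is
penalty scoring of every transcript window against the miRNA: match 0,
G:U wobble 0.5, mismatch 1, gap/bulged base 2, all penalties doubled at
miRNA positions 2–13 from the 5' end; at most one single-nucleotide
bulge per duplex (one extra target base, or one unpaired miRNA base).
For each start position the best variant is kept; hits score ≤ `cutoff`
(default 4.0, the common plant threshold — the original web tools'
cutoff is unstated, so this is an explicit instantiation, not a claim of
identical hit lists). The scanner is exact: it equals a brute-force
all-window oracle, asserted on random transcripts. A
`duplex_pseudo_energy` column (weighted pair count) is provided as a
diagnostic only; it is not a hybridisation energy.

Hotspot statistics classify each predicted target gene, per library, by
whether perfectly matching signatures exist in sense, antisense, both
or neither orientation. Published summaries of this kind count
"producing sense" inclusively of "both", so the summary emits inclusive
and exclusive tallies side by side, with percentages over the
target-gene set, plus the fraction of antisense-bearing genes with
cognate sense signatures.

# The synthetic study and what it does (not) show

`simulationConfig()` defaults define the study conditions: two libraries
of 2×10⁵ reads; 30 transcripts of 400–1200 nt; 20 planted miRNA genes
(10 in the catalogue = "known", 10 withheld = "novel"); 8 class-tagged
ncRNA references; an insert length distribution over 18–30 nt with 92%
of mass at 21–24 nt and 55% at 24 nt (the shape of plant libraries
dominated by 24-nt heterochromatic siRNAs); 1% adapter-free junk reads;
star arms carrying 20% of each gene's reads (matching the observed
ratio of mature to star abundances in fruit libraries, e.g. ~90 vs ~26
TPM); per-gene abundances log-uniform on 200–2000 TPM, the range where
miRNA\* detection is expected at this depth — the discovery criteria are
*meant* to be exercised with sequenced stars, and star sampling below
~8 expected reads would conflate sampling noise with the gating logic,
which a dedicated star-ablation check covers instead.

Three generator choices are deliberate realism decisions rather than
conveniences, and they matter:

* **Planted precursors have extended stems.** The mature/star duplex
  (star constructed analytically as the reverse complement of the
  mature core plus a 2-nt 3' overhang — never by folding, so ground
  truth is independent of the folder under test) is embedded in an
  imperfect lower stem (12% point mismatches) with short unstructured
  tails, the architecture of real plant pre-miRNAs. Embedding the
  duplex in long *random* flanks instead lets global pair maximisation
  assemble competing structure that misfolds ~10% of planted hairpins —
  a property of random RNA, not of precursors.
* **Background small RNAs are clustered.** Transcript-derived
  background comes from discrete producing loci (Poisson-distributed
  anchors per transcript, strand-specific, long-tailed weights, ±4-nt
  start jitter), as real libraries show, rather than uniform tiling.
  Uniform tiling at desk-scale depth covers every position several
  times and thereby fabricates "miRNA\*" evidence for arbitrary folding
  windows — an artifact no real library exhibits.
* **Dark matter is a finite pool.** Reads matching no reference come
  from a fixed hidden pool with long-tailed weights (so they survive
  the count filter, as real unannotated sRNAs do), length-stratified so
  the realised length distribution matches the configured weights.

Junk reads are random sequences without adapters, exercising the
trimming rejection path. Reads are
`adapter tail + insert + adapter head + random fill` at 50 nt with
constant quality — the generator emulates *composition*, not sequencing
error; quality-based filtering, positional degradation bias and
genome-scale references are explicitly out of scope. Passing recovery
tests therefore demonstrate the pipeline's logic and calibration, not
robustness to base-call errors or to genomic repeat structure.

With fixed seed the generator is byte-reproducible, and the whole
pipeline is deterministic given its inputs, so the end-to-end bundle is
byte-identical across reruns (asserted in the tests).

# Problem sizes and numerical choices

The shipped tests and the acceptance script run the full pipeline on
2×10⁵-read libraries (≈25 s), calibrate the null on 3×1000 genes at
10⁶ tags, compare the folding DP with explicit structure enumeration on
200 sequences of ≤ 13 nt, and check the target scanner against the
brute-force oracle on 50 transcripts of 200–700 nt — sizes chosen so
the whole validation cycle stays in the minutes range on one CPU while
every check retains its discriminating power. Floating-point score
comparisons use an absolute tolerance of 10⁻⁹; fold tracebacks,
tie-breaks and table orderings are all deterministic so that equality
assertions on whole output files are meaningful.

Degenerate inputs are defined, not accidental: empty libraries collapse
to an empty table; a table with no matches yields zeroed summaries;
`x1 = x2 = 0` gives z = 0, p = 1; fold change with one zero side is
flagged exclusive rather than computed; a mature whose projected star
leaves its window fails that window but may pass another flank
configuration.

# Known limitations

* Max-weight pairing is a geometric test, not thermodynamics; precursor
  structures and any ΔG-based filtering of the original tools are not
  reproduced.
* One library per condition: the Z test inherits the classical
  assumption that a tag's sampling is binomial within a library;
  replicate-aware dispersion modelling is out of scope by design.
* The target scorer is an explicit instantiation of the published
  penalty conventions, configurable but not guaranteed to match any web
  service's hit list.
* Known-miRNA homology is ungapped; indel isoforms beyond the sliding
  offset model are not matched.
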