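---
title: "Methods: pan-genome gene family analysis with panfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome gene family analysis with panfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panfam)
```

## Scope

`panfam` reconstructs and characterises a plant gene family across a
pan-genome of inbred-line assemblies — the setting is a family such as the
maize dirigent genes surveyed across the 26 NAM founder assemblies, but
every stage is parameterised and works on any per-genome collection of
(FASTA, GFF3, profile-HMM domain hits). The pipeline runs:
identification → orthogroup refinement → occupancy classification and
saturation → Ka/Ks selection screening → promoter cis-element profiling →
tandem duplication → association-window candidates → haplotype-by-cluster
summaries → expression profiles. A synthetic pan-genome generator with
planted ground truth makes the whole chain testable without any external
data.

Out of scope by design: running HMMER/OrthoFinder/MCScanX themselves,
cross-species synteny, subcellular-localisation prediction, GWAS model
fitting, and coordinate lift-over. The package starts from their tabular
outputs.

## Family identification

Domain hits (HMMER `--domtblout` dialect) are filtered on the per-domain
*independent* E-value at an inclusive threshold, default `1e-5`. The
independent E-value is used rather than the full-sequence one because the
decision is per domain: a gene carrying two tandem family domains should
contribute both hits, not a single pooled score.

Each passing gene contributes one protein: the transcript with the longest
total CDS is the representative (annotation pipelines disagree on isoform
order, and family censuses count genes, not isoforms; ties break to the
lexicographically first transcript id). CDS segments are spliced in
transcript orientation; the promoter is the 2,000 bp 5' of the CDS start
(not the transcript start — family censuses of this kind profile the
region proximal to the coding start), truncated and flagged at contig
edges. Genes whose representative CDS contains an internal stop are
excluded with a warning rather than silently translated.

Physicochemical properties use ExPASy average residue masses (+ one
water), the Kyte–Doolittle hydropathy scale for GRAVY, the Guruprasad
dipeptide weights for the instability index, and the EMBOSS pKa set for
the isoelectric point, solved by bisection of the Henderson–Hasselbalch
net charge on [0, 14] to |charge| < 1e-4. The charge function is strictly
decreasing in pH, so the zero is unique and the bracket always valid.
"Hydrophilic" is defined as GRAVY < 0.

Contigs whose (case-folded) name fails the chromosome pattern
(`^chr[0-9]+$` by default) are flagged `on_scaffold`.

## Orthogroup refinement

The input is either an external orthogroup table (OrthoFinder
`Orthogroups.tsv` dialect) or, absent that, a de novo single-linkage
clustering. Either way, the refinement rule is the same: within each
group, compute all pairwise protein identities; connect two genes when
identity ≥ the threshold (default 90%); connected components become the
refined orthogroups; components of size 1 become singletons, since an
orthogroup must have at least two members.

Identity is percent identical columns over the *global* alignment length
(Needleman–Wunsch, BLOSUM62, gap open 10, gap extend 0.5), with gap
columns counted in the denominator — the conservative, symmetric reading
of "pairwise similarity". Two numerical choices matter:

* **Symmetry under ties.** Optimal global alignments are not unique; the
  traceback chosen can depend on which sequence is the DP "pattern". The
  argument order is therefore canonicalised (the lexicographically
  smaller sequence is always the pattern), which makes
  `identity(a, b) == identity(b, a)` exact and the batched all-pairs
  matrix identical to single-pair calls.
* **Single linkage.** "Genes with similarity < 90% are subgrouped" is a
  graph statement; connected components are the unique parameter-free
  rule consistent with it. The consequence — a 60%-identical pair can
  share a group through a 95% chain — is intended and tested.

The de novo path is documented as *not* equivalent to MCL-based orthology
inference; it is a fallback so the pipeline runs without external tools.

## Occupancy classes and saturation

The orthogroup × genome presence matrix has a 1 where an orthogroup has
at least one member from that genome. With `n` genomes, categories are:
core (`k = n`), softcore (`soft_min ≤ k < n`), shell, and variable
(`k ≤ var_max`). At `n = 26` the cut-offs are softcore from 24 and
variable up to 5; for other `n` they generalise as `ceil(0.92 n)` and
`floor(0.20 n)`, chosen to reproduce the absolute values exactly at
`n = 26`.

The saturation (rarefaction) curve bootstraps, for each subset size `s`,
1000 uniform subsets of `s` *distinct* genomes and counts the fraction of
orthogroups discovered. The estimator's exact expectation is closed-form:
an orthogroup present in `k` genomes is missed by a random `s`-subset
with probability `C(n-k, s) / C(n, s)`, so

> E[fraction] = mean over orthogroups of 1 − C(n−k, s)/C(n, s).

The bootstrap is validated against this expectation (within Monte-Carlo
error), and `find_min_s()` reports the smallest `s` whose expectation
reaches a target (default 0.9). Saturation is counted at orthogroup-level
presence, not gene-level copy number: the question the curve answers is
how many genomes are needed to *discover* the orthogroups. The reported
value depends on the occupancy mix of the data at hand.

## Ka/Ks (NG86)

Pairs of coding sequences are compared on protein-guided codon
alignments: proteins are globally aligned (same scoring as above) and the
codons threaded back (residue gap → `---`). Gapped, ambiguous and stop
codon columns are dropped pairwise. The estimator is Nei–Gojobori (1986)
with equal-weight pathway averaging:

* **Sites.** At each codon position the three alternative nucleotides are
  examined; mutations creating stop codons are excluded from the
  denominator, and the synonymous fraction of the remaining changes
  accumulates into S, with N = 3·codons − S; S and N are averaged between
  the two sequences.
* **Differences.** A codon pair differing at `d` positions is resolved by
  averaging the synonymous/nonsynonymous step counts over all `d!`
  substitution orders. Orders passing through a stop codon are excluded;
  if every order is excluded, all orders are used (the standard
  fall-back, which keeps Sd + Nd = d exact).
* **Correction.** pS = Sd/S and pN = Nd/N are Jukes–Cantor corrected,
  `K = -3/4 ln(1 - 4/3 p)`. When p ≥ 3/4 the correction diverges and the
  result is flagged `saturated`; Ks = 0 flags the ratio `ks_zero`.
  Undefined ratios are reported as a status column, never as numeric
  infinities, so per-orthogroup medians stay well defined.

NG86 was chosen over ML estimators (YN00/GY94) because it is the
canonical counting default, closed-form, and verifiable against an
exhaustive pathway-enumeration oracle — which the test suite does for all
61 × 61 sense codon pairs, exactly. Site/difference tables for the 61
sense codons are precomputed once per session, so long alignments reduce
to table lookups.

Per orthogroup, all cross-genome pairs are estimated (same-genome
paralog pairs optional) and summarised by the median defined ratio and
the fraction of pairs with ratio > 1, flagging orthogroups with any
positively selected pair.

## Promoter cis-elements

The scanner counts exact IUPAC matches of a packaged ~30-element motif
table (ABRE, CGTCA-motif, TGACG-motif, G-box, TATA-box, …; categories
hormone/stress/light/development/core) on both strands of each 2 kb
promoter; overlapping matches all count, and an `N` in the scanned
sequence matches nothing. The table is an editable TSV convention — it is
explicitly *not* a reproduction of the PlantCARE catalogue, and absolute
motif counts from web tools are not comparable. Per orthogroup, the
category profile is the fraction of members with at least one hit in the
category. The scanner is validated against a naive sliding-window oracle
and by strand symmetry (`scan(seq) == scan(revcomp(seq))`).

## Tandem duplication and association windows

Tandem detection uses annotation rank: every gene's position among *all*
annotated genes of its chromosome. Two family genes are tandem-linked
when they share an orthogroup and chromosome with at most
`max_intervening` (default 5) genes between their ranks; clusters are the
transitive closure. This is a documented stand-in for collinearity-based
callers, whose numeric criterion the survey setting does not pin down, so
absolute tandem counts are conventions of this rule.

Candidate genes for association signals keep signals with score (a
resample model inclusion probability) ≥ 0.05 and report every gene whose
interval extended by ±100 kb contains a signal position, inclusive at
both edges ("within 100 kb" reads inclusive); distance is 0 inside the
gene, else bp to the nearest edge. Genes and signals must share one
assembly version; lift-over is out of scope and no attempt is made to
detect mismatched versions beyond unknown chromosome names (warned and
skipped).

## Haplotypes across breeding clusters

Variant calls are read from a minimal GT-only VCF; in inbred material a
homozygous diploid call collapses to one allele index and heterozygous or
missing calls become missing. A gene's haplotype string concatenates
allele indices over the gene-body variant sites in position order (flank
0 bp by default; exposed). Lines with any missing call in the region are
excluded and counted. Haplotypes below `min_count = 2` merge into a
"rare" class; names Hap1, Hap2, … follow descending frequency with
lexicographic tie-breaks.

Cluster skew is quantified — the underlying studies describe it only
qualitatively — by a labelled package convention: for each haplotype,
the chi-square statistic of its cluster counts against the cluster
marginals; the gene's score is the maximum over haplotypes divided by the
number of counted lines; significance comes from shuffling cluster labels
(999 permutations, seeded), with p = (1 + #≥obs)/(perms + 1), which is
valid (never below 1/(perms+1)) and reproducible.

## Expression

FPKM is `counts × 1e9 / (column_total × length)`, with the library size
taken as the within-matrix column sum — mapped-read totals from upstream
alignment are not available at the package boundary, which is a
documented deviation from alignment-time FPKM. Tissue profiles report
per-tissue means and per-gene z-scores of `log2(mean FPKM + 1)` across
tissues (constant rows get z = 0, all-zero genes get NA). Stress response
is `log2((mean treated + 1)/(mean control + 1))` per organ; "induced"
means log2FC ≥ 1. The pseudocount and threshold are conventions for a
qualitative induction call; the pseudocount shrinks fold-changes of
weakly expressed genes toward 0, visible in the validation summaries.

## The synthetic pan-genome generator

`simulate_pan_genome()` emits per-genome FASTA + GFF3 + domtblout files
and the planted truth; `simulate_population()`, `simulate_signals()` and
`simulate_counts()` cover the population, association and expression
inputs; `simulate_study()` chains all four under one seed and writes a
pipeline manifest.

Default scale mirrors the surveyed family: 26 genomes, ~70 orthogroups
with presence probabilities giving ~47 family genes per genome, core
genes just above 40% of the total and ~3% variable, small tandem arrays,
~1/6 of genes carrying the lectin co-domain, one variable orthogroup on
an unplaced scaffold, plus interleaved background genes (a fraction of
which carry above-threshold decoy hits that a correct E-value filter must
reject).

The codon model is deliberately the process NG86 assumes: an ancestral
codon sequence per orthogroup evolves independently down each genome;
every attempted substitution is kept if synonymous, kept with probability
min(1, ω) if nonsynonymous, and redrawn if it would create a stop. With
no transition/transversion bias, planted ω ≤ 1 is recoverable by the
estimator under its own model — which is exactly what the recovery tests
measure. Values ω > 1 cannot be realized by an accept/reject filter and
are not planted.

Promoters are uniform background with planted motif instances: `rate` is
the probability a promoter receives one guaranteed instance (position
uniform, IUPAC codes resolved randomly), so a rate-1.0 orthogroup has
category proportion exactly 1 and lower rates are binomially
recoverable. Background sequence can still produce chance hits — for
short motifs routinely, for 12-mers at ~2·L/4^12 per promoter — so
scanned counts are only bounded below by planted counts.

Population haplotypes mix a cluster-owned haplotype (weight = skew) with
a uniform pool; skew 1 makes each cluster own one haplotype exactly and
skew 0 is the exchangeable null used to check the permutation test's
validity. Counts are negative binomial (dispersion 0.05, 3 replicates)
around length-scaled lognormal baselines with planted root-specific
(8-fold) and salt/mannitol (log2FC 2) effects.

What the generator does **not** emulate: real chromosome structure,
transposons, recombination, annotation errors, alignment noise in the
domain scores, population LD structure, or library-size variation between
conditions. Passing the planted-truth suite therefore demonstrates the
*algorithms* are correct under their own assumptions, not that any
biological conclusion transfers to real assemblies.

## Validation scale and reproducibility

The shipped validation runs at desk scale, chosen so the whole suite
exercises every stage in minutes: planted-ω recovery uses 3 orthogroups ×
20 genomes × 300 codons (190 pairs per ω ∈ {0.2, 0.5, 1.0}); saturation
uses a 40 × 26 planted matrix at 1000 bootstrap replicates; motif-oracle
equivalence uses 1000 random 2 kb promoters; the haplotype power check
uses 150 lines in 7 clusters; the end-to-end determinism run uses a
5-genome study executed twice. Every stochastic step takes an explicit
seed, every output table carries a header with version, seed and
parameters, and rerunning any stage under the same seed reproduces
byte-identical files.

## Known limitations

* De novo clustering is single-linkage on identity; it will not
  reproduce MCL orthology on distant or chimeric families.
* NG86 has no transition bias or codon-frequency correction; on real
  data it under/over-counts relative to ML estimators at high divergence.
* The motif table is a convention; category proportions are comparable
  within a run, not against web-tool catalogues.
* The tandem rule depends on annotation completeness through gene ranks.
* FPKM from column sums differs from mapped-total FPKM when the matrix
  is a gene subset; comparisons should stay within one matrix.
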