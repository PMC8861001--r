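---
title: "Methods: SPL family identification and miR156 ceRNA network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SPL family identification and miR156 ceRNA network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(splnet)
```

# Scope and model

`splnet` analyses the miR156–SPL regulatory module across an ordered
four-stage developmental series (default stage labels Li, La, Ov, Bo — the
linear-to-broad-ovate leaf progression of heterophyllous poplars). The
biological model it operationalizes has three ingredients:

1. **The SPL family is defined by its domain.** A transcription factor is
   accepted as an SPL only if it is homologous to known family members
   *and* carries a complete SBP DNA-binding domain; alternative-splicing
   products of one locus are collapsed to a single canonical protein.
2. **miR156 represses SPL mRNAs.** Family members carry miR156 response
   elements (MREs); miR156 abundance declines across the stage series
   while its SPL targets rise.
3. **ceRNAs de-repress SPLs.** lncRNAs and circRNAs carrying the same MRE
   as an SPL mRNA can sponge miR156. A ceRNA–miR156–mRNA triad is called
   in a stage contrast when the pair shares an MRE, their expression
   profiles are positively correlated, both move in the same direction at
   a fold-change threshold, and the shared miRNA moves in the opposite
   direction.

# Family identification

## Homology screen

The screen wraps an exact Smith–Waterman local alignment (BLOSUM62, affine
gap cost 11 + L, the classic BLASTP parameterization). A candidate is
retained when its best reference hit reaches **identity ≥ 0.80 over the
aligned columns** (gap columns count in the denominator; the threshold is
inclusive) and **E < 10⁻⁵** (strict), with E = K·m·n·e^(−λS) using the
ungapped BLOSUM62 constants λ = 0.3176, K = 0.134 applied to the local
score. This is a transparent, oracle-testable stand-in for a BLASTP search:
the thresholds, not the search heuristics, are the contract. Identity is
computed over the aligned region (not the full query) — the choice that
makes a conserved domain in a divergent protein detectable.

## Domain scan

Pfam-style HMM matching is replaced by an ungapped position-specific score
matrix of fixed width W = 76 whose column *j* is the BLOSUM62 row of the
consensus residue *j*. The bundled consensus is **synthetic** (see
`inst/extdata/sbp_domain_consensus_synthetic.txt`): it reproduces the
hallmark architecture of the plant SBP domain — two Cys/His zinc-binding
clusters and a basic, NLS-like C-terminal stretch — but is not the Pfam
seed. Any consensus can be supplied to `sbp_profile()`.

The scan scores every full-width window plus *partial terminal windows*
(≥ 10 profile columns truncated by a sequence end). The best hit's
`full_length` flag is `TRUE` only when the window covers all W columns
inside the sequence; family membership requires it. This gives the
full-length criterion observable content: a protein ending mid-domain
produces a strong partial hit that is still rejected.

## Redundancy

`deduplicate_isoforms()` keeps the longest isoform per locus,
lexicographically smallest identifier on ties. The redundancy rule is
deliberately simple; the generator plants isoform groups so the rule is
testable against truth.

# Physicochemical profiles

`physchem_profile()` reproduces the ProtParam conventions: average (not
monoisotopic) residue masses plus one water for the molecular weight;
GRAVY as the mean Kyte–Doolittle hydropathy; the Guruprasad instability
index II = (10/L)·Σᵢ DIWV(xᵢ, xᵢ₊₁) with the published 20×20 dipeptide
weight table bundled as a fixture (proteins with II > 40 are classed
unstable); and the theoretical pI by bisection of the
Henderson–Hasselbalch net charge over pH 0–14 using Bjellqvist-type pKa
values (side chains D 4.05, E 4.45, C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0;
C-terminus 3.55; residue-specific N-terminus, default 7.5). The charge
curve is strictly decreasing in pH, so the root is unique; bisection stops
at |Q| < 10⁻⁶, comfortably inside the 10⁻⁴ contract checked by the tests.
Proteins with pI < 7 are classed acidic, otherwise alkalescent; the
boundary case pI = 7 does not arise in practice and the midpoint rule is
documented rather than tuned. A single residue has no dipeptides: the
instability index is returned as `NA` and flagged.

# Phylogeny

Because every accepted SPL carries a full-width domain window, the
extracted windows are mutually aligned by construction and feed the tree
directly; no multiple sequence alignment is performed (a deliberate scope
decision — domain windows are the phylogenetically conserved, equal-width
portion). Distances are p-distances with pairwise gap deletion, the
simplest protein option of the standard tree packages; pairs with no
comparable columns are an error, not a silent zero. Trees are built by
Saitou–Nei neighbor joining; on additive distances the topology and branch
lengths are recovered exactly (a property the test suite exercises against
a least-squares brute force over all 5-taxon topologies). Negative
branch-length estimates, which NJ can produce on noisy input, are clamped
to zero with a warning.

Bootstrap supports resample alignment columns with replacement (default
1000 replicates, per standard practice for family trees); the support of
an internal edge is the percentage of replicate trees containing the same
leaf bipartition, stored as internal node labels so Newick round-trips
preserve them. Leaves can be flagged by MRE presence
(`annotate_mre_class()`), the split used to subdivide the family's class II
clade, and `deepest_split()` reports the two clades flanking the
longest internal edge as an automatic subgroup proxy.

# Expression

Three per-million conventions match the three biotypes: FPKM for mRNA and
lncRNA (length-normalized fragments), TPM for miRNA (within-library
relative abundance; columns sum to 10⁶ by construction), RPM for circRNA
back-splice junction reads (no length normalization — a junction is a
point feature). Stage contrasts are log₂ ratios of replicate means with a
pseudocount (default 1) on both sides; the categorical fold bins used for
network annotation are A (1,2], B (2,5], C (5,10], D (>10) on the linear
fold magnitude, upper bounds inclusive, `none` at exactly fold 1.

Differential expression is deliberately *not* a reimplementation of a
count-model test: the pipeline's gate is |log₂FC| ≥ 1 (bin A or beyond) on
stage means. The networks this package builds are expressed in fold bins,
and significance machinery is out of scope; the threshold is a documented,
configurable approximation. Pair correlation is Pearson's r over the four
per-stage means (default gate r ≥ 0.8, configurable; only positive
thresholds are accepted because the ceRNA hypothesis requires co-varying
profiles). With four points the correlation is a coarse trend statistic —
this is a property of the study design, not of the implementation.
`ddct_ratio()` implements the comparative-Ct qPCR quantification
2^(−ΔΔCt) against a reference gene and calibrator sample.

# Target scoring

The duplex scorer is a penalty-minimizing alignment of the miRNA (5′→3′)
against the reverse-complement sense of a target window: mismatch 1, G:U
wobble 0.5, gap 2, all penalties doubled when the miRNA position lies in
the seed range 2–13; sites are called at total penalty ≤ 3 with at most
one gap. These are this package's bundled defaults in the style of the
plant target-prediction tools; every value is configurable and recorded in
the run manifest. Two conventions the scheme must fix (and the tests'
enumeration oracle shares by definition): a gap consuming miRNA position
*i* takes that position's seed weight, and a target-side bulge between
miRNA positions *i* and *i+1* takes the weight of min(*i*+1, length). The
dynamic program (in C++) carries a gap-count state and abandons a window
as soon as the running row minimum exceeds the cutoff — exact, because all
penalties are non-negative and every alignment path crosses every miRNA
row.

Overlapping calls for one miRNA on one transcript are resolved to the
lowest-score site (leftmost on ties). circRNAs are scanned twice: on the
linear representation and on the back-splice junction pseudo-sequence
(last *flank* + first *flank* bases, flank = miRNA length − 1 + max gaps);
junction hits are mapped back to circular coordinates, flagged
`spans_junction`, and deduplicated against linear hits by mapped start.

# ceRNA network construction

`shared_mre_pairs()` intersects the MRE sets of every (ceRNA, mRNA)
combination; "same MRE" means a site for the same miRNA identity, matching
the family-member resolution of the motivating study's networks.
`correlation_filter()` annotates and gates on r. `assemble_triads()` then
emits one triad per shared miRNA and contrast when the pair is
differentially expressed in the same direction and the miRNA in the
opposite direction (the sponge signature). The miRNA gate is default-on
but relaxable (`require_mirna_de = FALSE`): the positive pair correlation
is the primary gate of the ceRNA definition, and the miRNA anti-direction
is what the sponge mechanism implies. Tightening any gate (r, fold threshold,
site-score cutoff) can only shrink the triad set — a monotonicity property
the acceptance tests check. Networks are exported as SIF + node-attribute
TSV + GraphML with Up/Down fold-bin labels, ready for Cytoscape.

# The synthetic study and what it shows

The generator (`sim_config()`, default seed-reproducible conditions)
emulates the study design: 4 stages × 3 replicates (three biological
replicates being the stated qPCR design and a standard sequencing choice),
300 mRNAs, 100 lncRNAs, 30 circRNAs, a 12-member miR156 family of 21-nt
miRNAs, 15% of mRNA loci with 2–3 splice isoforms, and 12 planted
ceRNA–miR156–mRNA triads. miR156 members decline geometrically
(effect size 2 per stage, so 8-fold Li→Bo); triad ceRNAs and mRNAs rise
with the same ratio, making their noise-free stage profiles perfectly
correlated. All other features are stage-stable. Counts are negative
binomial with a single global dispersion (0.05, a typical biological-
replicate value; the Poisson limit at dispersion → 0 is tested), and
library-size factors are drawn once per sample from ±15%.

Two generator choices deserve justification:

* **Background miRNAs.** The small-RNA matrix additionally contains 188
  stage-stable background miRNA features. Without them, TPM
  renormalization over a 12-member matrix would cancel a family-wide
  decline exactly (columns are forced to 10⁶), making the central trend
  unobservable — an artifact of normalizing a tiny matrix, not of the
  biology. Real small-RNA libraries contain hundreds of stable miRNAs.
* **Homologous flanks.** Synthetic SPL proteins are mutated copies of a
  reference homolog (5% substitutions in the domain, 12% in the flanks)
  rather than domains dropped into random flanks: family members from
  related species share flank homology, and with non-homologous random
  flanks a local aligner chains chance matches through the flanks and
  dilutes aligned-column identity below any realistic screen threshold.

Planted MREs are reverse complements of their miRNA with 0–2 edits
(mismatch or wobble) outside the seed, so every designed penalty is ≤ 2
and below the call cutoff; about half of the circRNA sites span the
back-splice junction. A quarter of the remaining (non-triad) ceRNAs and
mRNAs receive decoy sites for random miRNAs; triad members receive no
extra sites, so the planted truth stays unambiguous.

What passing tests show — and what they do not: recovery of the planted
truth demonstrates the *procedure* is implemented correctly and is
internally consistent (precision = recall = 1 at the default gates on the
default dataset). It does not reproduce the motivating study's dataset-
dependent numbers (such as its triad counts per contrast or its 33-member
family), which require the deposited sequencing data and genome; those are
explicitly not targets of the synthetic validation. Real data add
features the generator does not model: shared-sequence isoforms with
correlated counts, composition shifts that bias per-million normalization,
overdispersion heterogeneity, and MREs with gapped or seed-imperfect
pairing.

# Numerical choices and degenerate inputs

* Identity thresholds: ≥ (inclusive) for identity, < (strict) for E,
  following the stated wording of the criteria they implement.
* pI bisection: interval [0, 14], 200 iterations max, |Q| < 10⁻⁶; the
  curve is strictly monotone so convergence is guaranteed.
* Fold-bin boundaries: upper-inclusive half-open intervals; direction
  `flat` only at exactly log₂FC = 0.
* Ties: domain hits prefer the leftmost window at equal score; isoform
  deduplication prefers the smallest id at equal length; overlapping MREs
  prefer the leftmost site at equal score.
* Degenerate inputs raise errors naming the offending field (empty
  reference sets, ragged alignments, pairs with no comparable columns,
  zero library sizes, unknown stage labels) rather than propagating NA.
* Problem sizes in the shipped tests: oracle equivalence on 100 random
  protein pairs (length ≤ 8), 200 random miRNA×30-nt instances, 125
  random additive matrices; the study-scale chain runs at the default
  generator conditions. These sizes are the package's validation design.

# Known limitations

* The E-value uses ungapped Karlin–Altschul constants with a gapped score
  — a documented approximation; the screen is threshold-driven and the
  tests exercise the thresholds, not BLAST parity.
* The domain profile is ungapped and fixed-width; genuinely gapped domain
  instances would need HMM machinery that is out of scope.
* No MSA: the phylogeny is a domain-window tree.
* DE gating by fold change only; no dispersion estimation, shrinkage or
  multiple-testing correction.
* Four-point Pearson correlations are coarse; the r threshold is a
  screening device, not an inference.
* The CLI regenerates upstream stages deterministically from the seed
  rather than consuming intermediate files.
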