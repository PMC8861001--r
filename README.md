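# splnet

SPL gene-family identification and miR156 ceRNA network inference for
multi-stage transcriptomes.

## The scientific problem

SQUAMOSA promoter-binding protein-like (SPL) transcription factors drive
the juvenile-to-adult phase transition in plants and are post-
transcriptionally repressed by the conserved microRNA family miR156. In
species with heteromorphic leaves — the motivating system is *Populus
euphratica*, whose leaves progress from linear (Li) through lanceolate (La)
and ovate (Ov) to broad-ovate (Bo) with tree age — the decline of miR156
across the series releases SPL expression. Long non-coding RNAs and
circular RNAs that carry the same miR156 response elements (MREs) can act
as competing endogenous RNAs (ceRNAs), sponging miR156 and further
de-repressing SPL mRNAs.

`splnet` implements the full analysis chain for this biology as a tested,
seed-reproducible R pipeline:

1. **Family identification** — homology screen (exact Smith–Waterman local
   alignment, BLOSUM62 with affine gaps 11/1; candidates retained at
   aligned-column identity ≥ 80% and Karlin–Altschul E-value < 10⁻⁵,
   E = K·m·n·e^(−λS)), followed by an SBP-domain scan (ungapped
   position-specific score matrix; only *full-length* domain hits qualify)
   and splice-isoform deduplication (longest isoform per locus).
2. **Physicochemical profiling** — ProtParam-style molecular weight,
   theoretical pI (bisection on the Henderson–Hasselbalch net-charge
   curve), GRAVY (mean Kyte–Doolittle hydropathy) and the Guruprasad
   instability index II = (10/L)·Σ DIWV(xᵢ, xᵢ₊₁), with the >40 instability
   and pI<7 acidity classifications.
3. **Phylogeny** — p-distances with pairwise gap deletion over the aligned
   domain windows, Saitou–Nei neighbor joining, and nonparametric bootstrap
   supports from column resampling (1000 replicates by default).
4. **Expression** — FPKM = c·10⁹/(N·L) for mRNA/lncRNA, TPM =
   (c/L)/Σ(c/L)·10⁶ for miRNA, RPM = j·10⁶/N for circRNA back-splice
   junction reads; stage contrasts as log₂ fold changes with the
   categorical fold bins A (1,2], B (2,5], C (5,10], D (>10); comparative-Ct
   qPCR ratios 2^(−ΔΔCt).
5. **Target scoring** — plant-style penalty-scored miRNA/target duplex
   alignment (mismatch 1, G:U wobble 0.5, gap 2, penalties doubled in the
   miRNA seed positions 2–13, sites called at penalty ≤ 3), including
   circRNA back-splice junction pseudo-sequences.
6. **ceRNA network** — ceRNA–mRNA pairs sharing MREs, filtered on positive
   expression correlation (Pearson r over stage means), intersected with
   same-direction differential expression of the pair and opposite-direction
   differential expression of the shared miRNA, yielding
   ceRNA–miR156–mRNA triads per stage contrast; exported as SIF/GraphML for
   Cytoscape.

A first-class synthetic-data generator plants MREs, regulatory triads,
expression trends and isoform redundancy with known ground truth, so every
stage is validated end to end.

## Worked example

```r
library(splnet)

cfg <- pipeline_config(synthetic = sim_config(seed = 3), n_bootstrap = 200)
out <- run_pipeline(cfg, "run1")
```

which logs, stage by stage:

```
simulate: 442 transcripts, 29 proteins, 102 planted sites
identify: 20 retained by screen, 17 with full-length domain, 12 canonical
physchem: 12 profiles
tree: 12 leaves, mean support 33.6
quantify: 3780 contrast rows over La/Li, Ov/Li, Bo/Li, Ov/La, Bo/La, Bo/Ov
targets: 102 MRE sites
network: 239 shared-MRE pairs -> 28 correlated -> 37 triads (Bo/Li: P=1.000 R=1.000)
```

Reading the chain: of 29 simulated proteins, 20 pass the homology screen,
17 carry a full-length SBP domain, and isoform deduplication leaves the 12
canonical SPLs (exactly the planted truth). All 102 planted miR156 response
elements are recovered at the default penalty cutoff; shared-MRE pairing,
the correlation gate (r ≥ 0.8) and the direction-consistent
differential-expression gate then reduce 239 candidate pairs to 37 triads
across the six stage contrasts, and in the extreme Bo/Li contrast the 12
recovered triads match the 12 planted ones (precision = recall = 1). The
output directory contains the per-stage tables (`spl_canonical.tsv`,
`spl_physchem.tsv`, `spl_tree.nwk`, `contrasts.tsv`, `mre_sites.tsv`,
`triads.tsv`), Cytoscape-ready networks under `network/`, the fixtures, a
`summary.json` and a provenance `manifest.json` recording the seed, every
defaulted parameter and per-file checksums.

A command-line front end with the same stages is installed as
`exec/splnet` (subcommands `simulate`, `identify`, `physchem`, `tree`,
`quantify`, `targets`, `network`, `run-all`).

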