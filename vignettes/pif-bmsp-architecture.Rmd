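---
title: "Delimiting and characterizing the Pif/BMSP shell-matrix-protein family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting and characterizing the Pif/BMSP shell-matrix-protein family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pifarch)
```

## The problem

Molluscan shells grow inside an organic framework of chitin and
shell matrix proteins (SMPs). A central SMP family — Pif/BMSP — is
built from one to four von Willebrand factor type A (VWA) domains
followed by chitin-binding (CBM_14/peritrophin-A) domains, and in many
members a *partial* laminin G (LG) domain whose two conserved terminal
peptides flank a long, compositionally biased insert. Family membership
and subfamily structure are read off a phylogeny of the VWA domains,
and the functional signatures of the family live in its low-complexity
regions (LCRs) and insert chemistries.

`pifarch` packages that whole in-silico workflow as tested, reusable
components:

1. **Homology gating** of candidate VWA domains against a reference
   (PfuPif-like) VWA by Smith–Waterman local alignment with
   Karlin–Altschul E-values, gate at E < 1e-10.
2. **Tiered chitin-binding classification** by independent E-value:
   confident `CBM_14` (< 1e-5), degenerate `CBM_14L1` [1e-5, 1) and
   `CBM_14L2` [1, 1e4).
3. **Family and subfamily extraction** from a tree carrying dual
   SH-aLRT/UFBoot branch supports, with strong (UFBoot ≥ 95 and
   SH-aLRT ≥ 85) and medium (UFBoot ≥ 75, SH-aLRT ≥ 65) thresholds.
4. **LG insert delimitation** from the two conserved anchor peptides.
5. **LCR detection** by entropy segmentation, assigned to four
   architecture-anchored zones.
6. **Composition clustering** of inserts and LCRs by Ward's method
   with silhouette-guided choice of the cluster number.

A synthetic-family generator with a machine-readable truth table
replaces the original genome/transcriptome inputs, so every stage is
testable offline.

## Models, parameters, and the reasoning behind them

### Homology gate

The gate reimplements a protein-BLAST-style search as exact
Smith–Waterman with affine gaps: a gap of length $g$ costs
$11 + (g-1)\cdot 1$ on BLOSUM62, the standard protein-BLAST
parameterization (the source method names the tool but not its
parameters). Significance uses the Karlin–Altschul form
$E = K m n e^{-\lambda S}$. Two calibrations exist:

* `canonical` — the published ungapped BLOSUM62 constants
  ($\lambda = 0.3176$, $K = 0.134$), documented defaults suitable for
  natural protein sequences;
* `shuffle` — a Gumbel fit (method of moments) to scores of the query
  against seeded residue shuffles of the subject, exact for synthetic
  alphabets where published constants do not apply.

`'X'` scores zero against everything, so unknown residues neither
reward nor penalise an alignment. The gate operates on extracted
VWA-domain subsequences, not whole proteins, because membership is
defined by VWA homology.

### Tier windows

The three chitin-binding tiers are half-open, lower-inclusive windows
of the independent E-value: $[0, 10^{-5})$, $[10^{-5}, 1)$,
$[1, 10^4)$, else none. The source ranges are written with "~" and do
not state inclusivity; lower-inclusive windows make the partition of
$[0, \infty)$ exact, which is asserted on every call. The synthetic
generator draws planted E-values log-uniformly *strictly inside* a
window so tier recovery is never decided by a boundary tie.

### Clade and subfamily extraction

Branch support is classified strong/medium/weak from the
(SH-aLRT, UFBoot) pair; a missing value fails every comparison it
appears in — a deliberately conservative reading, applied in
particular to unlabelled roots. Two circulating definitions of
"medium" (with and without the SH-aLRT ≥ 65 clause) are both
implemented; the stricter dual-threshold form is the default and
`medium_ufboot_only = TRUE` switches to the UFBoot-only form. Nothing
in the package guesses which was "intended".

The family clade is operationalized as *the largest supported clade
containing all reference leaves* (ties broken toward the root); if no
supported clade qualifies, the references' MRCA is returned flagged
unsupported rather than silently promoted. Subfamilies are the maximal
proper sub-clades of the family whose branch class meets the threshold
and which hold at least two leaves, chosen top-down so a supported
clade nested inside a chosen one is absorbed — this mirrors how
non-nested subfamily boxes are drawn on published trees. Both
operations are brute-force-checked in the test suite by enumerating
every internal node.

### LG anchors and the insert

The two anchor peptides (32 and 59 residues) are located by local
alignment; a match requires identity ≥ 0.5 over at least 80 % of the
anchor. These tolerances are package defaults (the source states
none) and are configuration keys. The anchor search is protein-level
local alignment; the N-anchor is searched first and the C-anchor is
constrained downstream of it. The reported span is the *full-anchor
projection*: the aligned span extended by any anchor residues trimmed
from the alignment ends. This matters because local alignment drops
mismatching terminal residues, which would otherwise shift the insert
boundary by a residue or two whenever an anchor end is substituted;
projection keeps insert extraction exact under substitution-only
noise. An insert requires *both* anchors. "Complete" LG status
additionally requires a middle Laminin_G_3 hit or an inter-anchor gap
of at most 250 residues (`max_complete_gap`), since most family
members carry only the partial domain.

### Low-complexity regions and zones

The segmenter is an entropy trigger/extension scheme in the SEG
tradition: Shannon entropy of each 12-residue window ('X' excluded); a
window at or below 2.2 bits seeds a segment; the segment spans the
maximal run of windows at or below 2.5 bits containing the seed;
overlapping/adjacent segments merge; segments shorter than the window
are dropped. The exact optimal-subsegment refinement of the original
SEG algorithm is intentionally not reproduced; the package documents
this as an approximation and tests it against exhaustive window
enumeration instead of a binary.

One measured consequence deserves emphasis: with these standard
parameters, a *single* triggered window already yields a reportable
12-residue segment, and roughly 0.5 % of 12-windows of
database-composition random sequence fall below 2.2 bits. About a
fifth of random 200-mers therefore contain at least one short called
segment (about 7 % even for uniform composition). This is inherent to
single-window triggering at these thresholds, not a defect of the
implementation; detection of genuine tracts (length ≥ 20) is at the
same time essentially perfect. Raising `min_len` toward twice the
window suppresses the short calls if an application needs a stricter
segmenter.

Zones partition a protein by its architecture: zone 1 upstream of the
first VWA (after any signal peptide), zone 2 the gaps between tandem
VWAs, zone 3 between the last VWA and the first chitin-binding element
*of any tier*, zone 4 between the LG anchors. An LCR belongs to the
zone containing its midpoint (boundary-straddling segments are not
split), and LCRs are numbered 1..k by start within each zone. Zone 4
is anchored on the conserved anchor peptides, not on Laminin_G_3 hit
boundaries, because the anchors are the reproducible landmark in this
family.

### Composition clustering

Regions are summarised as 20-vectors of residue percentages ('X'
excluded from the denominator; rows sum to 100 by construction).
Clustering is Ward's method on Euclidean distances between raw
percentage rows — ratios are clustered directly, as in the original
analysis, and Ward assumes Euclidean geometry; a z-score flag exists
but is off by default. The implementation delegates to
`stats::hclust(method = "ward.D2")` (heights on the Euclidean scale,
so the ESS increase of a merge is height²/2), cross-checked in the
tests against brute-force minimum-ESS agglomeration. The cluster
number is chosen by cutting the dendrogram at each k from 2 to
`min(8, rows − 1)` and maximizing the mean silhouette (singletons
score 0; ties go to the smaller k). When even the best mean silhouette
is below 0.25 the result carries a `weak_structure` flag: the chosen k
is then a formality, not a finding. Insert regions and LCRs are
clustered jointly per matrix, with the zone kept as row metadata.

## What the synthetic generator emulates — and what it does not

The generator plants, per protein: an optional signal peptide, 1–4
tandem VWA-like domains (instances mutated to 85 % identity around a
fixed consensus), optional Sushi repeats between VWA and the
chitin-binding block, 0–3 CB domains at chosen tiers, the two LG
anchors (optionally mutated, substitutions only, identity ≥ 0.7)
flanking an insert of length drawn uniformly from 138–1438 residues —
the observed span of insert lengths in the family — and homopolymeric
low-complexity tracts (default 24 residues) placed strictly inside the
four zones. Inserts follow one of two named composition profiles
emulating the family's characteristic contrast: `pinctada_like`
(Asp 25 %, Lys 12 %, Arg 10 %) versus `unionida_like` (Ser 22 %,
Asp 20 %). Linkers use a fixed database-average composition, a
documented constant. Hit tables carry E-values drawn log-uniformly
strictly inside the intended tier window. The support tree plants
subfamily ancestor branches in the intended class ranges (strong:
UFBoot 95–100 / SH-aLRT 85–100; medium 75–94 / 65–100; weak below
both), a strong family ancestor, a weak spine, and outgroup leaves
outside the family clade. Domain-boundary jitter is not modelled:
fixtures plant exact boundaries.

Because sequences and the tree are generated *independently* (no
substitution model along the tree) and domains are i.i.d. draws around
a consensus, passing tests demonstrate the correctness of the
machinery — gate, tiers, clade logic, insert delimitation, zone
geometry, clustering — not the biological recall of the original
study on real genomes, which depends on database versions and profile
databases outside this package's scope.

All randomness flows through per-task seeds derived from a single
master seed via `withr::with_seed`, so runs are byte-reproducible and
the global RNG stream is never disturbed.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere (the profile-search
  convention); hit coordinates are alignment coordinates.
* Alignment tie-breaking is deterministic: smaller query start, then
  smaller subject start, then diagonal-move preference (fewer gaps).
* Overlapping domain hits are resolved greedily by smaller independent
  E-value, ties by longer span then smaller start.
* A signal peptide overlapping a kept domain is a warning, not an
  error, and the signal is kept — real annotations disagree this way.
* Empty inserts, absent zones, proteins shorter than the LCR window,
  and empty hit tables are all values, not errors; hard errors are
  reserved for contract violations (duplicate ids, spans outside the
  protein, malformed tables, support values outside [0, 100]).
* Per-protein failures inside the pipeline are logged, skipped and
  counted; a missing reference leaf aborts before any stage runs.

## Problem sizes used by the checks

The shipped checks run at deliberate desk scales: a 200-protein
family (about 67 per subfamily) for architecture recovery, 500
single-tract fixtures and 500 random 200-mers for the segmenter, 100
random 12-leaf trees against brute-force clade enumeration, 100 seeded
34-row composition matrices (6 + 28 planted rows) for cluster
recovery, and a 24-protein default fixture set for end-to-end
determinism. `scripts/acceptance.R` recomputes all of these from
scratch for any seed.

## Known limitations

* The gate's canonical E-value constants are ungapped-model constants
  applied to gapped scores; use shuffle calibration when absolute
  E-values matter.
* The PSSM scanner is a windowed log-odds scanner with an empirical
  shuffle null — not a profile HMM; its E-value resolution is bounded
  below by roughly 1/`n_null`.
* The segmenter's single-window trigger calls short segments on random
  sequence at the measurable rate discussed above.
* Per-protein reproduction of the original study's counts (domain
  tables, 119 LCRs, cluster memberships of the 34 real inserts)
  requires the original databases and is out of scope.
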