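---
title: "Hydrogen-bond scoring and cluster analysis of miRNA binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrogen-bond scoring and cluster analysis of miRNA binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirclust)
library(dplyr)
```

## The model and its assumptions

`mirclust` predicts miRNA binding sites on mRNA with a deliberately simple,
fully deterministic duplex model. A candidate site is a *gapless,
antiparallel* pairing of the entire miRNA (5′→3′) against an equal-length
transcript window: window position $j$ faces miRNA position $L - j + 1$.
Each aligned pair contributes a fixed number of hydrogen bonds — 3 for G–C,
2 for A–U, and 1 each for the non-canonical G–U wobble and A–C pairs; every
other combination (including anything involving N) contributes 0 but stays
in register. The two non-canonical pairs are retained because their
internucleotide distances are essentially the same as those of the
Watson–Crick pairs, so they do not distort the double-stranded geometry;
they stabilize the duplex weakly but genuinely.

Free energy is taken proportional to the bond total $B$:
$\Delta G = -k_{hb} B$, and each miRNA's maximal energy is that of its
perfect complement, $\Delta G_m = -k_{hb} B_{max}$ with $B_{max} = 3\,n_{GC}
+ 2\,n_{AU}$. The selection statistic is the percentage

$$ \frac{\Delta G}{\Delta G_m}\,(\%) \;=\; 100\,\frac{B}{B_{max}}, $$

which is invariant to $k_{hb}$. A window is accepted when the *unrounded*
ratio reaches the threshold (default 87 %). The rationale for 87 % is a
family-similarity argument: members of one miRNA family typically differ by
one to three nucleotides, and for a 22-nt miRNA a three-nucleotide deficit
corresponds to roughly 19/22 ≈ 87 % of the maximal pairing. Every
qualifying start is reported as a separate site; adjacent qualifying starts
are *not* merged, which is what lets dinucleotide/trinucleotide repeat
regions carry runs of sites at 2–3-nt steps.

Assumptions worth keeping in mind: no bulges or internal loops (unpaired
positions keep register), no nearest-neighbour thermodynamics, no
secondary-structure/accessibility correction, no seed-region requirement,
and no conservation filtering. The criterion is whole-duplex energy only.

## Parameters

* `threshold_pct` (default **87**, percent): minimal ΔG/ΔGm. Comparison is
  against the exact rational ratio; printed ratios are rounded to integer
  percent only for reporting.
* `k_hb` (default **2.11** kJ/mole per hydrogen bond): reporting constant
  converting bonds to kJ/mole. Published site energies divided by their
  published ratios give ΔGm values which, for miRNAs of known GC-rich
  composition, imply roughly 2.1 kJ/mole per bond; `fit_khb()` performs
  that least-squares calibration if the user has matched (ΔG, ratio,
  $B_{max}$) triples. No result in this package depends on $k_{hb}$ other
  than printed kJ/mole values.
* Coordinates are 1-based from the first transcript nucleotide (the first
  nucleotide of the 5′UTR, when present). A site straddling a region
  boundary is assigned to the region of its **start** nucleotide, matching
  how site tables attribute each block to one region.

## Clusters and compaction

Accepted sites are grouped by transitive interval overlap: two sites belong
together when their occupied intervals `[start, start + length − 1]` share
at least one nucleotide, and clusters are the connected components of that
relation (computed with `IRanges`). Abutting sites (gap 0) do *not*
cluster. Per cluster we report:

* `total_len` — summed site length, with multiplicity;
* `span` — `max(start + length) − min(start) + 1`. This "one past the
  inclusive union" convention is non-obvious but is the one that reproduces
  published cluster sizes consistently (e.g. a 12-site cluster whose last
  covered nucleotide is 54, entered as "16 nt to 55 nt", size 40 nt). A few
  published spans deviate by ±1 nt from *any* single convention; we apply
  this one uniformly and treat those rows as source arithmetic slips rather
  than fitting per-row conventions.
* `compaction` — `total_len / span`, the factor by which overlap shrinks
  the occupied footprint; and `mean_dg`, the arithmetic mean of per-site
  ΔG.

Rounding of reported values is *half away from zero* (compaction to 1
decimal, energies to integer kJ/mole), the rule consistent with published
values such as 6.75 → 6.8 and −121.8 → −122; base R's round-half-even would
disagree exactly on ties. Singleton clusters report their total length only
— span and compaction are undefined for them and returned as `NA` with a
`singleton` flag rather than a number.

`region_summary()` aggregates per (gene, region): footprint (sum of cluster
spans; singletons contribute their site length), total site length, their
ratio, and a site-weighted mean ΔG, optionally normalized by the region
length.

## The printed-table dialect

Published site tables compress repeat-region sites as `miRNA (n)` with
start/energy/ratio intervals `a ÷ b`. `read_site_table()` expands such rows
into `n` sites in arithmetic progression; `write_site_table()` inverts this
(greedy left-to-right compression of maximal equal-step runs), and
writer∘parser is the identity on the bundled tables modulo thousands
separators. Two deliberate policies:

* **Ranged energies.** A row like `−134 ÷ −140` gives each expanded site
  the endpoint mean (−137). Individual per-site energies inside a range are
  unrecoverable; the endpoint mean is the unique single-value assignment
  that preserves the block's mean energy under the reasonable reading that
  endpoints describe the first and last site, and it reproduces the
  published mean energies (e.g. −127 for the 12-site 5′UTR cluster).
* **Non-integral steps.** One published row (`(4) 2,060 ÷ 2,095`) has a
  span not divisible by $n-1$, so no exact integer step exists. Because the
  downstream statistics (site count, total length, cluster span) do not
  depend on the interior starts, the parser by default places the starts
  evenly, rounds to integers, keeps the endpoints exact and warns;
  `strict = TRUE` turns this into an error for users who want the
  format contract enforced.

The bundled tables keep a few identifier spelling variants verbatim
(`D00436.3p-miR`, `D00915.3p-miR`, `ID0296.3p-miR`);
`normalize_mirna_id()` maps them to canonical ids for cross-referencing
only.

## The synthetic generator

`synth_generate()` builds a seeded, bit-reproducible fixture: i.i.d.
background sequence (uniform base frequencies by default; GC content is
configurable to probe the false-positive behaviour of the threshold) into
which reverse-complement windows are planted with exactly specified
corruptions. For each plant the expected bond total and ratio are computed
*a priori* from the corruption spec — a wobble at a G/C-facing position
costs 2 bonds, at an A/U-facing position 1 bond; a mismatch costs the full
3 or 2 — so recovery tests can demand exact agreement, not approximate.

The default configuration mirrors the site structures seen in the bundled
tables: three transcripts of 0.9–1.5 kb with 5′UTR/CDS/3′UTR splits
(including one transcript that, like some real mRNAs, has no 5′UTR at
all), six miRNAs of 18–24 nt, one perfect plant, one single-wobble and one
double-wobble plant, one four-mismatch plant constructed on a fixed 21-nt
sequence so that it is guaranteed to fall below the 87 % threshold (the
designed "expected miss"), and two tandem runs — six sites at step 2 and
nine sites at step 3, the patterns that dinucleotide and trinucleotide
repeats produce. Problem sizes throughout the tests (transcripts ≤ 1 kb,
100 random instances for the oracle-equivalence check) were chosen as the
smallest sizes at which every code path — hits, misses, tandem runs,
boundary windows — is exercised with comfortable margin.

What the generator does *not* emulate: real transcript base composition,
repeat families, expression levels, or secondary structure. Passing
recovery tests therefore demonstrates that the scanner implements the
stated criterion exactly — not that the criterion itself has any particular
sensitivity or specificity on real transcriptomes.

## Numerical and design choices

* Ties and degenerate inputs: duplicate starts never merge into one
  printed group; an empty site list yields empty (typed) statistics; a
  miRNA longer than its transcript yields a warning and no sites, not an
  error; `N` bases score 0 bonds rather than invalidating a record.
* Grouping greed: compression scans sorted starts left to right and
  extends the current run while the consecutive difference is constant.
  This recovers every grouped row of the bundled tables and makes
  `group_starts(expand_group(g)) == g` for any well-formed group; for
  irregular spacings like `{10, 12, 15}` it yields `{10, 12}` + `{15}`.
* Determinism: clustering is order-invariant (components are relabelled by
  leftmost start), and the whole simulate → scan → cluster pipeline is
  identical across repeated runs at a fixed seed.

## Known limitations

* Gapless scoring cannot represent bulged duplexes; if single-nucleotide
  bulges matter for a use case, the alignment layer is the place to extend
  (`align_at()` is the single scoring entry point).
* $k_{hb}$ is a calibration constant; absolute kJ/mole values should not be
  compared against nearest-neighbour free energies.
* Region annotation comes from a sidecar TSV of region lengths rather than
  GenBank/GFF feature parsing, which keeps the format surface minimal; a
  feature-table importer would be a separate layer.
* Cluster statistics recomputed from printed tables inherit any arithmetic
  slips in the source rows; the package reports what the data imply under
  the uniform conventions above and does not patch individual rows.
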