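---
title: "Screening crystal structures for overlooked NOS linkages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening crystal structures for overlooked NOS linkages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A nitrogen–oxygen–sulfur (NOS) bridge covalently links a cysteine sulfur to
a backbone or side-chain nitrogen through an oxygen atom and acts as a redox
switch: it forms and breaks with the redox state of the cell and thereby
modulates enzyme activity. Deposited crystallographic models almost never
contain the bridging oxygen, because refinement libraries do not expect it.
What survives in the deposited model is the signature of the bond: an S and
an N atom at roughly covalent distance (2.6–3.2 Å), often flagged in the
wwPDB validation report as a "too-close contact". A large fraction of
experimentally verified Lys-NOS-Cys linkages are flagged exactly this way —
the flag frequently marks a missing bond, not a modelling error.

`nosscan` re-screens deposited models for such S–N pairs and ranks them by
how closely their structural context matches verified NOS linkages. It is a
screening tool: its output is a list of *probable* candidates for visual
electron-density inspection and re-refinement, not a final verdict.

## The pipeline

**1. Screening.** Entries must be X-ray structures at resolution ≤ 2 Å
(inclusive). Within an entry, sulfur donors are the side-chain S of Cys
(and, if enabled, Met); nitrogen acceptors are the backbone N of the twenty
standard residues plus the side-chain N of Lys, Arg, His, Trp, Asn and Gln.
A pair is a candidate when dist(S,N) ≤ 3.2 Å (inclusive), the covalent
cutoff calibrated on verified Lys/Cys linkages. Quality gates are strict:
both target atoms need occupancy > 0.8, both residues need RSRZ < 2.0 in
the validation report, and both atoms must carry a B-factor in the
companion BDB file (PDB-format files whose B-factor column holds consistent
full isotropic values; an atom missing there signals unreliable mobility
information, and the pair is excluded). Cys–Cys backbone contacts
(disulfide bridges) and His contacts (metal coordination) are tabulated but
excluded from the default target classes.

**2. Descriptors.** Fifteen numbers per retained pair, in fixed order
(`nos_descriptor_names()`): the angles ∠CSN and ∠CNS, the torsion
φ(C_S–S–N–C_N) with IUPAC sign convention, the distances dist(C_S,N) and
dist(S,N); deposited and BDB B-factors of both target atoms; the number of
neighbouring residues within 4 Å of each partner's Cα (any non-hydrogen
atom counts, each residue once); and Shrake–Rupley solvent accessibilities
of both target atoms and both residues. "C_S"/"C_N" are the closest carbons
covalently bound (≤ 1.9 Å) to S and N; for a backbone nitrogen the
candidates are the residue's own Cα and the preceding residue's carbonyl
carbon, and the literal closest-carbon reading selects the carbonyl carbon
(≈ 1.33 Å vs ≈ 1.46 Å) in ideal geometry. dist(C,N) uses C_S, pairing it
with ∠CSN as the third side of that triangle.

**3. Subset search.** Verified NOS linkages (reference points) should
occupy the same region of descriptor space as undiscovered ones. For every
descriptor subset of size ≥ 3 — `sum(choose(15, 3:15))` = 32,647 subsets in
the full search — the selected columns are z-scored, embedded with UMAP
(2 output dimensions for 3-descriptor subsets, 3 otherwise), clustered by
mean-shift, and scored. A subset is accepted when it yields 2–3 clusters
with mean Silhouette ≥ 0.5, at least one cluster is reference-poor
(≤ 2 references — without such an *improbable* cluster the subset
discriminates nothing), and at most 2 references fall outside the
reference-rich *probable* clusters. Accepted subsets are ranked by
(smallest size, fewest reference leaks, highest Silhouette); the winner is
the minimal descriptor set, and every non-reference pair inherits its
cluster's probable/improbable label.

**4. Reporting.** Per-cluster summaries give the dominant density mode of
each winning descriptor (Gaussian KDE, Scott's-rule bandwidth, argmax on a
512-point grid spanning the data range; constant input returns that
constant), plus TSV exports of probable and improbable candidates keyed by
PDB id, chains, residue names/numbers and atom names.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `max_resolution` | 2.0 | Å | fine bond detail is unreliable in coarser maps |
| `max_sn_dist` | 3.2 | Å | covalent S(-O-)N cutoff from verified linkages |
| `min_occupancy` | 0.8 (strict) | — | excludes positionally uncertain atoms |
| `max_rsrz` | 2.0 (strict) | — | both residues must fit their density |
| `neighbor_radius` | 4.0 | Å | packing shell around Cα |
| `sasa_probe_radius` | 1.4 | Å | water-sized probe |
| `sasa_points` | 960 | — | quadrature density; ≤ 2% error on an isolated atom |
| `min_silhouette` | 0.5 | — | acceptance gate for a subset's clustering |
| `min_clusters`–`max_clusters` | 2–3 | — | the screen expects probable/improbable segmentation |
| `ref_leak_tolerance` | 2 | count | "a minimal number" of stray references is acceptable |
| `umap_n_neighbors`, `umap_min_dist` | 15, 0.1 | — | conventional UMAP defaults |
| `ms_quantile` | 0.3 | — | mean-shift bandwidth heuristic (see below) |

## Numerical choices

- **Inclusive cutoffs carry a 1e-4 Å guard.** Coordinates pass through text
  formats (mmCIF at 1e-6 Å here, PDB at 1e-3 Å for B-factor files), so a
  pair planted exactly at 3.20 Å can reparse to 3.2000001 Å. Inclusive
  comparisons (`dist ≤ cutoff + 1e-4`) make the boundary decision stable
  under format round-off; the guard is far below any physically meaningful
  difference. Strict thresholds (occupancy > 0.8, RSRZ < 2.0) compare
  exactly: their operands are parsed decimals, not derived quantities.
- **Standardization.** Descriptors mix degrees, Å, Å² and counts; columns
  are z-scored before embedding so no unit dominates the metric.
  Zero-variance columns become all-zero. Verdicts are invariant under
  positive rescaling of any descriptor column.
- **Degenerate embeddings.** When the standardized submatrix has no row
  variation, the all-zero embedding is returned directly: a
  stochastic-gradient layout would scatter exactly coincident points.
- **UMAP determinism.** Single-threaded optimization with a seeded RNG;
  the same seed, input and subset give byte-identical coordinates. 200
  epochs (rather than uwot's 500 for small data) keeps desk-scale subset
  streams fast; blob-separation behaviour at the fixture sizes used here
  is unchanged.
- **Mean-shift bandwidth.** Estimated as the average distance to the
  `floor(0.3 n)`-th nearest neighbour — the conventional mean-shift
  default. At a 0.2 quantile the flat kernel fragments diffuse embedded
  clusters (a well-separated 124-point blob splits into 3–4 modes whose
  basins are narrower than the blob), which would reject every subset.
  Converged modes closer than one bandwidth merge (strongest mode wins);
  modes holding under 5% of points are outlier satellites and dissolve
  into the nearest surviving mode — the smallest cluster this screen cares
  about, the improbable cluster, is an order of magnitude larger.
- **Acceptance requires an improbable cluster.** If references scatter so
  that every cluster is reference-rich, the leak criterion is vacuously
  satisfied while the subset separates nothing; such subsets are rejected
  (`no_improbable_cluster`). This mirrors the screen's purpose: a useful
  feature space must isolate a reference-poor cluster.
- **Ties.** Altloc collapse keeps the highest-occupancy conformer,
  lexicographically smallest altloc on ties. Frequency tables break count
  ties alphabetically. Mean-shift clusters are numbered by descending
  size.

## The synthetic generator

Real inputs at study scale (10⁵ PDB-REDO entries, their BDB companions and
validation reports) are bulk downloads; every test here instead runs on
generated fixtures whose truth is known by construction.

`make_contact_structure()` builds an entry by *inverse geometry*: the four
contact atoms C_S–S–N–C_N are placed so the extracted descriptors equal the
requested dist(S,N), ∠CSN, ∠CNS and torsion to text precision (the default
geometry is the quantum-mechanically optimized Gly-NOS-Cys contact:
2.70 Å, 94.02°, 95.11°), then minimal residue scaffolds with idealized bond
lengths (N–C 1.33 Å, N–CA 1.46 Å, SG–CB 1.81 Å) are grown around them so
bonded-carbon resolution, packing and SASA are well defined. The same
construction serializes mmCIF, a BDB companion (with selectable per-atom
omissions) and a validation XML (with selectable per-residue RSRZ values
and clash records), and a corpus manifest records the expected screening
outcome of every entry. `make_descriptor_blobs()` emulates the statistical
side: isotropic Gaussian blobs on an informative descriptor subset, i.i.d.
noise elsewhere, reference rows drawn from an assigned blob.

What the fixtures do *not* emulate: real side-chain rotamer distributions,
crystal-packing contacts and symmetry mates, electron density, correlated
B-factor structure along chains, and heterogeneous entry sizes. Passing
tests therefore demonstrate that the machinery is correct and that the
method recovers structure it is designed to find — not that real deposited
models contain that structure.

## Design choices on open points

- **RSRZ is applied per residue** (both partners must pass): wwPDB reports
  are residue-granular.
- **Occupancy is tested on the two target atoms only**, matching the
  purpose of excluding positionally uncertain target atoms.
- **Only the deposited asymmetric unit is searched**; symmetry-related
  contacts are out of scope.
- **Only the first model** of a multi-model file is used; X-ray-only
  filtering makes other models rare.
- **Waters are excluded from SASA and packing**: crystallographic waters
  would bury surfaces inconsistently across entries.
- **Torsion sign** follows the IUPAC right-hand convention for
  φ(C_S–S–N–C_N); the mirror image of a structure flips the sign.
- **Reference injection**: reference descriptor vectors are appended as
  rows to every pair-class matrix before embedding, so a Gly–Cys dataset
  can still be gated by Lys–Cys reference linkages.

## Problem sizes used by the tests

The bundled suites run the subset search on restricted streams: planted
recovery uses a 12-subset stream (the planted subset plus 11 decoys) over
20 seeds on 174-row matrices (100 data rows + 74 references), and the
50-entry end-to-end corpus searches a 152-subset stride of the 455
3-descriptor subsets. These sizes were chosen as the smallest that exercise
ranking against plausible competitors; the full 32,647-subset search is the
same code path via `sizes = 3:15`.

## Known limitations

- The screen finds *candidates*; confirmation requires electron-density
  inspection and re-refinement with an explicit NOS restraint, which are
  outside this package.
- UMAP embeddings are seed-dependent; verdicts are deterministic for a
  fixed seed but cluster shapes (and therefore Silhouette values) vary
  across seeds. The acceptance gates, not the absolute Silhouette, are the
  contract.
- Mean-shift on UMAP output inherits UMAP's tendency to exaggerate
  separation; the reference-containment and improbable-cluster gates are
  what keep unstructured data from being accepted.
- B-factors taken from deposited files are not comparable across entries
  unless recalibrated; that is exactly why the BDB variant exists and why
  pairs without BDB values are dropped rather than defaulted.

## A worked run

```{r, eval = FALSE}
library(nosscan)

dir <- tempfile()
corpus <- make_example_corpus(dir, seed = 1)
res <- run_nos_pipeline(dir, corpus$reference,
                        subsets = enumerate_subsets(15, 3)[seq(1, 455, 3)],
                        seed = 17, out_dir = file.path(dir, "out"))
res$selection$best
table(res$verdicts$label)
```

The run screens 50 entries (42 pairs survive; 8 entries are rejected, one
per planted defect), searches the subset stream, and labels the five
planted NOS-like pairs probable alongside the reference linkages.
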