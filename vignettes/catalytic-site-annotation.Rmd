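---
title: "Geometric annotation of Mg-NTP catalytic sites in P-loop NTPases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric annotation of Mg-NTP catalytic sites in P-loop NTPases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploopscan)
```

## The problem

P-loop fold NTPases — GTPases, motor ATPases, helicases, ABC transporters,
recombinases — share a conserved phosphate-binding loop (Walker A motif,
`[G/A]xxxxGK[S/T]`) whose lysine anchors the β- and γ-phosphates of the bound
nucleotide, and a Walker B motif (`hhhhD`, four hydrophobics and an aspartate)
whose aspartate hydrogen-bonds the serine/threonine that follows the Walker A
lysine. Because the fold, not the sequence, is what is conserved across this
enormous superfamily, catalytically equivalent residues carry unrelated
sequence numbers in different families. This package identifies them
*geometrically*, from the coordinates of the Mg-triphosphate moiety itself,
and names them by their structural role:

* **Lys^WA^** — the Walker A lysine, found as the lysine whose NZ is nearest
  to a β-phosphate oxygen (within 5 Å);
* **[Ser/Thr]^K+1^** — the next residue in chain; its hydroxyl is ligand #4
  of the Mg²⁺ octahedron;
* **K−3** — three residues before Lys^WA^; its backbone amide points at the
  γ-phosphate (O^2G^) in transition-state-like structures;
* **Asp^WB^** — the Walker B aspartate (occasionally a glutamate), chosen as
  the carboxylate nearest the K+1 hydroxyl (≤ 5 Å) whose three N-terminal
  neighbours are all non-ionizable (outside {Glu, Asp, Ser, Thr, Tyr, Lys,
  Arg, His}); when no candidate has such a hydrophobic window the nearest one
  is taken and flagged as a fallback;
* **[Thr/Ser]^SwI^** — the Switch I hydroxyl occupying shell position #3 in
  TRAFAC-class enzymes;
* **W_cat** — the catalytic water, apical to the O^3B^–P^G^ axis.

The diagnostic quantity of the survey is the Asp^WB^–[Ser/Thr]^K+1^
donor–acceptor oxygen distance. It is short (< 2.7 Å) in most closed sites
and extremely short (2.4–2.5 Å) when a transition-state analogue such as
AlF₄⁻ is bound, which is the structural signature motivating the proton-relay
interpretation of this residue pair.

## Site detection, ligand classes and quality control

A candidate site is one nucleotide hetero-residue (ATP/GTP, an imido-,
methylene- or thio-analogue, or ADP/GDP). For a diphosphate, a γ-phosphate
mimic (AlF₄⁻, AlF₃, MgF₃⁻, BeF₃, VO₄³⁻) is attached when its central atom
lies within 3.5 Å of the terminal O^3B^ oxygen — the length scale of the
O^3B^–P^G^ bond being mimicked; the value is a package choice, exposed in the
configuration. Sites partition into four classes: `native` (ATP/GTP),
`non_hydrolyzable` (AMP-PNP and relatives), `substrate_analog` (NDP·BeF₃ /
AlF₃, ground-state mimics) and `ts_analog` (NDP·AlF₄⁻ / MgF₃⁻ / VO₄³⁻).
Because metal-fluoride species are repeatedly misassigned in deposited
structures, the species is re-derived from geometry — four fluorines
square-planar within a 0.3 Å plane deviation is AlF₄⁻; three trigonal-planar
fluorines are AlF₃/MgF₃⁻/BeF₃ by central element — and the geometric verdict
overrides the deposited component code. An NDP with no γ-moiety (or with a
detached inorganic phosphate, the post-hydrolysis state) is `ndp_only` and is
excluded from accepted sites.

Quality control accepts a site when (i) a Walker A lysine NZ is within 5 Å of
a β-phosphate oxygen, (ii) a γ-phosphate or mimic is present, (iii) the
[Ser/Thr]^K+1^ hydroxyl is within 2.5 Å of the cofactor ion, and (iv) the ion
is within 6 Å of the Walker B carboxylate. Criteria (iii) and (iv) jointly
reject disassembled or poorly resolved sites and sites where the acid
directly coordinates the metal.

## Geometry

**Mg²⁺ shell.** The six nearest O/N atoms within 2.6 Å of the ion form the
first shell (standard Mg–O bonds are 2.05–2.15 Å; the cutoff is a package
choice). Canonical labels: #1 = O^2B^, #2 = O^1G^ or the mimic atom standing
in for it, #4 = the K+1 hydroxyl (confirmed as the ligand trans to #2); of
the rest, the atom trans to #1 is #6 and the last trans pair splits into #3
(nearer the Walker B carboxylate — the proton-entry side) and #5. Shell
edges are all cis ligand pairs (Mg-centred angle < 120°); for an ideal
octahedron with bond length *b* there are twelve edges of *b*·√2, i.e. all
within 2.9–3.0 Å for *b* in the observed 2.05–2.12 Å range — close enough
for proton exchange between neighbouring ligands.

**H-bond classes and the pKa-mismatch calibration.** Donor–acceptor O–O
distances classify as short (< 2.7 Å), typical (2.7–3.2 Å) or long; boundary
values are typical. The ΔpKa estimate maps bond length linearly through the
empirical anchor points (2.4 Å, 0) and (2.9 Å, 20 pKa units), clamped
outside. (The slope implied by these endpoints is 0.025 Å per pKa unit; a
printed slope of 0.02 Å per unit circulates in the literature and is
inconsistent with the endpoints, so the endpoints are taken as authoritative.)

**Superposition.** Structures are compared on the backbone N/CA/C/O of the
20-residue window K−12..K+7 (β1-strand, P-loop, α1-helix) by least-squares
rigid superposition (Kabsch, via SVD), cross-checked in the test suite
against an independent reference implementation.

**SASA.** Shrake–Rupley with a 1.4 Å probe. Test points come from a
deterministic golden-spiral quadrature (default 960 points per atom) rather
than random sphere sampling, so site records are bit-reproducible; a point
is exposed iff it lies strictly outside every other atom's expanded sphere,
which makes areas monotonically non-increasing under atom addition. Element
radii are a shipped, overridable table (C 1.70, N 1.55, O 1.52, S 1.80,
P 1.80, Mg 1.73, F 1.47, Al 1.84, V 2.00 Å). Relative SASA divides the
residue's heavy-atom area by a published theoretical maximum-accessibility
reference (whole-residue, Gly-X-Gly-based; Tien et al. 2013). Whole-residue
rather than side-chain normalisation is an assumption — the precise
normalisation used by common viewers is not documented — and a residue
extracted with no neighbours at all exceeds 100% of a tripeptide-based
reference by construction; such values are flagged rather than clamped.

**Statistics.** Distance distributions per ligand class are summarised with
robust quantiles, and classes are compared with the two-sided Mann–Whitney U
test (midrank formula, normal approximation with tie correction and no
continuity correction, so identical samples give p = 1 exactly), with
Benjamini–Hochberg adjustment across the pairwise comparisons. A rank test
is used because the observed distributions are multimodal and skewed; the
original appendix routine is not published, so exact reproduction of
published p-values is not claimed. Kernel-density panels use Scott's-rule
bandwidth and are purely presentational.

## The synthetic-site generator

Every stage is tested against structures built by `build_ideal_site()`, which
plants: a Mg²⁺ at the origin with its octahedral shell at `mg_bond_length`
(default 2.1 Å) on the axes; an extended triphosphate with IUPAC atom names
whose O^2B^ and O^1G^ occupy shell positions #1 and #2; a 20-residue
P-loop-like chain (author numbering 217–236, lysine at 229) with the planted
NZ 3 Å from O^1B^ and the K−3 amide nitrogen 3 Å from O^2G^; a Walker B
aspartate whose nearer carboxylate oxygen sits exactly `wb_k1_target` from
the K+1 hydroxyl behind a controllable three-residue window; optional
γ-mimics built with correct square-planar/trigonal/tetrahedral geometry and
one peripheral atom placed at the Mg bond length (solved analytically by
rotating the peripheral ring about the apical axis); an optional apical
water at a controllable angle and distance; and Gaussian coordinate jitter
under a fixed seed. Peptide geometry is minimal-but-legal — standard bond
lengths, no Ramachandran realism — because the pipeline consumes distances
and angles, not stereochemistry.

`build_batch()` draws per-class Walker-B-to-K+1 targets from normal
distributions (transition-state analogues: mean 2.5 Å, sd 0.05; all other
classes: mean 2.65 Å, sd 0.08; jitter sd 0.05 Å). These values echo the
qualitative class ordering reported for real structures — TS-analogue sites
have the shortest bonds — but they are *test scaffolding*, not measured
data, and the truth-table header says so. Consequently, passing tests
demonstrate that the pipeline recovers planted geometry and class structure
under realistic coordinate noise; they do not certify behaviour on real
crystallographic pathologies (alternate conformations beyond simple altloc
pairs, missing atoms, symmetry-related sites), which the worked-example
tests on deposited structures cover when those files are present.

## Numerical choices and degenerate inputs

* Altlocs: highest occupancy wins, ties to the alphabetically first code;
  first model only; hydrogens discarded (all measured distances are
  heavy-atom distances, appropriate for X-ray structures).
* Ties in any nearest-atom search break deterministically by (chain,
  residue number, atom name).
* A site without an ion is annotated as far as possible and fails QC; a K+1
  without a hydroxyl (e.g. the glycine of some kinases) is flagged and the
  Walker B search reports absence; shells with fewer than six ligands are
  flagged incomplete rather than rejected.
* Distances are stored at 0.01 Å and compared against printed literature
  values at the precision those values carry (0.1 Å unless stated finer).

## Problem sizes used in the shipped checks

The test suite regenerates all fixtures in code: 200 jittered replicates
(sd 0.05–0.2 Å) for annotation recovery, 20 ten-atom clusters against a
5·10⁴-sample Monte-Carlo SASA oracle, batches of 8–10 sites per ligand class
for the end-to-end statistics, and 2000–5000-permutation oracles for the
rank tests. These sizes give comfortable statistical margins for the
assertions made while keeping the default check run short.

## Known limitations

* Annotation is geometric by design; there is no sequence-profile (HMM)
  motif search, and stimulatory fingers/sensors from partner chains are out
  of scope.
* Corpus assembly (database queries, family assignment) is out of scope: the
  pipeline consumes user-supplied files, and `fetch_pdb()` is a convenience
  only.
* No NMR ensembles, assembly expansion or hydrogen placement.
* Walker B candidates are searched only in the chain owning K+1; inter-chain
  Walker B arrangements, never observed in the motivating survey, would be
  missed.
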