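---
title: "Mapping orthosteric and allosteric ligand responses from HDX-MS"
author: "AlloHDX"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping orthosteric and allosteric ligand responses from HDX-MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AlloHDX)
```

## The problem

Backbone amide hydrogens exchange with solvent deuterium at rates that
report on hydrogen bonding and solvent access. When a ligand binds a
protein, peptide-level hydrogen/deuterium exchange mass spectrometry
(HDX-MS) sees two kinds of change at once: slowed exchange at amides the
ligand physically occludes (the orthosteric site), and changes — in
either direction — at distal regions whose conformational ensemble the
binding perturbs (allosteric responses). The two are indistinguishable
from the uptake data alone; they separate only when a ligand-bound
structure says where the ligand actually sits. AlloHDX implements that
separation for apo-versus-bound comparisons and uses it to compare and
rank ligands, including weak-affinity fragments (dissociation constants
in the hundreds of micromolar), which is where the approach earns its
keep for fragment-based ligand discovery.

## Exchange at an occluded amide

At a binding-site amide under reversible ligand binding, exchange
requires the complex to open, and reassociation competes with the
chemical exchange step. The observed rate is

$$k_{obs} = \frac{k_{off}\,k_{ex}}{k_{on}[L] + k_{ex}},$$

where $k_{ex}$ is the intrinsic exchange rate of the amide. Three
regimes follow. When $k_{off}$ is very slow (below about $10^{-2}$
min$^{-1}$ here), the complex effectively never opens during the
experiment. When ligand is in vast excess ($k_{on}[L] \gg k_{ex}$), the
expression reduces to the limiting form

$$k_{obs} = \frac{K_D\,k_{ex}}{[L]},$$

and the complex reassociates before an exchange event can occur. In
between, the full expression is needed. `observedExchangeRate()`,
`limitingRate()` and `saturationCheck()` implement these; the package
interprets "vast excess" as $k_{on}[L] \ge 10\,k_{ex}$ by default,
configurable, since the qualitative criterion has no canonical constant.
This rate model was originally derived in the context of deuterium
off-exchange from pre-formed interfaces; we adopt it unchanged for
on-exchange simulation, which is the standard practice, and note the
caveat here rather than in every function page.

```{r}
kin <- bindingKinetics(kOn = 1e6, KD = 19e-9, ligandConc = 20e-6,
                       proteinConc = 3.3e-6)
saturationCheck(kin, kex = 0.1)$message
```

Two design helpers complete the arithmetic. `fractionalOccupancy()`
solves the binding quadratic with **total** (not free) ligand — the
exact smaller root of $x^2 - x(P+L+K_D) + PL = 0$, evaluated in the
cancellation-free form $2PL/(b+\sqrt{b^2-4PL})$ — because fragments are
used near $K_D$-scale concentrations where depletion is not always
negligible, and the exact form costs nothing. `mixConcentrations()` and
`ligandProteinRatio()` do volume-weighted dilution arithmetic and report
at two significant figures, the precision at which such numbers are
conventionally quoted.

Since no association rates are published for the ligands modelled by the
fixture, a single diffusion-limited-scale $k_{on}$ of $10^6$
M$^{-1}$min$^{-1}$ is assumed and exposed as a parameter; every scenario
classification for real ligands therefore requires the user's own
$k_{on}$.

## Relative uptake and reporter peptides

The relative deuterium uptake of a peptide at an exposure is the ratio
of deuterons exchanged to exchange-observable amides. The amide count
excludes the first residue (whose amide back-exchanges too fast to
retain label) and prolines; `exchangeableAmides()` exposes the N-terminal
convention (`nFastTermini`, default 1, settable to 2 for the stricter
back-exchange convention) rather than baking one in. A peptide is a
*reporter* — dynamic enough to respond to ligand on the experimental
timescale — when its short-labelling-time RDU exceeds half the maximum
RDU observed across the protein:

$$\mathrm{RDU} > 0.5 \times \max \mathrm{RDU}\ (\text{short labelling times}).$$

The factor and the set of "short" times are parameters
(`reporterRegions()`); the pipeline defaults to the earliest exposure,
and the Hsp90-patterned configuration uses 10 min.

## Difference profiles and response regions

`differenceProfile()` computes $\Delta = \text{apo} - \text{bound}$ per
peptide and exposure, so positive values mean protection (decreased
exchange when bound). A peptide is significant when $|\Delta|$ exceeds a
fixed Dalton threshold — 0.5 Da by default — at at least
`minTimepoints` exposures (default 1, matching the practice of flagging
any excursion past the threshold line). The fixed-threshold design is
deliberate: it is how these comparisons are done in the field this
package models, and no multiple-testing machinery is attached to it. A
replicate-SD z-score is reported alongside as a diagnostic, clearly an
extension, and never feeds the significance call. Apo and bound states
must share an identical (peptide, exposure) grid; mismatches are an
error that lists the missing pairs, with an explicit `strict = FALSE`
opt-in to analyse the intersection.

`mergeRegions()` unions significant peptides of like direction into
residue intervals; spans that overlap or are directly adjacent merge
(`maxGap = 0`), and larger bridgeable gaps are configurable. Merged
output is sorted, idempotent, and pairwise non-overlapping.
Opposite-direction peptides are never merged directly; if a protection
and a deprotection region nevertheless overlap, the package must choose
between overlapping output and a combined region — it combines them into
one region of direction `"mixed"` with a warning, keeping the
non-overlap guarantee, which downstream classification depends on.
Residue coordinates are 1-based inclusive throughout.

## Structure overlay and classification

`loadStructure()` reads a PDB file, partitions ATOM records from one
selected HETATM group, drops waters, hydrogens and alternate locations
beyond the first, and uses only the first model — all for deterministic
output. `contactResidues()` marks a residue as a ligand contact when any
of its heavy atoms lies within 4.0 Å of any ligand atom. The boundary is
inclusive (exactly 4.00 Å is a contact) because distal sites are defined
by strictly greater distances. This is a pure distance screen at an
H-bonding-scale radius: no donor/acceptor geometry, protonation or
energetics — a deliberate simplification, stated here so nobody mistakes
the contact set for a hydrogen-bond inventory. The scan is a naive
all-pairs distance computation, which at single-structure scale
(thousands of atoms) is entirely adequate; any spatial-indexing
optimisation would be required to return identical results.

`classifyRegions()` then labels a response region *orthosteric* if it
contains at least one contact residue, and *allosteric* otherwise. A
single contact residue suffices (no fractional-overlap threshold):
published orthosteric regions are routinely anchored by a handful of
contacts inside a much longer peptide interval. Direction is carried
through but ignored by the classifier, since allosteric changes can be
protections or deprotections. Regions are named `O1..On` and `A1..Am` by
ascending start within each label. An integer offset maps author
residue numbering to the HDX sequence coordinate when the two differ.

## Comparing and ranking ligands

`compareLigands()` matches regions across ligands by interval overlap of
at least one residue, reporting a presence/magnitude matrix over the
unioned comparison intervals while each ligand's own region list is kept
intact — published catalogues can name overlapping intervals separately
per ligand, so the package does not re-segment anyone's regions.
`rankLigands()` orders ligands by number of response regions, then by
total magnitude, then alphabetically for determinism, flagging exact
ties. The per-region magnitude defaults to the maximum over exposures of
$|\Delta|$; since "magnitude of the shifts" has no canonical formula,
the alternatives (sum over exposures, earliest exposure) are one
argument away (`magnitudeStat`).

## The synthetic generator, and what passing tests mean

`simulateExperiment()` generates apo/bound uptake tables from first
principles: per-residue intrinsic rates drawn log-uniformly from 0.05–5
min$^{-1}$ (a plausible seconds-to-tens-of-minutes window at
quench-compatible conditions; sequence-based intrinsic-rate tables are
out of scope and pluggable), single-exponential labelling per amide,
peptide centroids as sums over amides, Gaussian centroid noise (SD 0.05
Da, a typical replicate scatter) truncated at zero, and exposures of
0.5, 2, 5 and 10 min. In the bound state, orthosteric residues exchange
at $k_{obs}$ of the two-state model and allosteric residues at
`allostericFactor` times their intrinsic rate — a multiplicative
modulation, the minimal mechanism that reproduces an exchange-rate
change without direct contact; factors below 1 model the protections
observed in the system the fixture emulates, above 1 are allowed.
`makeSyntheticStructure()` writes a deliberately artificial geometry
(C$_\alpha$ trace on a widely spaced line, one ligand atom 3.5 Å from
each designated contact) whose 4 Å contact set is *exactly* the
designated residue set — the point is exercising the contact mapper with
a known answer, not depicting a fold.

The generator does **not** simulate back-exchange, EX1 bimodality,
isotopic envelopes, charge states or sequence-dependent intrinsic rates.
Green tests therefore demonstrate that the analysis chain recovers
ground truth under an idealised two-state EX2-like error model; they do
not certify behaviour on real spectra, where centroid extraction,
back-exchange correction and bimodal envelopes live upstream of this
package's inputs.

## The Hsp90 fixture

`makeHsp90Fixture()` encodes the published response catalogue of the
Hsp90 N-terminal ATPase domain as a deterministic synthetic dataset:
nine regions (O1 45–70, O2 89–119, O3 131–138, O4 171–197, A1 2–16, A2
62–90, A3 77–90, A4 120–127, A5 201–213), seventeen contact residues,
and four ligands — radicicol ($K_D$ 19 nM at 20 µM), 17-AAG (33 nM at
20 µM), fragment 1 (490 µM at 5 mM) and fragment 2 (570 µM at 5 mM) —
with the published presence pattern (all ligands at O1–O4, A1, A2; A3
and A4 only for radicicol and fragment 1; A5 unique to fragment 1). The
protein sequence, intrinsic rates and pepsin map are synthetic: the real
peptide table is not public, so peptides are tiled to reproduce the
printed region boundaries instead.

Two quirks of the printed catalogue forced explicit design decisions:

* **A3 ⊂ A2.** As printed, A3 (77–90) lies inside A2 (62–90), yet some
  ligands respond at A2 without A3. The only residue-level mechanism
  consistent with that is a split effect: the fixture localises the A2
  response at residues 62–76 and the A3 response at 77–90, so a peptide
  spanning 74–90 reports A2 for every ligand while the 77–90 peptide
  responds only when A3 is active. Correspondingly, presence of a
  catalogued region is assessed by *containment* — a significant peptide
  lying entirely inside the interval (`regionPresence()`) — because with
  overlapping printed intervals mere overlap cannot distinguish the
  narrower region from the wider one.
* **Overlapping printed intervals cannot survive union-merging.** O1
  (45–70), A2 (62–90), O2 (89–119) and A4 (120–127) form an overlapping
  or adjacent chain, so merging significant peptides yields one
  45–127 block (orthosteric, since it contains contacts) rather than
  separate O1/A2/O2/A3/A4 intervals. The pipeline consequently reports
  four merged regions for radicicol, while the per-region
  presence/containment view reproduces the full printed table. Both
  views are reported; neither is wrong — they answer different
  questions. (The source catalogue also counts its own regions
  inconsistently — "seven" distinct regions against eight names, and an
  89 vs 90 start for O2 between sections; the fixture keeps the
  tabulated intervals and does not attempt to resolve this.)

Rates at the effect sites are fixed rather than drawn: the
hydrogen-bonding core of the pocket (the O2 contact residues) gets
$k_{ex} = 3$ min$^{-1}$ so its protection appears already at 0.5 min and
reaches several Daltons, the remaining contacts $k_{ex} = 1$, and
allosteric residues $k_{ex} = 0.8$ with factor 0.2, so distal responses
accumulate at later exposures — reproducing the qualitative kinetic
signature of the system (early large pocket-core differences, late
allosteric differences) without targeting its exact figure-derived
magnitudes. The fixture defaults to zero centroid noise so its outputs
are bit-stable.

## Numerical choices

* Occupancy uses the stable quadratic root form; degenerate inputs
  ($L = 0$, $K_D = 0$) short-circuit to their limits.
* `fitSingleExponential()` (least-squares fit of
  $A(1-e^{-kt})$) initialises $A$ at 1.05× the maximum uptake and $k$
  from the median log-linearised slope, fits with `nls` (port), and
  falls back to a Levenberg–Marquardt fit if that fails; rates are
  bounded positive.
* Ranking ties break alphabetically; merged regions sort by start;
  contact tables sort by residue — all output orderings are total.
* A contact at exactly the cutoff counts as contact; a difference at
  exactly the threshold does not count as significant (strict
  inequality), matching the respective published conventions.

## Validation problem sizes

The shipped test-suite exercises: the 236-residue, 20-peptide,
4-exposure, 5-state fixture end-to-end; 50 seeded 80-residue
simulations for ground-truth recovery of orthosteric and allosteric
regions (effect sizes chosen so every affected peptide clears the
threshold by more than 3 noise SDs, making recovery a deterministic
expectation rather than a coin flip); a $10^4$-point random grid for the
saturating-limit convergence of the kinetic model; 1000 random parameter
sets against a bisection oracle for occupancy; and 100-trial
brute-force oracles for contact mapping and region merging.

## Limitations

Inputs are peptide-level centroid uptake tables: everything upstream
(spectral processing, peptide identification, centroid extraction,
back-exchange correction) is out of scope. The kinetic model covers a
single two-state EX2-like regime; EX1 analysis, proton-inventory and
pH-rate corrections are not modelled. Rate constants are not fitted
from exchange data — the package predicts and classifies, it does not
invert. Classification inherits the quality of the structure and of the
residue-numbering offset; mismatches beyond span bounds warn rather
than silently truncate.
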