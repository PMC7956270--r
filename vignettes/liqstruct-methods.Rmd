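---
title: "Methods: structural analysis of hydrogen-bonded liquid mixtures under pressure"
author: "liqstruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural analysis of hydrogen-bonded liquid mixtures under pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liqstruct)
```

## Scope and model

`liqstruct` implements the analysis chain applied to molecular
configurations of water–methanol mixtures under GPa-scale pressure:

1. **Partial radial distribution functions** (PRDFs) $g_{ij}(r)$ between
   labelled atomic species under orthorhombic periodic boundary conditions;
2. **Partial structure factors** $S_{ij}(Q)$ by Fourier transform of
   $g_{ij}(r)-1$, combined with coherent neutron scattering lengths and
   concentrations into the **total scattering structure factor** $F(Q)$
   (Faber–Ziman convention);
3. **Geometric hydrogen-bond detection** and the molecule-level network
   graph;
4. **Primitive (shortest-path) ring statistics** of that network up to
   10-membered cycles, with per-size participation ratios;
5. A **modified Tait equation-of-state** consistency check on
   density–pressure tables.

Because MD trajectories are not part of the package, a family of
seed-deterministic **synthetic generators** supplies configurations with
analytically known structure: an ideal molecular gas (null model for the
scattering chain), a periodic diamond hydrogen-bond network (known ring
census), hard-core mixture packings (disordered input at tabulated
densities), and planted-ring graphs (known ring ground truth).

## Conventions and key parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `bin_width` | 0.02 | Å | PRDF histogram resolution; resolves few-tenths-Å peak shifts |
| `r_max` (half-box) | 0.49 L | Å | PRDF range under minimum image |
| Q grid | 0.1–20, step 0.05 | Å⁻¹ | working range of $F(Q)$ |
| `r_OO_max` | 3.6 | Å | H-bond O···O cutoff |
| `r_OH_max` | 2.5 | Å | H-bond H···O cutoff |
| `angle_min` | 150 | deg | O–H···O linearity threshold (vertex at H) |
| `max_size` | 10 | — | largest ring reported |
| $p_0$ | 0.15 | GPa | Tait reference pressure (lowest tabulated point) |

PRDF normalisation uses
$g_{ij}(r_k) = \langle n_{ij}(r_k)\rangle / (N_i\, 4\pi r_k^2 \Delta r\, \rho_j)$
with the partner density reduced by the per-centre number of excluded
partners (the identical atom for self pairs; same-molecule atoms when
intramolecular pairs are excluded). This makes $g \equiv 1$ exact in
expectation for uncorrelated molecules — without the correction the
intramolecular exclusion biases $g$ by $-m/N$ and produces a spurious
low-$Q$ offset in $S(Q)$.

Configurations are isotope-blind (hydrogens carry the label H); isotope
identity enters only through the scattering weights, which default to full
deuteration (D₂O + CD₃OD, the usual neutron-experiment contrast). The
Sears coherent scattering lengths ship as an editable CSV asset. The
weight matrix $w_{ij} = c_i c_j b_i b_j / (\sum_k c_k b_k)^2$ sums to one
over ordered pairs for every composition; the normalisation tag
(`faber_ziman_mean_b_squared` or `unnormalized`) is recorded in every
output because data-reduction conventions differ between communities and
the source-convention question cannot be settled from a single total.

## Full-cell histograms and the low-Q problem

A histogram truncated at $L/2$ feeds the Fourier transform an integral
whose low-$Q$ value equals the fluctuation of the pair count inside the
half-box sphere — for a finite sample this fluctuates strongly even when
the underlying $g$ is exactly flat. `compute_prdf(range = "full_cell")`
therefore histograms *every* minimum-image pair distance, out to
$\sqrt{3}L/2$, normalising each bin by the exact sphere–cube intersection
shell volume (closed form to $L/\sqrt2$, high-accuracy quadrature beyond).
Every pair is then counted exactly once, the pair-count sum rule
$\rho_j \int_\text{cell} g\,dV = N_j - m$ holds frame by frame, and
$S(Q\to 0)$ is pinned without variance. This estimator is the default
input of `total_structure_factor()`.

What it cannot remove: at $Q$ near the box fundamental $2\pi/L$ the
structure factor of a finite sample genuinely fluctuates with
$\sigma \approx 1/\sqrt{n_\text{frames}}$, independent of system size.
An ideal-gas null therefore shows $|F(Q)| \lesssim 0.01$ away from the
lowest few box modes at modest frame counts, while the modes at
$Q \lesssim 1$ Å⁻¹ retain visible sampling noise; driving them below 0.02
would require tens of thousands of independent frames. Tests assert the
flat behaviour away from the lowest modes; the ensemble-limit statement
over the full grid is asserted as such and documented as unattainable at
finite sampling.

## Hydrogen-bond detection

A bond is recorded for a donor O–H and acceptor O when O···O < 3.6 Å,
H···O < 2.5 Å and the O–H···O angle at the hydrogen exceeds 150°; methyl
hydrogens never donate, all oxygens may accept, intramolecular pairs are
never candidates. The angle vertex is configurable: the `"donor"`
convention bounds the H–O–O angle at the donor oxygen by 180° minus the
threshold, the equivalent near-linearity condition phrased at the other
vertex; the H-centred form is the default reading of an "O–H···O angle".
Candidate search uses a cell list (cells at least one cutoff wide, 27
neighbours); a brute-force all-pairs path (`method = "brute"`) exists
purely as an independent cross-check and the two are asserted identical
on randomized mixtures. By default a donor H keeps only its closest
acceptor (bifurcated bonds are suppressed); the full match list is
available behind `allow_bifurcated`. For ring analysis parallel edges
between a molecule pair merge into one topological edge.

## Primitive rings

A cycle is *primitive* when the along-ring distance between every vertex
pair equals their graph shortest-path distance. `find_primitive_rings()`
constructs candidates from geodesic pairs — for even size $2k$, two
internally disjoint geodesics between a vertex and its ring antipode; for
odd $2k{+}1$, geodesics to the two endpoints of the antipodal edge —
verifies the no-shortcut property against the full distance matrix, and
canonicalises (smallest vertex first, lexicographic direction).
`brute_force_rings()` enumerates all simple cycles by rooted DFS and
filters by the same definition; it is deliberately independent and the
two enumerations are asserted identical on hundreds of planted-ring
graphs and on the periodic diamond fixture.

One subtlety of periodic fixtures: in a 2×2×2-cell diamond network,
bond chains wrap the box in 8 steps and those wrap cycles are *primitive*
(no shortcut exists), so the census contains 8-rings alongside the
6-rings — both enumerations agree on this. With 3×3×3 cells the shortest
wrap cycle has 12 edges, beyond the size-10 cap, and the census is purely
six-membered: 2 rings per molecule, participation 1. The generator
therefore defaults to `n_cells = 3`.

Participation ratios follow the per-size definition: the fraction of
molecules belonging to at least one primitive ring of that size,
frame-averaged; a per-size ring-count-per-molecule normalisation is
reported alongside, since either reading can be wanted when comparing
"ratio of molecules participating in rings" across studies.

## Synthetic generators: what they emulate, what they do not

All generators are fully determined by their seed.

* **Ideal gas** — rigid molecules (O–H 0.96 Å, H–O–H 104.5°; standard
  rigid methanol) at iid uniform positions/orientations; box edge from the
  tabulated atomic number density. Every intermolecular correlation is
  flat by construction, so the scattering chain must return
  $F \approx 0$: the null test of the pipeline.
* **Diamond network** — oxygens on a periodic diamond-cubic lattice
  (lattice constant set so O···O = 2.8 Å), hydrogens at bond midpoints
  along an ice-rule (Eulerian-circuit) orientation so each oxygen donates
  exactly two; every lattice edge satisfies the bond criterion exactly
  (collinear, well inside both cutoffs) and second neighbours (4.6 Å) are
  safely outside. Detection must reproduce the returned adjacency
  verbatim.
* **Mixture packing** — random sequential insertion with a 2.4 Å O–O hard
  core at the tabulated density, a short Metropolis hard-core relaxation,
  and, by default, hydrogen-bond-seeking orientations: each molecule keeps
  the trial rotation bonding most strongly to its placed neighbours.
  The orientation bias is deliberate: purely random orientations give a
  mean H-bond degree near 0.5 — a forest, with no rings at any
  composition — which cannot exercise the ring statistics at all, whereas
  the greedy orientations reach a degree near 1.7 and produce rings whose
  abundance falls with methanol content for the physically right reason
  (water donates twice, methanol once). `orient = "random"` restores the
  uncorrelated fluid.
* **Planted-ring graphs** — vertex-disjoint cycles of requested sizes plus
  random tree attachments (which cannot create cycles), under a random
  vertex relabelling; the exact census is returned.

None of these reproduce realistic liquid-state correlations: peak shapes,
shoulder structure and absolute intensities of real mixtures are outside
what passing tests demonstrate. The fixtures verify the *machinery* —
histogram normalisation, transform, weighting, detection, enumeration —
on inputs whose answers are known exactly.

## Tait equation fitting

The fit minimises $\sum_i [(1 - V_i/V_0) - C\ln((B+p_i)/(B+p_0))]^2$ with
$V_0$ fixed to the measured volume at $p_0 = 0.15$ GPa (the lowest
tabulated pressure). For fixed $B$ the optimal $C$ is closed-form, so the
objective is profiled over a deterministic logarithmic $B$ grid and the
best bracket refined by Brent's method — no random starts, exact
reproducibility. The objective is relative-volume based and therefore
invariant to volume units. Noiseless synthetic data are recovered to
$10^{-6}$ relative. With four pressure points and realistic noise, $C$
and $B$ trade off along a likelihood ridge: at 0.5% volume noise the
median $C$ error across noise seeds is ≈ 22%, an identifiability limit of
the four-point design rather than an optimizer artefact (fitted SSE is
verified to be at or below the true-parameter SSE).

The shipped density table stores atomic number densities for the eleven
compositions at 0.15/0.4/0.8/1.2 GPa, with two flagged cells: the
60 mol%–1.2 GPa entry is stored as 0.1200, correcting an apparent
misprint (0.200 breaks both the composition and the pressure trend by an
order of magnitude), and the pure-water 1.2 GPa entry is retained but
flagged as an outlier (the jump is consistent with leaving the liquid
branch; whether it reflects a phase change or a typo cannot be decided
from the table). Tait fits across x = 0.1–1.0 give residuals of order
1e-3 relative volume; the pure-water fit is visibly degraded by the
flagged point.

## Numerical choices and degenerate inputs

* Histogram binning by `floor(d / Δr)`; distances exactly on a bin edge
  go to the upper bin. Bin centres are used for shell volumes; the
  coordination-number integral uses the trapezoid rule with the exact
  zero at $r = 0$ prepended, which makes isolated-shell counts exact.
* $Q = 0$ uses the analytic $\sin(Qr)/(Qr) \to 1$ limit.
* The Lorch window $\sin(\pi r/r_\text{max})/(\pi r/r_\text{max})$ is
  available for truncation-ripple suppression and is verified to reduce
  high-Q ringing on a discontinuous test profile.
* Peak positions are refined by parabolic interpolation through the three
  points around the discrete maximum; a maximum on the search boundary is
  flagged rather than interpolated.
* Ties in bifurcated-donor resolution break on H···O distance, then on
  stable edge order — detection output is deterministic.
* Degenerate inputs error early with named causes: empty selections,
  non-cubic boxes for full-cell histograms, constant volumes in the Tait
  fit, ring caps below 3, triclinic lattices in readers.

## Problem sizes

Test and acceptance workloads are sized for interactive desk use: ideal
gas nulls at 300–1000 molecules with 6–24 frames, packings of 120–300
molecules, diamond networks of 64 (oracle comparisons) or 216 (census)
molecules, and planted-ring batteries of 200 graphs up to 50 vertices.
The analysis drivers under `analysis/` use the same scales.

## Known limitations

* Orthorhombic (for full-cell histograms: cubic) boxes only.
* No bond perception, topology parsing, or binary trajectory formats.
* The scattering chain performs no instrument corrections (resolution,
  attenuation, multiple scattering, inelasticity); measured patterns are
  not quantitatively reproducible from these synthetic fixtures.
* Ring statistics use the shortest-path (primitive) definition only;
  King/Guttman variants are out of scope.
* No dynamics: bond lifetimes and correlation functions are not covered.
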