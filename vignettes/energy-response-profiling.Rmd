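---
title: "Energy-response profiling of C-alpha structures with enmpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-response profiling of C-alpha structures with enmpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enmpath)
```

## The model

`enmpath` implements a Gaussian (elastic) network model over the C-alpha
trace of a protein. Each residue is a bead; every pair of beads whose
C-alpha atoms lie within a cutoff distance $r_c$ is joined by a linear
spring of stiffness $\gamma$. The contact topology is encoded by the binary
connectivity matrix $C$ ($C_{ij} = 1$ iff $i \neq j$ and
$\lVert \mathbf{R}_i - \mathbf{R}_j \rVert \le r_c$) and by the Kirchhoff
(graph Laplacian) matrix

$$\Gamma_{ij} = \begin{cases} -\gamma\, C_{ij} & i \neq j \\
\gamma \sum_k C_{ik} & i = j. \end{cases}$$

With this sign convention $\Gamma$ is symmetric positive semidefinite, its
rows sum to zero, and it has exactly one zero eigenvalue per connected
component of the contact graph. (The diagonal is sometimes printed with the
opposite sign in the GNM literature; only the positive-semidefinite form
makes the inverse below meaningful, so that is what we use.)

Equilibrium statistical mechanics of the harmonic network gives the residue
fluctuation correlations from the (pseudo-)inverse of $\Gamma$:

$$\langle \Delta\mathbf{R}_i \cdot \Delta\mathbf{R}_j \rangle
  = k_B T\, (\Gamma^{-1})_{ij},$$

whose diagonal is the per-residue mean-square fluctuation. It maps onto
crystallographic B-factors through the Debye–Waller relation
$\langle (\Delta R_i)^2 \rangle = \tfrac{3}{8\pi^2} B_i$, which
`predicted_bfactors()` inverts as $B_i^{\mathrm{pred}} = \tfrac{8\pi^2}{3}
\langle (\Delta R_i)^2 \rangle$. Because $k_B T/\gamma$ is a single global
scale, predicted B-factors are compared with experiment through one
least-squares scalar; the Pearson correlation is invariant to $\gamma$ and
$k_B T$.

## Mode selection and the energy response

Eigendecomposition $\Gamma = \sum_m \lambda_m \mathbf{u}_m
\mathbf{u}_m^\top$ separates global, slow motions (small nonzero
$\lambda_m$) from localized, fast motions (large $\lambda_m$).
`mode_restricted_inverse()` forms

$$\langle \Delta\mathbf{R}_i \cdot \Delta\mathbf{R}_j \rangle_{\mathcal{M}}
 = k_B T \sum_{m \in \mathcal{M}} \lambda_m^{-1}
   u_{mi}\, u_{mj}$$

for a mode set $\mathcal{M}$: `all-nonzero` (the full pseudo-inverse),
`fastest:k` or `slowest:k`. The variance of the *distance* between residues
i and j follows as

$$\langle (\Delta R_{ij})^2 \rangle =
 (\Gamma^{-1})_{ii} - 2 (\Gamma^{-1})_{ij} + (\Gamma^{-1})_{jj},$$

and the **energy response** of residue i is the sum of these distance
fluctuations over its contact neighbours:

$$\Delta U_i = \sum_{j:\, C_{ij} = 1} \langle (\Delta R_{ij})^2 \rangle.$$

Fluctuations of a harmonic pair energy are proportional to the fluctuations
of the pair distance, so $\Delta U_i$ measures how much fluctuational
energy residue i exchanges with its surroundings, in arbitrary,
unnormalized units. Computed over the fastest modes it picks out
kinetically hot, energetically responsive residues; five fast modes are
enough to resolve residue-level detail, hence the default
`mode_selection = "fastest:5"`. Full-spectrum quantities (`msf`, predicted
B-factors) always use `all-nonzero`, since the B-factor relation invokes
the complete inverse.

## Tunable parameters

* `cutoff` (Å, default 7.0) — radius of the first coordination shell;
  physically sensible values span 6.5–7.0 Å. The contact rule uses a closed
  boundary (`<=`).
* `gamma` (energy Å$^{-2}$, default 1) and `kT` (same energy units,
  default 1) — pure scale factors; doubling `gamma` exactly halves every
  fluctuation and energy response.
* `mode_selection` (default `fastest:5`) — see above.
* `z` in `detect_peaks()` (default 1) — a residue is a peak when it is a
  local maximum of $\Delta U$ along the sequence *and* exceeds
  $\mathrm{mean}(\Delta U) + z\,\mathrm{sd}(\Delta U)$; adjacent qualifying
  residues merge into one hotspot region reported by its maximum. No
  universally agreed peak-calling rule exists for these profiles, so the
  rule is deliberately simple, scale-invariant, and exposed as a parameter.

## Hotspots, paths, conservation

`build_contact_graph()` reuses the Kirchhoff contact rule as an undirected
graph; `extract_path()` returns the hop-shortest path between two residues
(ties broken by total Euclidean length, then lexicographic residue order),
optionally restricted to the detected peak residues plus the endpoints —
the energy-conduction path through hotspot residues. Disconnected endpoints
produce an explicit no-path result rather than an error.

`conservation_overlap()` relates hotspots to residue conservation levels
(an ordinal 1–8 scale, 8 most conserved). The observed statistic is the
fraction of residues at level $\ge$ `level` that are peak members or
contact-graph neighbours of one; graph adjacency at the ENM cutoff stands
in for "hydrogen-bonded to the path", which a C-alpha model cannot
evaluate. Significance comes from a seeded permutation test that reassigns
the conserved labels uniformly over all residues,
$p = (1 + \#\{f^{\mathrm{perm}} \ge f^{\mathrm{obs}}\}) / (n_{\mathrm{perm}}
+ 1)$. This test is an addition of this package: it turns a qualitative
overlap claim into a statistic. Degenerate cases behave analytically (all
residues conserved gives $p = 1$; no residues at the level yields an
explicitly flagged undefined fraction).

## Peptide libraries and dissociation constants

For docking campaigns, `tile_peptides()` slides a window of length $k$
(default 6) one residue at a time, producing $n - k + 1$ peptides from an
$n$-residue chain — a 336-residue kinase chain yields 331 hexapeptides.
Windows never bridge gaps in author residue numbering; they are dropped
with a warning instead. `peptide_at()` extracts a specific range (e.g. the
hexapeptide FKGPGD from residues 318–323 of a kinase chain), and
`write_library_fasta()` emits one record per window with `source|start-end`
headers.

A docking free energy $\Delta A$ (kJ/mol) converts to a dissociation
constant via $k_D = \exp(\Delta A / RT)$ with $R$ the molar gas constant
and a 1 M standard state. The default temperature is physiological, 310 K:
at that temperature a $-49$ kJ/mol binder has $k_D \approx 5.5$ nM (at
298 K the same energy would give 2.6 nM, so the temperature convention
matters and is exposed as an argument).

## The synthetic generator

`generate_synthetic_trace()` builds toy C-alpha geometries with known
contact topology: straight chains at the canonical 3.8 Å virtual-bond
spacing, ideal alpha-helical coils (rise 1.5 Å per residue, 100° per turn,
radius 2.3 Å — giving the 8–12 contact neighbours typical of packed
residues at the 7 Å cutoff), and cubic perturbed lattices, each with
optional isotropic Gaussian noise and a fixed seed.
`generate_planted_trace()` additionally pushes short Gaussian-shaped
segments radially out of a helical body: the pushed segments keep chain
contacts but lose packing contacts, so they fluctuate more and the
energy-response profile develops peak regions at the planted loci. Peak
detection on these plants uses the full-spectrum profile, because
flexibility (large $\langle (\Delta R_i)^2 \rangle$) is a full-inverse
property, dominated by the slow modes.

These fixtures emulate contact topology, connectivity and planted
flexibility contrast only. They do not emulate real secondary-structure
packing heterogeneity, side-chain effects, crystal contacts, or the
experimental noise in real B-factor columns — so passing tests demonstrate
correctness of the computations, not predictive performance on real
structures. A separate validation script
(`system.file("scripts", "validate_pdb.R", package = "enmpath")`) runs the
qualitative checks against user-supplied crystal structures of the RyR2
N-terminal domain and the PKA chain; it is not part of the test suite
because it requires external files and because hotspot centers depend on
the peak-calling threshold, which real-structure reports rarely state.

## Numerical choices

* Zero-mode tolerance: an eigenvalue below $10^{-8} \times
  \lambda_{\max}$ counts as zero. Disconnected structures are allowed: the
  analysis proceeds per component, a warning names the contact-free
  residues, and every component's zero mode is excluded from inverses.
* `eigen(symmetric = TRUE)` supplies the decomposition; the
  mode-restricted inverse is symmetrized against round-off.
* Tiny structures: the one-call `enm_profile()` caps `fastest:k` at the
  number of available nonzero modes (with a warning) so 3-residue fixtures
  remain analysable; the low-level `mode_restricted_inverse()` stays
  strict and errors instead.
* Energy responses are clamped at zero against round-off; mathematically
  they are sums of nonnegative quadratic forms.
* Path tie-breaking is deterministic (hops, then Euclidean length, then
  lexicographic order), so reports are byte-reproducible.
* Alternate locations in PDB input keep the blank/`A` altloc; only `ATOM`
  records with atom name `CA` are used; NMR multi-model files contribute
  model 1 only.

## Problem sizes in the test suite

The suite exercises structures of 3–100 residues: brute-force $O(n^2)$
contact oracles, explicit pseudo-inverses, literal double-loop energy
responses and breadth-first-search distances are all recomputed
independently at these sizes, where they are exact and fast. The planted
recovery and permutation analyses use an 80-residue coil with two planted
loci and 999 permutations. These sizes give fully deterministic, rapidly
verifiable ground truth; nothing in the method is size-limited beyond the
usual dense-eigendecomposition cost.

## Known limitations

* Isotropic GNM only: no directional (anisotropic) fluctuations, normal
  mode displacements, or dynamics.
* A C-alpha contact proxy cannot resolve hydrogen bonds or side-chain
  chemistry; conservation "adjacency" is a coarse stand-in.
* The peak rule, while scale-invariant and deterministic, is one of many
  plausible conventions; exact hotspot centers on real structures shift
  with `z` and the cutoff.
* Docking itself (pose generation, scoring) is out of scope; the package
  prepares libraries for it and interprets its energies.
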