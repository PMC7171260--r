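---
title: "Methods: pH-dependent electrostatic stability from structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pH-dependent electrostatic stability from structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and its assumptions

`phstab` treats a folded protein as a set of ionisable sites — Asp, Glu,
His, Lys, Arg by default — each reduced to a single point charge at its
sidechain charge centre, carrying its model (solution) pKa as the intrinsic
value. A protonation microstate assigns 0/1 protons to every site; its
energy is the proton-binding term `ln(10)·RT·Σ xᵢ(pH − pKaᵢ)` plus pairwise
screened Coulomb interactions `W(r)·qᵢqⱼ` with

$$W(r) = \frac{1389.35}{\varepsilon_r\, r}\,e^{-\kappa r}\ \text{kJ/mol},
\qquad \kappa = \frac{\sqrt{I}}{3.04}
\sqrt{\frac{78.4 \times 298.15}{\varepsilon_r T}}\ \text{Å}^{-1}.$$

The assumptions this buys, and their cost:

* **Uniform dielectric, surface-group model.** There is no Born/desolvation
  self-energy and the intrinsic pKa equals the model pKa. This describes
  solvent-exposed charge networks well; buried groups with strongly shifted
  pKas (e.g. buried carboxylates in acid proteases) are outside the model's
  reach, which is why the mutation-scan tools exist: their effect can be
  probed by removing sites, not by predicting their shifted pKas.
* **Simple exponential screening.** The canonical `exp(−κr)` form is used
  with no ion-exclusion `(1+κa)⁻¹` denominator. The choice is declared
  rather than fitted; every test oracle uses the same form, so the package
  is internally consistent and the form is trivially replaceable.
* **Rigid structure.** Profiles are computed on one conformation across the
  whole pH 1–14 range; conformational change with pH is deliberately not
  modelled.
* **Non-interacting unfolded reference.** The unfolded state titrates every
  site independently at its model pKa, giving the closed-form free energy
  `−RT Σ ln(1 + 10^{pKa−pH})`. Sequence-local interactions in the unfolded
  chain are set to zero.

The stability readout `ΔG(pH) = G_fold − G_unf` is normalised per amino
acid (residues with a CA atom), so domains of different size compare
directly; the same normalisation is applied to the net charge.

## Exact and sampled titration

Up to 20 sites the package enumerates all 2^N microstates and computes
Boltzmann averages and `G_fold = −RT·log Σ e^{−E/RT}` exactly (log-sum-exp
with max shift). Beyond that, Metropolis Monte Carlo is used: one sweep is
N single-site flip attempts plus N/2 attempts on randomly chosen strongly
coupled pairs (pairs whose interaction factor exceeds 2RT, where
single-site moves decorrelate slowly). Defaults are 10⁵ sweeps after 10⁴
burn-in sweeps, one independent chain per pH value, initialised at the
model-pKa prediction. The sampler runs in C++ on R's RNG stream, so a
single `seed` makes every run bit-reproducible.

On the Monte Carlo path the free energy is recovered by
*anchor-and-integrate*: at `pH_a = max(pKa) + 6` the fully deprotonated
microstate dominates both states, so `ΔG(pH_a)` equals the
deprotonated-charge interaction energy exactly; from there
`dΔG/dpH = ln10·RT·(⟨X⟩_fold − ⟨X⟩_unf)` (Wyman linkage) is integrated down
the grid by the trapezoid rule at the grid step (0.25 pH by default; the
grid is extended internally up to the anchor when needed). The anchor
identity is itself tested, and the whole path is validated against
enumeration on systems of up to 12 sites.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `epsilon_r` | 78.4 | – | water at 25 °C |
| `ionic_strength` | 0.15 | mol/L | physiological saline |
| `temperature` | 298.15 | K | standard conditions |
| pH grid | 1–14 step 0.25 | pH | traverses all ionisation states |
| model pKas | D 4.0, E 4.4, H 6.3, K 10.4, R 12.0, C 8.3, Y 9.6, N-term 7.5, C-term 3.8 | pH | common model-compound values |
| salt-bridge cutoff | 4.0 | Å | carboxylate O to basic N heavy-atom distance |
| H-bond cutoff | 3.5 | Å | donor heavy atom to carboxylate O |
| burial threshold | 0.10 | – | relative sidechain accessibility |
| contact clamp | 2.0 | Å | minimum distance fed to W(r) |

Cys, Tyr and the chain termini are present in the machinery but disabled by
default: the analyses this package supports concern D/E/H/K/R titration,
and whether termini or thiols titrated in comparable published calculations
is generally unstated, so the conservative default is off, overridable via
`site_config()`. Disulphide-bonded cysteines (SG–SG < 2.5 Å) never titrate.

Charge centres: Asp mean(OD1,OD2); Glu mean(OE1,OE2); His mean(ND1,NE2);
Lys NZ; Arg CZ; Cys SG; Tyr OH; N-terminus backbone N; C-terminus
mean(O,OXT). When charge atoms are missing the centre falls back to CB,
then CA, with a warning and a flag — a degraded but usable site rather than
a silent failure.

## Numerical choices

* **Altloc resolution** keeps the highest-occupancy alternate; ties keep
  the first record in file order. HETATM residues are dropped unless
  whitelisted. Multi-model files are split at the text level and one model
  is parsed.
* **Solvent accessibility** is Shrake–Rupley with a 1.4 Å probe and a
  deterministic 960-point Fibonacci-spiral sphere per atom. Coordinates are
  first expressed in a molecule-fixed principal-axes frame (eigenvector
  signs fixed by third moments), which makes the discrete occlusion test
  invariant under rigid motion of the input — a property the tests assert
  at 10⁻⁶ relative tolerance. Burial is judged against the sidechain area
  of the same residue type computed in isolation with the same engine, so
  the reference and the measurement share every discretisation choice.
* **Apparent pKa** is the linear interpolation of the half-protonation pH;
  multiple crossings use the first (lowest pH) with a warning, no crossing
  returns `NA` with a warning.
* **Degenerate inputs**: coincident site centres are an error naming the
  pair; distances below 2 Å are clamped with a warning; structures with no
  ionisable sites yield an all-zero profile with a warning rather than an
  error, so dataset sweeps do not abort.
* **Mutation = site removal.** A charge-neutralising mutation removes the
  site from the titrating set and changes nothing else; the geometry of the
  neutral replacement is irrelevant at this level of theory.
* **Hydrogen bonds by heavy-atom distance only** (no angles, no modelled
  hydrogens): crystal structures carry no hydrogens, and the contact
  classes feed comparative counts, not energies. One record per residue
  pair, at the minimum atom distance.

## What the synthetic generator emulates — and what it does not

`make_pair()` places two full-sidechain residues with their charge centres
at an exact separation; `make_toy_domain()` builds a circular CA backbone
with stub sidechains carrying an exact number of engineered Asp–Lys salt
bridges (3.5 Å) and/or Asp–Asn hydrogen-bond pairs (3.0 Å, plus a 3.2 Å
carboxylate-to-mainchain-N contact), with glycine spacers and a deterministic
sub-Å jitter. Engineered pairs sit on consecutive slots so the charged patch
is dense, as on a real protein surface: when the acids neutralise at low pH
the neighbouring basic charges still repel, which is what makes a
neutral-pH-optimised surface acid-labile. Every engineered contact is
listed in a manifest and verified by brute-force distance scan in the
tests.

These fixtures are idealised: no packing, no rotamers, no backbone
realism, no clash checking beyond construction geometry. Passing tests
demonstrate that the electrostatic model, the samplers and the detectors
are correct *given* charge-centre geometry; they do not demonstrate
predictive accuracy on real structures, which additionally stresses pKa
models, desolvation, and structure quality.

Test and acceptance problem sizes — pairs (2 sites) and toy domains of
30–60 residues (6–12 sites), 10⁵ Monte Carlo sweeps, pH 1–14 at 0.25 —
were chosen so exhaustive enumeration remains available as the oracle for
every sampled quantity.

## Design choices where the design was open

* The Fab-domain cleaving motifs are user configuration, not built in:
  only the Fc motifs (CH2: PSVF/SK[AT]K, CH3: GQPRE/LSL) are shipped.
  Motif matching is first-match, with warnings listing any further matches;
  domain lengths are validated against [90, 130] by default.
* "Basic" in composition statistics means K, R, H — consistent with the
  charged set (D, E, K, R, H at neutral pH) that includes histidine.
* Heat maps default to 10 log-spaced ionic strengths from 0.001 to 0.5 M,
  rebuilding the interaction matrix at each point (screening is the whole
  effect being mapped).
* The default toy domain (60 residues, 6 bridges) has its stability
  minimum at pH 7.25 and turns net-destabilising below pH ≈ 2.7 — the
  crossing sits below pH 4 because all engineered acids share the Asp
  model pKa of 4.0 and strong pairing holds their charges down to
  ~1.5 units below it; real proteins, with a spread of pKas and weaker
  average coupling, cross higher.

## Known limitations

* No Poisson–Boltzmann treatment of buried groups: pKa shifts from
  desolvation and buried hydrogen bonding are not modelled, only probed by
  site-removal scans.
* The unfolded state has no residual interactions.
* His tautomers are not placed; the imidazole is one site with one pKa.
* mmCIF is not parsed; glycans and other heteroatoms are excluded from the
  electrostatic model.
* Exact enumeration is capped at 20 sites; above that, accuracy is bounded
  by the sampling tolerances stated above, not by machine precision.
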