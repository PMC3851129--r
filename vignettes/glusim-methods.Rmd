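---
title: "Methods: kinetic simulation and gene-dosage sensitivity analysis of L-glutamate fermentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetic simulation and gene-dosage sensitivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modelling problem

*Escherichia coli* MG1655 ΔsucA lacks α-ketoglutarate dehydrogenase, so
carbon entering the TCA cycle cannot proceed past α-ketoglutarate (AKG)
and is instead aminated to L-glutamate and exported — the defining lesion
of a model glutamate-production strain. `glusim` implements a dynamic
kinetic model of this system: Michaelis–Menten enzymatic reactions, a
transcription/translation layer whose machinery (RNA polymerase,
ribosomes) tracks the specific growth rate μ, the covalent-modification
cycle that phosphorylates and thereby inactivates isocitrate
dehydrogenase (ICD), growth-proportional biomass precursor drains, and a
*prescribed* fed-batch growth profile. On top of the simulator sits a
gene-dosage sensitivity analysis: each gene unit's copy number is scaled
over an exponential grid (×0.001 … ×1000), the glutamate yield Y of each
perturbed model is compared with the baseline Y0, and units are ranked
by the maximum sensitivity max (Y − Y0)/Y0, recording the scale factor
X/X0 at which the maximum occurs.

## Model structure and rate conventions

**Units.** Concentrations are mM on a 1 L culture-volume basis
(extracellular and intracellular pools share the volume basis; this
avoids a cell-volume conversion and is documented as a reduction), time
is in minutes, biomass density in g dry cell weight per litre.

**Rate laws.** Irreversible Michaelis–Menten rates use a product of
independent saturation terms, `kcat·E·Π S/(Km+S)` — no ternary-complex
mechanism is implied. Reversible reactions use a Keq-scaled net rate in
the convenience-kinetics style,

    v = kcat·E · (Π S/KmS − Π P/(Keq·Π KmS)) / (dS + dP − 1),

which vanishes exactly when the concentration ratio reaches Keq
(Haldane-consistent, with Keq in concentration units). Inhibition is one
hyperbolic multiplier `1/(1+I/Ki)` per inhibitor — a noncompetitive-style
choice; the source literature states *that* 3-phosphoglycerate inhibits
the AceK kinase but not the kinetic form, so the form (and the Ki value)
are reference-model parameters, not literature claims. Mass action is
used for export steps.

**The ICD phosphorylation cycle.** One bifunctional converter enzyme
(AceK, expressed from the aceBAK operon, so its dosage scales both
activities) interconverts active ICD and inactive ICD-P; the kinase arm
carries the 3PG inhibition factor. Both arms saturate in their protein
substrate with a shared `Km_cycle`. The curated reference model sets
`Km_cycle` an order of magnitude below the ICD pool, placing the cycle
in the zero-order (Goldbeter–Koshland) ultrasensitive regime: the active
fraction switches sharply when `k_kin·inh(3PG)` crosses `k_phos`. This
is a deliberate design choice — with a shallow (first-order) cycle the
3PG signal moves the active fraction by only a few percent and the
documented dosage phenotypes (pgk amplification helping, gpmA/eno
attenuation helping, pykF overdose hurting) are numerically invisible at
the reduced-model scale. The baseline phosphorylated fraction lies
mid-transition (0.2–0.8), so the switch can move in both directions.

**Gene expression.** Each gene unit (gene or operon) has one promoter,
one mRNA and one or more member proteins that share the synthesis term.
Transcription is `k_tx · promoter · copy_factor · sat(RNAP) · Π
occupancy`; the copy factor multiplies the promoter term, i.e. dosage
acts at transcription initiation. TF occupancy is single-site hyperbolic
(Hill 1), with an optional effector that hyperbolically activates or
inactivates the TF (Cra–FDP, PdhR–pyruvate). RNAP and ribosome levels
are piecewise-linear functions of μ, clamped at the table ends. Both
mRNA and protein are diluted by μ in addition to first-order
degradation; whether μ-dilution applies to mRNA is not stated in the
source literature — it is applied here to both pools and flagged as a
choice (its effect is small: mRNA degradation dominates dilution by an
order of magnitude at all realized μ).

**Biomass.** Growth drains key precursors at `coefficient · μ(t) · X(t)`
(mmol/g × 1/min × g/L = mM/min). The composition table ships as data:
standard *E. coli* precursor demands (G6P 0.205, R5P 0.898, PYR 2.833,
ACCoA 3.748, OAA 1.787 mmol/g, …) with the revision-mandated sign
semantics — OAA and FUM must be *positive* (consumed), and branch-point
key substances such as S7P appear as explicit entries.
`validate_precursor_table()` enforces exactly this and rejects the
pre-revision pattern. The rewritten side reactions (argininosuccinate →
arginine and SAICAR → AICAR with the released fumarate fully oxidized:
net +4 CO2, +6 NADH, +2 FADH, +2 ATP per unit flux; glycogen = 8 G6P +
8 ATP) are installed verbatim as stoichiometry — the implied electron
bookkeeping is not re-derived, since the underlying assumption
("immediately and completely oxidized") fixes only the net coefficients.
Each drain carries a hyperbolic shutoff with half-saturation `drain_eps`
(default 3·10⁻⁴ mM): growth is prescribed, so without the shutoff an
emptying pool would be driven negative by a demand that does not care
about supply. `drain_eps = 0` recovers strictly linear drains (used by
the conservation tests).

**Branch-point combination.** When one metabolite is produced by several
routes, the single balance expression is the minimum-norm (pseudoinverse)
solution of the stacked per-route system — the unweighted average for
independent routes, which is why branch coefficients are generally not
integers (S7P = 0.5 E4P − 1 GAP + 0.5 R5P + 0.5 F6P + 0.5 X5P). The
implementation uses an SVD pseudoinverse; the test suite checks it
against an independent QR least-squares oracle on random 2–4-route
systems.

## Numerical integration

No stiff ODE solver package is available in the target environment, so
the integrator is implemented in compiled code (Rcpp/RcppArmadillo): an
adaptive L-stable Rosenbrock 2(3) scheme (the ode23s linearly implicit
method) with a finite-difference Jacobian that is reused across steps
W-method-style (refreshed after a rejection or every 20 accepted steps),
step-size control by the embedded error estimate, and exact landing on
the uniform output grid. Defaults are `rel_tol 1e-6`, `abs_tol 1e-9`;
for a second-order method this is the sweet spot at the reduced-model
scale — the acceptance suite verifies that 10× tighter tolerances move
final states by far less than 0.1 %, and the heavy sensitivity sweeps
run at `1e-4` under the same verified-convergence argument. States are
clamped to zero within solver tolerance; a pool more negative than
100·abs_tol aborts the run naming the species. Concentrations entering
rate laws are clamped at zero so transient solver undershoot cannot
produce negative fluxes.

## The reference model: what it emulates, and what it does not

`build_reference_model()` generates the bundled reduced ΔsucA
central-metabolism model: PTS uptake as a two-step phosphorelay (PEP +
Crr → pyruvate + Crr~P; glucose + Crr~P → G6P + Crr, via PtsG),
glycolysis with explicit PGK/GpmA/Eno steps plus the
2,3-BPG-independent mutase isozyme (GpmM) as a constant-capacity
background, the oxidative PP branch (lumped) with the full non-oxidative
rearrangements, PDH, PEP carboxylase (CO2-limited), citrate synthase →
aconitase → ICD to AKG, glutamate dehydrogenase and export, the
glyoxylate shunt under IclR and Cra(FDP) control with succinate export
as its carbon loss, the ICD↔ICD-P cycle, a KGDH reaction present in the
template and removed by `knockout("sucAB")` (its flux is asserted to be
identically zero), 18 gene units (the 15 ranked units + ppc + pdh +
sucAB), and the biomass table above. CO2 is a dynamic species fed by
decarboxylations and removed by first-order outgassing, so PEP
carboxylase can only re-fix carbon the cell actually released —
modelling CO2 as a clamped boundary pool let high ppc dosage fix
unbounded external carbon and push molar yields above 1.

The growth profile is a logistic curve X(t) from 0.25 to ~10 g/L over
840 min tabulated at 10-min knots, with μ(t) = X′/X declining toward
stationary phase — qualitatively a fed-batch jar cultivation. Initial
glucose is 400 mM (a fed-batch-equivalent reserve chosen so that
glucose remains available across the whole horizon even under
uptake-amplifying perturbations; if glucose exhausts mid-run, every
uptake perturbation collapses onto the same total consumption and
dosage sensitivity of the uptake system becomes invisible).

**Parameterization is a stand-in, not a reproduction.** The full kinetic
parameter set behind the published sensitivity table lives in a
predecessor model's supplement and is explicitly out of scope. Reference
values here are literature-plausible round numbers (kcat 10²–10³/min,
Km near pool sizes, enzyme levels ~2 µM) tuned *once* so the model is
numerically well behaved and displays the qualitative regulatory
structure; the tuning history is not revisited per-test. A green sign
panel therefore establishes that the *mechanisms* (dosage → expression →
flux → 3PG → ICD state → branch partition → yield) are wired and signed
correctly — it does not establish quantitative agreement with the
published sensitivities, which are recorded as non-desk targets.

## Yield basis

`yield_metric()` defaults to the molar basis, (GLUxt(T) − GLUxt(0)) /
(GLCxt(0) + fed − GLCxt(T)). The reference sensitivity analysis and the
acceptance checks use the titer basis (final extracellular glutamate)
via `sim_config(yield_basis = "titer")`. Reason: growth is prescribed,
so a perturbation that starves uptake almost to zero still "grows" and
its molar yield degenerates to a ratio of two near-zero numbers —
severely attenuated uptake then *gains* molar yield by harvesting the
initial pools while evading the biomass tax. The titer basis is immune
to this ill-conditioning and, with glucose never exhausted, preserves
the ordering the molar basis gives for well-conditioned perturbations.
The source analysis does not state which basis its yield used; both are
supported, and the choice is surfaced in the configuration rather than
hidden.

## Sensitivity analysis conventions

The default grid is 61 log-spaced factors over [0.001, 1000] (10 per
decade, containing 1); tests and the acceptance script use 19 points (3
per decade) to stay inside their CPU budget — the grid is a parameter,
and the brute-force-oracle check establishes that the summary (maximum
sensitivity, scale factor) is grid-consistent. Ties in the maximum are
broken toward the factor nearest 1 in log distance (smallest
perturbation). Each sweep member simulation starts from the unperturbed
network with only that unit's copy factor scaled, so results are
independent of execution order. A failed member simulation records its
factor as failed; a sweep with more than half its members failed errors
out.

Direction classification for the curated sign panel: scale factor < 1 is
attenuate-helps; ≥ 30 is amplify-helps; in between, the curve is called
interior-optimum when the yield at the top of the grid has fallen back
below half of the best gain, else amplify-helps (the published table's
"large finite" optima — ×400–×900 — read as amplification, while ×3–×5
optima with collapse at high dosage read as interior). Units with
maximum sensitivity below 0.002 are "insensitive". The curated panel
and the ≥12/16 match criterion acknowledge that a reduced stand-in
cannot reproduce every direction: in the shipped model, crr classifies
as interior-optimum (its PEP-consuming phosphorelay arm turns high
dosage costly), ppc as insensitive, pdhR as attenuate-helps (its
repression target PDH is ACCoA-limiting here), and tpiA as
amplify-helps — all four are documented mismatches; the twelve others,
including every mechanistically central unit, match.

## Degenerate inputs and edge policies

Knocking out an already-removed unit warns and returns the network
unchanged. `apply_copy_factor(·, 1)` returns an identical network, so
the factor-1 sweep member reuses the baseline run bit-for-bit. Yield is
an error (not NaN) when no substrate was consumed. Boundary species are
never drained, never diluted, and have identically zero derivatives.
Machinery interpolation clamps outside the table. The model-file parser
reports the offending line number; round trips are written at full
precision (`%.17g`) so read(write(x)) is exact.

## Known limitations

Acetate overflow, Mlc/EIIB sequestration, YdcI, fed-batch volume
dynamics and emergent (precursor-dependent) growth are out of scope by
design. The biomass tax can be partially evaded by perturbations that
empty precursor pools, a structural consequence of prescribing growth;
the titer yield basis and the drain shutoff bound, but do not remove,
this artifact. The reference model's quantitative sensitivities are not
comparable to the published values; only directions and mechanisms are.
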