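---
title: "From lambda trajectories to pKa: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From lambda trajectories to pKa: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phtitr)
```

## The problem

In constant-pH molecular dynamics with lambda dynamics, every titratable
site carries a continuous coordinate $\lambda$ that interpolates between
its protonated ($\lambda \approx 0$) and deprotonated
($\lambda \approx 1$) forms, and the equations of motion drive
$\lambda$ together with the atomic coordinates at a fixed solution pH.
Everything a practitioner wants afterwards — protonation fractions,
titration curves, pKa values, anomalous-ionization calls, net charge
versus pH — is a post-processing problem on those $\lambda(t)$ series.
`phtitr` implements that post-processing, and ships a seeded generator
of synthetic $\lambda$ trajectories with known ground truth so that
every stage can be validated against a closed-form answer.

The motivating system is the *E. coli* outer-membrane porin OmpF: a
trimeric channel whose 41 acidic residues per monomer control ion
selectivity and antibiotic passage, scanned over pH 1–8 in unit steps
with three independent replicas and three structurally equivalent
monomers per replica.

## Protonation fractions

Two estimators are provided, and their agreement is itself a data-quality
diagnostic:

* **threshold counting** — a frame is protonated when $\lambda < 0.2$,
  deprotonated when $\lambda > 0.8$, frames in between are excluded;
  $\theta = N_\mathrm{proto} / (N_\mathrm{proto} + N_\mathrm{deproto})$;
* **lambda averaging** — $\theta = 1 - \overline{\lambda}$, with the
  *mean* clipped to $[0, 1]$.

Clipping the mean, not each frame, is deliberate.  Emission noise
around the state centres is symmetric, so per-frame clipping at 0 and 1
would fold half of that noise back and bias the estimate by roughly
$0.4\,\sigma$ near the ends of the titration curve — two percentage
points at $\sigma = 0.05$, which would swamp the sub-1% agreement the
two estimators are supposed to exhibit on well-separated bimodal data.
With the mean-level clip both estimators agree to well under one
percentage point on generator output, and the pipeline default is
lambda averaging with threshold counting kept as the reference.

Fractions are averaged hierarchically: monomers within a replica first,
then across replicas, so the reported SD per pH point is a true
between-replica uncertainty on three nearly independent 200 ns runs.
Burn-in defaults to 0 ns (production runs are assumed already relaxed)
and is exposed as a parameter.

## pKa estimation

For a single ideal site the protonated fraction follows
Henderson–Hasselbalch; the package writes the generalized (Hill) form as

$$\theta(\mathrm{pH}) = \frac{1}{1 + 10^{\,n\,(\mathrm{pH} - \mathrm{p}K_a)}},$$

which decreases with pH and equals $0.5$ at $\mathrm{pH} = \mathrm{p}K_a$
— the convention in which $\theta$ is the *protonated* fraction of an
acid.  (The same equation sometimes circulates with
$\mathrm{p}K_a - \mathrm{pH}$ in the exponent, which contradicts that
reading; this package consistently uses the form above.)

Three estimates are computed per residue:

1. **interpolation** — the pH where the curve crosses $\theta = 0.5$,
   solved linearly between the bracketing grid points.  Noisy curves are
   first regularized to be non-increasing by pooled-adjacent-violators
   (`stats::isoreg` on $-\theta$), which guarantees a unique crossing;
   a grid point landing exactly on 0.5 resolves to that grid pH.
2. **HH fit** — unweighted least squares with the pKa as the only free
   parameter ($n \equiv 1$), bracketed within 5 pH units of the grid and
   solved by Brent's method, initialized at the interpolated value.
   Replica SDs are reported but not used as weights (no weighting is
   assumed in the emulated protocol).
3. **Hill fit** — both $\mathrm{p}K_a$ and $n$ free, bound-constrained
   ($n \in [0.05, 5]$) L-BFGS-B with a Nelder–Mead polish when the line
   search stalls at a near-exact optimum.

On clean HH data the three agree to better than 0.05 pKa units; the
residual difference between interpolation and fitting is the chord
error of linearizing a sigmoid over a unit grid step (zero when the pKa
sits on a grid point or halfway between two, maximal in between — about
0.03 at worst, 0.02–0.03 on average over a uniformly placed panel).

A curve that never crosses 0.5 inside the scanned range cannot yield a
number; it yields a **censored** estimate at the scan boundary:
`"< 1"` for residues that stay deprotonated (always charged, for an
acid) and `"> 8"` for residues that stay protonated (always neutral)
on the default 1–8 grid.  Censoring is kept as a typed bound — not a
sentinel value — through every downstream computation, and published
tables mixing limits (`"< 1"`, `"< 0"`) parse losslessly.

## Benchmarking pKa predictors

`compare_report()` computes pairwise RMSD and Pearson matrices over a
residues-by-methods table, plus per-method RMSD against a designated
reference.  Two masking policies are available: `pairwise` drops a
residue only from pairs in which it is censored in either member, and
`complete` drops any residue censored in *any* method from every
statistic, so all pairs share one benchmark set — the convention when a
fixed collection of anomalously ionizing residues is excluded from a
whole comparison.  When a composition table is supplied, statistics are
computed on pKa *shifts* (prediction minus model pKa); pairwise RMSDs
are identical on shifts and raw values because the per-residue model
pKa cancels in the difference, while Pearson correlations do depend on
the model assignment.  Reports round to two decimals for display and
keep full precision in JSON.

The bundled panel `ompf_pka_panel_synthetic.csv` (41 OmpF-style acidic
residues, 7 methods) is **synthetic**: the eight anomalously ionizing
residues carry published values verbatim, and the remaining entries are
constructed analytically — per-method deviations from the reference
column live in a fixed two-dimensional subspace spanned by vectors
orthonormal under the root-mean-square inner product — so that the
panel's pairwise summary statistics equal published benchmark values
exactly and the comparison engine can be validated against analytically
known ground truth.  It is a validation instrument, not a data release:
individual synthetic cells carry no per-residue meaning.

## Net charge versus pH

Each residue contributes $-(1-\theta)$ (acids) or $+\theta$ (bases) at
its assigned pKa; the per-monomer curve is the plain sum — no
electrostatic coupling, no spatial weighting, deliberately.  Censored
residues enter as fixed charges (censored below the scan: permanently
$-1$; above: permanently neutral), matching their observed behaviour
rather than extrapolating a number past the data.  Basic residues with
no assigned pKa stay fully protonated across the acidic scan.  The
null model assigns every residue its model pKa.  For comparison with
measured reversal-potential series, curves are normalized to their
values at pH 2 and pH 8; the package makes no attempt to model the
electrophysiology beyond that normalization, since net charge alone
does not determine conductance or reversal potential.  An *effective*
Hill fit of the normalized aggregate curve summarizes whole-protein
titration; spreading site pKa values flattens the aggregate, so the
effective $n$ falls below 1 even when every site is ideal.

## Microstate heterogeneity and apparent cooperativity

A Hill coefficient below 1 is conventionally read as negative
cooperativity, but the same shallow curve arises with *no* site–site
interaction when a residue exchanges slowly between conformations with
distinct pKa values: the observed curve is then the weighted mixture
$\theta(\mathrm{pH}) = \sum_j w_j\,\theta_{HH}(\mathrm{pH}; \mathrm{p}K_{a,j})$.
`fit_mixture()` fits that model with simplex-constrained weights and
multistarts seeded from quantiles of the curve, guarded by parsimony:
the two-component fit is kept only when it reduces the residual sum of
squares at least four-fold over the single-component fit (and a
single-component fit that is already essentially exact short-circuits
the comparison).  The guard factor and the companion "shallow
titration" flag ($n < 0.8$) are package choices, exposed as arguments,
since no quantitative criterion is standard.

`apparent_hill_vs_separation()` maps the phenomenon quantitatively: for
equal-weight symmetric mixtures the least-squares Hill coefficient is 1
at zero separation and falls monotonically — about 0.80 at
$\Delta\mathrm{p}K_a = 1$, 0.54 at 2, and 0.38 at 3 (brute-force global
grid search confirms these are the global optima).  Coefficients in the
0.3–0.4 range therefore point to conformer pKa separations of roughly
3 pH units.  Complementary trajectory-level diagnostics:
`persistent_intervals()` finds long single-state episodes (a residue
staying protonated for tens of ns at a pH where it should titrate
freely), and `state_trace_correlation()` correlates the protonation
indicator with any structural trace (RMSD-like or dihedral-like series
are consumed as generic time series; the package does not compute them
from coordinates).

## The synthetic generator

`simulate_lambda()` draws from two coupled Markov chains per frame: a
conformer chain re-drawn from the mixture weights at rate
$1/\tau_\mathrm{exch}$ and a protonation chain re-drawn from its
conformer-conditional stationary probability at rate
$1/\tau_\mathrm{prot}$.  Both chains have exact stationary laws and
exponential autocorrelation, so the variance of a time-averaged
fraction has the closed form used throughout the tests,

$$\mathrm{Var}[\hat\theta] \approx \frac{2}{T}\Big(
  \tau_\mathrm{prot}\, \mathbb{E}_w[\theta_k(1-\theta_k)]
  + \tau_\mathrm{exch}\, \mathrm{Var}_w[\theta_k]\Big),$$

with the second term absent for single-conformer sites.  Emission
noise is Gaussian, truncated *symmetrically* to $\pm 0.1$ around the
state centre (hence $\lambda \in [-0.1, 1.1]$ always); a one-sided cut
at the box edge would shift the per-state mean and bias lambda-averaged
fractions near the curve extremes.  No attempt is made to mimic the
inertial dynamics, barrier re-crossings or interpolated-charge
energetics of real lambda dynamics — downstream analysis senses only
occupancy and correlation time, which is exactly what the generator
prescribes.

Defaults: frame interval 0.01 ns, protonation relaxation 0.5 ns,
conformer exchange 50 ns, emission sd 0.05.  The exchange time yields
rare, tens-of-ns single-conformer excursions in a 200 ns run — the
persistent-interval phenomenology — and the relaxation time gives an
effective sample size of $T/(2\tau_\mathrm{prot})$ per trace.  One
consequence is worth stating plainly: with these kinetics the running
mean of even a nine-trace average at $\mathrm{pH} = \mathrm{p}K_a$ has
a standard error of about 0.05 after 10 ns, so a $\pm 0.02$
convergence band is typically not reached until several tens of ns
into a run.  Generator-based sampling at this correlation time simply
does not settle within 10 ns, and the test suite documents (rather
than hides) that fact; real lambda-dynamics output with faster
protonation kinetics converges correspondingly faster.

Reproducibility is hierarchical: every (residue, monomer, replica, pH)
file gets a sub-seed from a stable hash of the master seed and its
indices, so a dataset regenerates bit-for-bit while files stay
mutually independent.  Conformers with identical pKa are merged at
model construction, which makes degenerate mixtures literally the
single-conformer model, random stream included.

## What passing tests do and do not show

The generator emulates occupancy statistics, two-state emission, slow
conformer exchange and the monomer/replica hierarchy.  It does not
emulate coupled-site electrostatics (coupling appears only through
conformer-specific pKa values), pH-dependent conformational drift,
force-field or barrier-height physics, or autocorrelation structure
beyond a single exponential per chain.  Tests passing on generator
output therefore validate the *analysis* — estimators, averaging,
fitting, censoring, masking, mixture identification — not the physics
of any particular simulation engine.

Problem sizes used by the test suite are chosen to exercise the
study's own geometry at tractable cost: single trajectories of 20 ns
for estimator-agreement properties, 200 ns at the full
3-monomer, 3-replica hierarchy for pKa-recovery checks, 1000–2000 ns
single runs for oracle-equivalence checks at 3 standard errors, and a
41-residue synthetic panel for the interpolation-versus-fit bound.

## Known limitations

* No multistate reweighting across pH and no autocorrelation-aware
  error models beyond the closed-form SE above.
* Mixture fitting is restricted to small $k$ (default 2) with an RSS
  guard rather than information-criterion model selection; on noisy
  replica-scale curves the recovered weights of a slow-exchange site
  are only as good as the conformer sampling of the input run.
* Net-charge curves treat the protein as a sum of independent sites;
  absolute charges for a real protein require its full ionizable
  inventory, which is an input, not something the package infers.
* Only the xvg dialect is parsed; other trajectory formats and
  structure files are out of scope.
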