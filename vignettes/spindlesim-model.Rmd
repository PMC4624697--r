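---
title: "The spindlesim model: motor-driven chromosome congression and bi-orientation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The spindlesim model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`spindlesim` is a three-dimensional agent-based simulator of mitotic
chromosome congression and bi-orientation in a mammalian cell. This
vignette describes the model, its assumptions, the parameters that matter,
and the numerical and design choices the package makes where the science
leaves room.

## Geometry and agents

The cell cortex is a hard ellipsoid with semi-axes $a$ (default 15 µm,
along the pole–pole axis $x$), $b = 0.9a$ and $c = 0.7a$. Two spindle
poles sit fixed at $(\pm a/2, 0, 0)$; pole separation dynamics are outside
the model's scope. Microtubules (MTs) are straight rays from a pole in a
uniformly random direction, described by a length, a growth phase, and an
optional scaffold flag. At nuclear-envelope breakdown ($t = 0$), $n_C$
chromosomes (default 46) are released uniformly in a nuclear sphere of
radius $0.65a$. A chromosome carries a disk of radius $r_C$ representing
the cross-section of its arms (normal to the $x$ axis, the plane into
which polar ejection forces align arms; an orientation-free spherical
cross-section is available via `arm_geometry = "sphere"`) and a
kinetochore interaction sphere of radius $r_k$, split by the mid-plane
normal into a left and a right hemisphere with $N_k$ end-on slots each.

## Microtubule dynamic instability

Each dynamic MT grows at $v_g$ or shrinks at $v_s$ and switches
stochastically: catastrophes at rate
$p_{cat} = p_{cat,0} e^{-F/F_{cat}}$ and rescues at rate
$p_{res} = p_{res,0} e^{+F/F_{res}}$, where $F \ge 0$ is the tension
transmitted to the tip by an end-on coupling (zero for unattached MTs;
compression is not modelled, so tension stabilizes growth, consistent
with kinetochore catch-bond measurements). Rates convert to per-step
probabilities exactly, $1 - e^{-r\,\Delta t}$, which stays correct for the
large catastrophe rates reached in the depolymerase-overexpression
sweeps. Lengths are clamped at the cortex (no forced boundary
catastrophe); an MT shrinking to zero length collapses. In fixed-$N$ mode
it is immediately renucleated in a fresh random direction from the same
pole, keeping the MT number exactly constant; in nucleation mode it is
removed while new MTs appear at each pole as a Poisson process of rate
$k_{nucl}$. A fraction $p_{sc}$ of MTs forms a permanent interpolar
scaffold: their directions are resampled so each ray passes within
$0.45a$ of the cell centre, they span to the cortex, never switch phase,
and have infinite age.

## The motor program

Chromosome transport is driven by three motor systems:

* **Polar ejection forces (PEF).** Every MT whose segment crosses the arm
  disk within $r_C$ of the chromosome centre contributes $F_{PEF}$
  (0.5 pN) along its plus-end direction. PEFs push chromosomes away from
  the poles and grow linearly with the MT number — the mechanism that
  closes the upper edge of the MT-number window.
* **Kinetochore dynein.** Chromosomes released outside the shell of
  radius $0.45a$ start dynein-driven: they link laterally to the nearest
  MT of their nearest pole (any age) and are pulled with $F_{DYN}$
  towards the minus end, i.e. to the pole, where they are held against
  the PEFs.
* **CENP-E.** Chromosomes released inside the shell start CENP-E-driven.
  A dynein chromosome held within `delta_pole` of a pole is permanently
  switched to CENP-E as soon as a long-lived track — an MT older than
  `tau_MT` (or scaffold) emanating from that pole and pointing towards
  the cell interior, the geometry of detyrosinated spindle MTs — passes
  through the pole region; the kinetochore is reeled onto that fiber and
  slides with $F_{CENPE}$ towards the plus end, away from the pole.
  Because eligible tracks always belong to the chromosome's nearest pole,
  rides are plateward everywhere and flip direction at the mid-plane, so
  laterally transported chromosomes oscillate about the metaphase plate.

Free chromosomes move overdamped, $r \leftarrow r + F\,\Delta t/\eta$,
with hard radial projection back inside the cortex.

## End-on attachment kinetics

When CENP-E is active and the chromosome is outside the pole regions, any
MT tip inside the kinetochore sphere occupies a free slot of the
hemisphere containing it (ties go to the hemisphere facing the MT's own
pole); lateral links are dropped while end-on attachments exist. Each
attachment is a zero-rest-length harmonic coupling of stiffness $k_k$.
The kinetochore interface is far stiffer than the chromosome drag is
slow: $\eta/k_k$ would exceed the slip-bond lifetime at any appreciable
load, so the package treats coupled chromosomes quasi-statically — a
chromosome holding attachments sits at the force balance of its attached
tips and the remaining motor forces, and the tip loads are the
equilibrium spring forces. This is the stiff-spring limit; it makes
amphitelic configurations carry balanced tension while syntelic and
externally loaded grips carry the full motor load.

A chromosome is classified `STABLE` (amphitelic) when its left hemisphere
holds at least one MT from the left pole *and* its right hemisphere one
from the right pole; monotelic, syntelic and crossed configurations are
`UNSTABLE`. Unstable attachments are slip bonds
($p_u = p_{u,0}e^{+F/F_u}$), stable ones catch bonds
($p_s = p_{s,0}e^{-F/F_s}$), and the growth of stably attached MTs is
slowed exponentially by load. A detached MT is refractory towards that
kinetochore for `tau_refract` (5 s) or until its tip leaves the
interaction sphere — without this, a detached tip still in range would
re-bind on the next step and detachment would have no effect. End-on
attachments do not form within `delta_pole` of a pole, reflecting the
polar kinase activity that destabilizes kinetochore attachments near
centrosomes; without this rule, near-pole grips under strong PEF load
ratchet chromosomes onto the cortex behind the poles.

## Observables

Congression is scored as the first instant every chromosome lies in the
central slab $|x| \le \varepsilon a$ (default $\varepsilon = 0.1$, i.e. a
1.5 µm half-width at full scale); bi-orientation as the first instant
every chromosome is simultaneously `STABLE`. Both are censored at their
deadlines (defaults $10^3$ s and $10^5$ s). Ensembles aggregate into
empirical probability curves (censored runs stay in the denominator) and
median event times. In nucleation mode the MT count follows the
birth–death kinetics $dN/dt = k_{nucl} - k_{out} N$, with closed form
$N(t) = (k_{nucl}/k_{out})(1 - e^{-k_{out}t})$; `fit_kout()` profiles the
least-squares fit exactly so the search is one-dimensional and
derivative-free.

## Parameters

Defaults (see `spindle_params()`): $r_k = 0.3$ µm, $r_C = 1.2$ µm,
$N_k = 25$ (25–50 admissible; 25 reproduces the ~25 MTs per kinetochore
observed at saturation), $k_k = 100$ pN/µm, $v_g = 12$, $v_s = 14$
µm/min, $F_g = 6$, $F_s = 4$ pN, $p_{cat,0} = 0.058$/s (unloaded;
0.058–0.58 admissible), $p_{res,0} = 0.045$/s, $F_{cat} = 2.4$,
$F_{res} = 2.3$ pN, $p_{u,0} = 0.1$/s, $p_{s,0} = 0.001$/s,
$F_u = F_s = 4$ pN, $F_{PEF} = 0.5$ pN per MT, $F_{CENPE} = F_{DYN} = 50$
pN per motor group, $p_{sc} = 0.1$, $\tau_{MT} = 60$ s, $n_C = 46$,
$N_{MT} = 10^4$.

Choices the package had to make:

* **Drag coefficient.** The literature-style estimate from cytoplasmic
  viscosity ($10^{-7}$ kg/s) implies ~500 µm/s chromosome speeds under a
  50 pN motor group — the cell would be crossed in tens of milliseconds —
  while a drag reproducing ~3 µm/min transport makes the kinetochore
  spring relax over ~10 s and no end-on attachment could survive its
  capture load. `spindlesim` separates the two roles: the stiff end-on
  coupling is quasi-static (as the viscosity estimate implies), and
  $\eta$ sets only the motor transport speed. The default
  $\eta = 200$ pN·s/µm gives 50 pN groups 0.25 µm/s (15 µm/min), in the
  physiological range of kinetochore cargo transport.
* **Pole-region radius.** `delta_pole` (2.5 µm) defines "at the pole":
  the radius at which dynein is replaced by CENP-E, within which the
  whole aster counts as within latching reach, and within which end-on
  attachments are suppressed. It must exceed the dynein–PEF stall
  distance (1.3–2 µm at the densities studied); at high MT numbers the
  stall point moves outside `delta_pole` and peripheral chromosomes never
  escape the poles — the congression failure at the upper edge of the
  MT-number window.
* **Catastrophe rate for the population experiment.** The admissible
  range spans unloaded wild type to depolymerase overexpression. The
  nucleation-mode preset uses $p_{cat,0} = 0.205$/s, the value at which
  the per-MT collapse rate $1/\mathbb{E}[\text{lifetime}]$ equals the
  0.09/s relaxation that the closed-form fit of the population transient
  reports; the fit then recovers $k_{out} = 0.090$/s. Note that the
  simulated MT lifetime is *not* exponential (rescue-sustained length
  excursions give it a slow tail), so the ensemble-mean count approaches
  the last percent of its plateau more slowly than the memoryless
  closed form: the 99%-of-plateau crossing lands near 60–75 s rather
  than $\ln(100)/k_{out} \approx 51$ s, and with 100-run ensembles the
  mean count deviates from the best single-exponential by several
  standard errors through the rise (a young MT cannot collapse before its
  first catastrophe completes, so early deaths are delayed relative to a
  memoryless population). The fitted rate, the directly measured collapse
  rate and the plateau all agree with the closed form; the residual shape
  (2–4% of the signal) does not.
* **Time step.** $\Delta t = 0.1$ s resolves all event probabilities
  ($\max r\,\Delta t \approx 0.02$ at defaults) and keeps per-step
  chromosome displacements well below $r_k$; `check_timestep()` refuses
  to integrate otherwise.

## What the simulations emulate, and what they do not

Runs at the full scale of the paper-grade experiments ($a = 15$ µm,
46 chromosomes, $10^4$–$3\times10^4$ MTs, $10^5$ s bi-orientation
deadlines) take hours per run on one CPU; ready-to-run configurations for
them ship in `inst/extdata/configs/`. The package's test suite instead
uses a half-scale cell ($a = 7.5$ µm, 10 chromosomes, 2000 MTs, deadlines
1500 s / 4000 s, and $\varepsilon = 0.3$: the metaphase plate is
relatively thicker in a small cell because the kinetochore and attachment
geometry keep their absolute size, so the slab is set between the
observed plate thickness (~2 µm) and the pole regions (|x| > 3.2 µm),
following the same calibration rule as the full-scale default — congress
must be reportable for a wild-type plate while a pole-trapped chromosome
must fail it. Search-and-capture times scale with
the absolute density of MT tips, so shrinking the cell together with the
MT number preserves the per-volume and per-kinetochore densities of the
full-scale system and, with them, the qualitative phenotypes: wild-type
congression and bi-orientation, knockdown failures, and the non-monotonic
MT-number dependence. The model contains no thermal noise (the equation
of motion is deterministic between stochastic events), no
chromosome–chromosome excluded volume, no arm elasticity, no MT
flexibility and no explicit error-correction biochemistry beyond the
stable/unstable dichotomy; passing desk-scale tests demonstrates the
mechanistic pipeline, not quantitative agreement with any real cell type.

Two documented divergences from the source phenomenology remain: the
99%-of-plateau transient of the nucleation-mode MT count sits near 73 s
(see above), and suppressing polar ejection forces does not lower the
desk-scale bi-orientation probability — in this implementation PEF load
sheds attachment precursors and pushes chromosomes off the tip-rich
spindle axis, so the knockout mildly accelerates bi-orientation while
widening the plate. Both are properties the tests measure honestly rather
than assert away.
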