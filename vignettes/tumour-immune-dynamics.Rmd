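---
title: "Modelling tumour evolution under chemotherapy and checkpoint blockade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tumour evolution under chemotherapy and checkpoint blockade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoICB)
```

## The models

chemoICB studies how a tumour's *antigenic* composition shapes its response
to chemotherapy, immune checkpoint blockade (ICB), and their combination.
Tumour cells are classified by their immune status:

* **NC** — antigenically neutral cells, invisible to the immune system;
* **AC** — antigenic cells, carrying neoantigens but present at too low a
  frequency to be recognised (heterogeneity model only);
* **IC** — immunogenic cells, actively attacked by the immune system;
* **EC** — immune-escaped cells (e.g. checkpoint-ligand overexpression),
  no longer killed.

Two nested models are provided. The **homogeneity model** (`"ihom"`) is the
classical predator–prey picture: NCs divide at rate $r_1$ and transform into
ICs with probability $\mu_1$ per division; ICs divide at $r_2$, die from
immune predation at rate $d$, and escape into the EC pool in a fraction
$p_e$ of divisions; ECs divide freely at $r_2$. The **heterogeneity model**
(`"ihem"`) inserts the AC compartment and makes immune recognition
*negative frequency-dependent*: ACs become visible at rate $\mu_2 f_1$ with
$f_1 = A/(N+A)$, and ICs slip back under the radar at rate $\mu_3 f_2$ with
$f_2 = I/(N+A+I)$. A rare clone therefore evades selection not by mutating
away its antigens but simply by being rare — the mechanism by which a highly
heterogeneous tumour blunts immune attack. Every pair of cells additionally
competes at rate $c$, one of the two dying; this quadratic loss caps every
population at carrying capacities of order $\text{rate}/c$.

The untreated heterogeneous system is

$$
\begin{aligned}
\dot N &= r_1(1-\mu_1)N - r_1\mu_1 N - cN\,T,\\
\dot A &= r_1 A + r_1\mu_1 N - \mu_2 f_1 A + \mu_3 f_2 I - cA\,T,\\
\dot I &= (r_2 - d)I + \mu_2 f_1 A - \mu_3 f_2 I - 2 r_2 p_e I - cI\,T,\\
\dot E &= r_2 E + r_2 p_e I - cE\,T,
\end{aligned}
$$

with $T = N+A+I+E$; the homogeneous system drops the $A$ equation and sends
the mutation flux $r_1 \mu_1 N$ straight into $I$. Transformation processes
are written in their compact single-cell form (NC $\to$ IC rather than
separate NC $\to$ NC+IC and NC $\to$ IC+IC channels); `ihom_full_rhs()`
exposes the split-channel variant for users who want the asymmetric and
symmetric divisions separately.

## Therapy

Drugs follow square-wave pharmacokinetics: each cycle of length
$T = 2\pi/f$ (21 days at the default $f$) starts with a half-cycle of
constant-rate infusion ($v_m$, $v_b$) followed by a drug-free recovery
half-cycle, with first-order elimination at rate $\gamma$ throughout:
$\dot M = -\gamma M + v_m(t)$, likewise for the ICB concentration $B$.
The closed-form piecewise-exponential solution (`drug_closed_form()`) is
exact for this input class and doubles as the integrator's oracle and as the
drug signal of the stochastic engine.

Three effects couple the drugs to the cells:

1. **Chemotherapy kill.** Cells of type $X$ die at rate
   $K_X\,(1 - e^{-M})$ — the saturating kill law, linear at low
   concentration and plateauing at high concentration. The sensitivity
   coefficients order the cell types ($K_N = K_A = K_I = 0.9$ for the
   fast-cycling compartments, $K_E = 0.6$ for escaped cells, consistent
   with checkpoint-overexpressing cells responding poorly to cytotoxics).
   We define the kill rate directly by the sensitivity coefficient, not
   additionally scaled by the type's division rate: the coefficient is the
   *fractional kill* at drug saturation per unit time, and this convention
   is required for the reference dose ($v_m = 5$) to clear the
   neutral/antigenic compartments faster than the frequency-dependent
   recycling loop between ACs and ICs replenishes them — the regime in
   which chemotherapy strips the heterogeneous tumour down to its escaped
   fraction and combination therapy is curative. Under the alternative
   (rate-scaled) convention the $A \rightleftharpoons I$ loop stays
   supercritical at the reference parameters and no therapy combination
   clears the tumour; `treated_rhs()` implements the convention stated
   here and the test suite pins it against independent transcriptions of
   all eight treated systems.
2. **Immunotoxicity.** Chemotherapy damages the immune system itself:
   immune killing is attenuated to $d\,(1 - K_d (1-e^{-M}))$.
3. **ICB conversion.** Blockade restores recognition of escaped cells,
   converting EC back to IC at rate $k B$.

The **alternating protocol** moves the ICB infusion to the second
half-cycle (chemo first, blockade during recovery) and engages the healing
factor $h \in [0,1]$, which *scales the immunotoxic damage*:
$d\,(1 - h\,K_d(1-e^{-M}))$. Thus $h = 0$ means the immune system heals
completely before blockade and $h = 1$ means no benefit; outcomes degrade
monotonically as $h$ grows (the `protocol_comparison()` grid makes this
directly checkable).

## Parameters

| field | meaning | default | unit |
|---|---|---|---|
| `r1` | NC/AC division rate | 1 | /day |
| `r2` | IC/EC division rate | 0.5 | /day |
| `mu1` | antigenic mutation probability per division | 0.5 | — |
| `mu2` | immune recognition coefficient | 0.6 | /day |
| `mu3` | heterogeneity shielding coefficient | 0.05 | /day |
| `d` | immune killing of ICs | *per experiment*, $[0,1]$ | /day |
| `c` | competition death rate | $10^{-8}$ | /cell/day |
| `pe` | escape fraction of IC divisions | $10^{-5}$ | — |
| `gamma` | drug elimination rate | 0.9 | /day |
| `KN,KA,KI` | chemo sensitivity, fast compartments | 0.9 | — |
| `KE = Kd` | EC sensitivity / immunotoxicity | 0.6 | — |
| `k` | ICB conversion efficacy | 1 | /conc/day |
| `lam` | neoantigen antigenicity parameter | 0.2 | — |
| `h` | healing factor (alternating protocol) | 0.5 | — |

`d` deliberately has no default: the growth studies scan it and the therapy
studies fix it at 0.5 (intermediate killing). Doses live on the protocol:
the reference course is $v_m = 5$, $v_b = 0.9$, twelve 21-day cycles.
`KE` is kept equal to `Kd` (escaped cells share the immune compartment's
chemosensitivity) and `validate_params()` enforces it.

The antigenicity parameter is read as an exponential **rate** (mean
antigenicity $1/\lambda = 5$); `sim_config(lam_convention = "scale")`
switches to the mean-$\lambda$ reading. Antigenicity feeds only the
diversity metrics, not the dynamics, so this choice does not affect
population trajectories.

## The stochastic engine

`simulate_tumor()` runs the same processes per cell in a fixed-step scheme:
in a step of length $\Delta t$ each cell experiences at most one event,
selected by a single uniform draw against the cumulative probabilities
$\text{rate}\cdot\Delta t$ (division, immune death, the frequency-dependent
transitions, chemo kill, ICB conversion, and competition at the per-capita
mean-field rate $c_{\text{sim}}(n-1)$). The engine refuses steps in which
any cell's total event probability exceeds 0.1, keeping multi-event
probabilities second order; a step-halving test in the suite checks that
ensemble means are insensitive to $\Delta t$.

Neoantigen bookkeeping follows the division process: a *neutral* cell's
division draws a Poisson($\mu$) mutation count for the daughter pair, with
$\mu = -\ln(1-\mu_1)$ so that $P(m \ge 1) = \mu_1$ exactly matches the
compartment models' transformation probability. A division with $m \ge 1$
realises the transformation: the mutated offspring becomes an AC
(heterogeneity model) or IC (homogeneity model) *founded* with those $m$
antigens, each antigen drawn fresh from the exponential antigenicity
distribution and given a never-reused integer id. Daughters of non-neutral
divisions inherit their parent's antigen set unchanged, so a lineage's set
only ever grows and a clone is identified by its founding antigens. We
considered letting every division keep accumulating antigens; that makes
per-cell antigenicity grow without bound with lineage depth, so the spread
of cell antigenicity is dominated by lineage-age differences rather than by
clonal structure, which is not the quantity the diversity analyses are
about.

Mean-field correspondence is exact in rates: every per-cell probability is
the per-capita term of the matching ODE (the transformation flux is
$r_1 \mu_1 N$ — one calibrated draw per division, not independent draws per
daughter, which would double the flux). Two caveats matter in practice and
shape the tests:

* the synchronous scheme compounds within-step births only at the next
  step, a deficit of order $r^2 \Delta t/2$ per day in exponential phases —
  negligible at $\Delta t = 0.005$–$0.01$ against Monte-Carlo error;
* from a single founder cell the *ensemble mean* is not the ODE solution:
  early demographic noise disperses the timing of each replicate's logistic
  rise, and the nonlinear saturation does not average out. Mean-field
  agreement is a law-of-large-numbers statement, so the agreement tests
  start both descriptions from a macroscopic founder population (hundreds
  of cells) and compare wherever the deterministic total stays above a few
  hundred.

Simulation-scale choices are deliberate and fixed: ensemble runs use
$c_{\text{sim}} = 10^{-3}$ (equilibria of a few hundred cells; hundreds of
replicates in seconds); the diversity study uses $c_{\text{sim}} =
2\times10^{-5}$ (about $1.2\times10^4$ cells at detection) because a single
chemo cycle bottlenecks the population to roughly $10^{-3}$ of its
pre-therapy size — a macroscopic tumour survives that, a few-hundred-cell
desk tumour does not — and a 100-cell neutral founder pool, because the
critical neutral lineage of a single founder dies after seeding only a
couple of antigenic clones, leaving a near-monoclonal tumour with no
diversity to lose. Growth replicates condition on establishment (a fresh
derived seed on extinction): the analyses concern tumours that grew.

## Metrics and experiment conventions

* **Shannon diversity** is computed over *antigen incidence*: $q_j$ is
  antigen $j$'s share of all carrier counts and $H = -\sum_j q_j \ln q_j$
  (nats; a clone-level variant groups cells by identical antigen sets).
* **Cell antigenicity** is the sum of a cell's antigen antigenicities, and
  its **variation** is the population variance (denominator $n$, neutral
  cells included at 0).
* **Relative tumour size** is total population at the end of the course
  (plus one drug half-life) divided by the total at therapy start.
* Therapy experiments grow the tumour untreated from one cell until
  *detection* at half the escaped carrying capacity
  ($0.5\,r_2/c = 2.5\times10^7$ cells), then start the course at an
  on-phase. **Cure** is declared when the total drops below one cell (an
  ODE never reaches exactly zero; sub-unity populations are non-physical).
  **Relapse** is flagged when the post-nadir total regrows to twice the
  nadir; the escaped-cell share *of the relapse* is measured once the
  regrown tumour recovers half its pre-therapy size, because at the moment
  regrowth first becomes detectable the shrinking antigenic/immunogenic
  remnant still dominates the census. Per-cycle regrowth is reported both
  as an absolute amplitude (peak-after-nadir minus nadir, in cells) and as
  a ratio; the ratio mechanically penalises arms that reach deeper nadirs.
* The sensitivity analysis perturbs one rate at a time by ±20 % (clipped
  to valid ranges; `KE` moves with `Kd`) and re-runs growth *and* therapy
  from scratch under the perturbed rates. Its course is deliberately long
  (36 cycles): the question asked is whether sustained combination therapy
  still cures, not whether a fixed 12-cycle course is exactly long enough.

## Numerical choices

Integration uses `deSolve` (lsoda by default) at `rtol = 1e-8`,
`atol = 1e-10` — populations span $1$ to $10^8$ — and is restarted at every
half-cycle switch time so the discontinuous infusion never crosses an
adaptive step; the drug components are verified against the exact closed
form at every boundary. Reported abundances are clamped at zero on output
only; the solver state is never touched. Quasi-equilibrium (for the
composition scans) means a relative change below $10^{-8}$ per day in every
compartment, with a 3000-day cap and a `converged` flag. Ties to
experiment reproducibility: every stochastic run derives all randomness
from one seed, replicate $r$ of a batch uses a seed derived from
`(base_seed, r)`, and identical manifests produce byte-identical outputs.

## Reference regimes and known limitations

At the reference therapy point ($d = 0.5$, $v_m = 5$, $v_b = 0.9$,
21-day cycles) the package reproduces the qualitative response regimes that
motivate combination therapy: blockade alone cannot cure the heterogeneous
tumour (nothing kills the frequency-shielded AC pool); chemotherapy alone
produces a deep response followed by relapse of an escaped-cell-dominated
tumour (immunotoxicity hands ECs their window); the concurrent combination
is curative; and the alternating schedule with $h = 0.5$ cures with
markedly smaller per-cycle regrowth.

One regime deserves a caution. For a *homogeneous* tumour under blockade
monotherapy the escaped compartment's per-cycle growth factor is exactly
$\exp(r_2 T - k v_b T/(2\gamma))$ in the periodic drug steady state, and at
the reference values $r_2 = k v_b/(2\gamma)$ **exactly**: the EC pool sits
on a knife edge, decaying only through the $2 r_2 p_e$ escape drain
($10^{-5}$/day) and the quadratic competition term (algebraic, $\sim
1/(ct)$). Extinction of a macroscopic homogeneous tumour under blockade
alone is therefore unreachable on any realistic horizon at this parameter
point — the corresponding panel of `run_therapy_panel()` honestly reports
no cure, and the matching expectation in the acceptance suite documents the
discrepancy rather than papering over it. For the same structural reason,
low-dose chemotherapy ($v_m \le 1$) cannot suppress the AC compartment
(its per-cycle balance $r_1 T - \mu_2 T - K_A \int (1-e^{-M}) \approx
+4.6$ stays positive however much blockade is added), so the low-chemo /
high-ICB corner of the dose grid responds only partially, and the ±20 %
sensitivity scan finds three perturbations (`r1` up, `mu2` down, `KA`
down) that push the antigenic compartment's clearance margin past zero and
flip the cure verdict — a real fragility of the reference parameter point,
reported as such.

Scope limits: no spatial structure; no explicit effector-cell (T/NK/Treg)
compartments — the immune microenvironment is summarised by $d$, $\mu_2$,
$\mu_3$, $K_d$; antigenicity weights do not feed back on recognition or
killing rates, so analyses that depend on them are confined to the
diversity metrics; the stochastic engine is a fixed-step scheme, not an
exact simulation algorithm (an SSA mode is a possible extension); and no
fitting to patient data is attempted.
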