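---
title: "Synchronization cores of coupled neuromodules: model, methods, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchronization cores of coupled neuromodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncore)
```

## The model

A *neuromodule* is a recurrent network of `n` graded-response neurons
with hyperbolic-tangent transfer function, iterated in discrete time:

$$a_i(t+1) \;=\; \theta_i + \sum_{j=1}^n w_{ij}\,\tanh(a_j(t)),
\qquad i = 1,\dots,n .$$

`a` is the activation vector, `o = tanh(a)` the output (confined to the
open cube $(-1,1)^n$), `w[i, j]` the synaptic weight from neuron `j` to
neuron `i`, and `theta` the effective bias — a fixed bias plus any
stationary external input, stored as a single number per neuron because
every analysis here treats their sum as one parameter.  Activations are
a priori bounded by $|\theta_i| + \sum_j |w_{ij}|$, so orbits can never
overflow.  All indices in files, printed output, and this document are
1-based.

Two structural summaries are used throughout: the **structure matrix**
(entrywise sign of `w`, self-connections included) and the
**adjacency matrix** (0/1 off-diagonal connectivity).  Directed cycles
of the structure are classified *even* or *odd* by the parity of the
inhibitory (negative) connections they traverse; odd cycles are the
canonical source of oscillation in these networks, and
`cycle_census()` enumerates them with parity.

## Coupled pairs and the synchronization condition

Two modules A and B of equal dimension, joined by coupling blocks
`wAB` (B→A) and `wBA` (A→B), form a `2n`-neuron module with block
weight matrix `[[wA, wAB], [wBA, wB]]`.  Unequal dimensions are
rejected: complete synchronization identifies neuron `i` of A with
neuron `i` of B, and the partial synchronization of unequal modules is
out of scope for this package.

If

$$\theta^A=\theta^B,\qquad w^A - w^{BA} = w^B - w^{AB},\qquad
w^{AB}\neq 0,\qquad w^{BA}\neq 0,$$

then the diagonal $M^s=\{a=b\}$ is invariant.  In the adapted
coordinates $\xi=(a+b)/2$, $\eta=(a-b)/2$ the dynamics on $M^s$ is that
of the `n`-module with the **synchronization matrix** $w^+=w^A+w^{AB}$,
while transversal deviations obey the bias-free **obstruction
dynamics** $\eta(t+1) = w^-\tanh(\eta(t))$ with $w^-=w^A-w^{BA}$.
`xi_eta_step()` implements the exact transformed map for *any* pair
(the condition is not needed to change coordinates), and the package
checks numerically that it agrees with the direct route to within
rounding.

The sign pattern of `w+` is the **synchronization core**; systems with
the same core carry the same parameterized family of synchronized
dynamics, whatever their internal wiring.  A coupling is **generative**
if `w+` is nonzero at a position where both `wA` and `wB` vanish, and
**conservative** otherwise.  `sync_equivalent()` compares cores
entrywise by default; comparison up to a simultaneous neuron
relabeling is available as an explicit option, since equality of
structures as labelled matrices and equality up to isomorphism are
both defensible readings and the package does not presume which one a
user means.

### Tolerances

The synchronization condition is checked entrywise with an absolute
tolerance of `1e-9` (weights are user-specified constants, not
estimates; a loose tolerance would silently admit pairs whose manifold
is not invariant).  `sync_matrix()` deterministically returns
`wA + wAB` — not an average of the two equal expressions — so results
are bit-reproducible.

## Stability of the synchronization manifold

Three instruments, from crude to sharp:

1. **Entrywise bound** (`theorem32_check`): if every $|w^-_{ij}| <
   1/n$, the origin of the obstruction dynamics is a *global*
   attractor and synchronization is reached from anywhere.  The bound
   is implemented on absolute values although its usual statement can
   be read as a bound on signed entries: a contraction estimate
   concerns magnitudes, and the signed reading would certify any
   strongly negative matrix, contradicting the eigenvalue criterion
   below.  This is an interpretation, and it is documented as one.
2. **Spectral criterion** (`obstruction_eigen`): the linearization of
   the obstruction dynamics at the synchronized state is
   $w^-\,\mathrm{diag}(\tanh'(\xi))$ with $0<\tanh'\le 1$; if all
   eigenvalues of $w^-$ have modulus below 1 the manifold is
   asymptotically stable.  Eigenvalues are reported sorted by
   decreasing modulus (ties: real part, then imaginary part,
   descending).
3. **Transversal Lyapunov exponents** (`split_spectrum`): along a
   synchronized orbit $\xi(t)$ the tangent dynamics block-splits into
   $w^+\mathrm{diag}(\tanh'(\xi))$ (within the manifold) and
   $w^-\mathrm{diag}(\tanh'(\xi))$ (off it).  Both spectra are
   accumulated with QR re-orthonormalization at every step.  The orbit
   is stable against desynchronization iff the largest transversal
   exponent is negative; manifold-global statements require this *for
   every orbit*, which the package operationalizes by evaluating the
   exponent along each attractor found by a census — a sampled claim,
   reported as such, never a proof.

QR at every step is cheap for the dimensions this package targets
(n ≤ ~10) and avoids tangent-collapse entirely; an exactly singular
Jacobian (a zero row of `w`) legitimately sends an exponent to
$-\infty$ and is clamped to about $-690$ ($\log 10^{-300}$) so averages
stay finite.  Defaults are $10^4$ transient and $10^5$ accumulation
steps; on 2-dimensional systems that resolves exponents to about
$10^{-2}$ in well under a second.

## The attractor census

`attractor_census()` samples initial conditions in output space —
uniform on $(-1,1)^{\dim}$, clipped at $1-10^{-9}$ and mapped through
$\mathrm{artanh}$ — because outputs, not activations, are the natural
bounded coordinates of these networks.  Each orbit is iterated past a
transient, recorded, and classified:

* a minimal period $p \le$ `max_period` is sought by recurrence
  within `point_tol` over a trailing window, testing periods in
  increasing order so minimality is automatic (`p = 1` is a fixed
  point);
* otherwise the largest Lyapunov exponent decides: above `chaos_tol`
  chaotic, within it quasiperiodic; a clearly negative exponent with
  no detected period means the orbit was not resolved (for example a
  very long transient) and is labelled quasiperiodic with a
  low-confidence flag rather than guessed at.

Defaults: transient $10^4$, record $2{,}000$, `max_period` 64,
`point_tol` $10^{-6}$, `chaos_tol` $5\times10^{-3}$, `sync_tol`
$10^{-6}$.  Any detected period wins over a near-zero exponent; the
`max_period` setting records that decision.

### Deduplication

Two sampled orbits are the same attractor when their output-space
sample clouds coincide as sets.  The package compares clouds by the
**average nearest-neighbour distance** (each point's distance to the
nearest point of the other cloud, averaged both ways) with threshold
`dedup_tol = 0.1`.  The classical symmetric Hausdorff maximum was
evaluated and rejected for this purpose: for a chaotic attractor with
a two-dimensional unstable structure, $2{,}000$ recorded points leave
coverage gaps of order $10^{-1}$, so the max-based distance between
two independent samples of the *same* attractor never falls much below
0.1 at practical sample sizes — while distinct coexisting attractors
of the systems studied here sit at 0.3–2.2 on the averaged metric and
independent samples of the same attractor fall below 0.05.  The 0.1
threshold therefore has at least a factor-two margin on either side,
measured, not assumed.  After the census, clouds that ended up
overlapping (chaotic samples that explored an attractor unevenly early
on) are merged by the same criterion, and counts are always reported
together with `n_inits` and the settings — a census is a lower bound,
not an inventory.

### Invariant-manifold stratification

For coupled systems, a fraction `manifold_frac` (default 0.2) of the
initial conditions is placed exactly on the diagonal $a_0=b_0$.  This
is not cosmetic: a chaotic attractor of the synchronized dynamics
whose transversal exponent is positive is a genuine attractor of the
manifold-restricted system, but it *repels* generic orbits, and in
double precision a generic orbit never lands on the diagonal by
chance (measured on the showcase system: an asynchronous orbit's
distance to the manifold stays above 0.39 for $10^6$ steps).
Stratifying over the invariant subspace is the standard way to census
an equivariant system; synchronized-vs-asynchronous flags are still
decided by the sampled states themselves (`sync_tol` on
$\max_i|a_i-b_i|$), and for identical modules with symmetric coupling
the diagonal is preserved bit-exactly, so the flag is unambiguous.

The coupled dynamics of identical modules commutes with the block swap
$(a,b)\mapsto(b,a)$, so the attractor set must be closed under
`swap_image()`; the test suite asserts this closure on the census of
the showcase system.

### Bifurcation scans

`bifurcation_scan()` sweeps one bias entry over a monotone grid and
records the asymptotic mean output per step.  Two branch types are
recorded at every grid point: a continuation branch that carries the
state across the parameter change (following one attractor until it
disappears), and fresh random restarts that expose coexisting
branches.  Scans use shorter transients than censuses (2,000 and 100
recorded steps by default) — a scan needs density along the parameter
axis, not certainty at each point.

## The worked configuration

The package ships, as `load_fixture()` entries, the coupled system of
two identical odd 2-cycles (`w12 = 1.6 = -w21`) with one inhibitory
coupling connection `w11_coup = -4`: its core `w+ = [[-4, 1.6], [-1.6,
0]]` is generative (new self-connection), its obstruction matrix has
eigenvalues 3.2 and 0.8 (manifold destabilized), and within the
chaotic bias range of the core the censuses resolve five coexisting
attractors at `theta1 = -4` (synchronized period-3 and chaotic,
asynchronous period-6, two asynchronous chaotic) and nine at
`theta1 = -3` (synchronized period-5 and chaotic, two asynchronous
period-10, five asynchronous chaotic).  Here $w^-$ equals $-S w^+ S$
with $S=\mathrm{diag}(-1,1)$, so the synchronization and transversal
exponents coincide along every orbit — synchronized chaos in this
configuration is always transversally unstable, which is exactly why
the asynchronous attractors exist.  The conservative counterpart
(`pair_conservative`, same core, obstruction eigenvalues −0.984 and
−0.366) keeps every attractor synchronized.  The
`kii_structure_synthetic` fixture encodes only the qualitative
excitatory/inhibitory population motif it is named after and is
flagged synthetic; it is not a reference connectivity.

## Random synchronizable pairs

`random_sync_pair()` is the package's instrument for property-style
testing, and its defaults are fixed study conditions, not knobs:

* module dimension 3, edge density 0.4 beyond a guaranteed directed
  ring (strong connectivity by construction), bias magnitudes up to
  0.5 — small networks in the moderately-coupled regime where the
  interesting synchronization phenomenology lives;
* all weights are drawn on the dyadic grid $k/64$, $8\le|k|\le 64$, so
  that `wB := wA + wAB - wBA` is computed *exactly* in binary floating
  point and the synchronization condition holds with zero residual —
  invariance tests then measure the dynamics, not the generator's
  rounding;
* the obstruction matrix is rescaled by powers of two (exact) until
  its operator norm is below 0.9.  Because $a'-b' =
  w^-(\tanh a-\tanh b)$ and tanh is 1-Lipschitz, an operator norm
  below 1 makes the manifold globally attracting at every step.  A
  bound on the spectral radius would not suffice: non-normal matrices
  can amplify transversal perturbations transiently even with all
  eigenvalues inside the unit circle, and that amplification acts on
  the rounding noise a dynamical invariance test necessarily injects.
  With the norm bound, 200 generated pairs iterated 1,000 steps from
  synchronized states stay within $10^{-15}$ of the diagonal;
* with `generative = TRUE`, one coupling entry is forced at a position
  where `wA` vanishes with `wAB = wBA` there, so `wB` vanishes there
  too and the pair is generative by construction; the coupling is
  redrawn if an exact cancellation in `wB` would leave module B not
  strongly connected (modules are strongly connected by definition
  here).

What these generated systems do *not* emulate: heavy-tailed or
near-critical weight distributions, large sparse networks, unequal
module dimensions, and chaotic transversal regimes.  Tests passing on
them certify the algebra and the contraction regime, not behaviour at
criticality.

## s-decomposition

`s_decompose()` asks the inverse question: given one even-dimensional
module, which balanced bipartitions and pairings of its neurons split
the weight matrix into blocks satisfying the synchronization
condition, with both coupling blocks nonzero and (by default) both
submodules strongly connected?  The search is exhaustive over
$\binom{2m}{m}/2$ bipartitions (the A/B exchange symmetry is
deduplicated by keeping neuron 1 in A) times $m!$ pairings, because
the condition is a matrix equation whose truth depends on how
A-neurons are matched with B-neurons; guessing a canonical pairing
would silently miss decompositions.  Inputs beyond 12 neurons are
refused unless the caller raises the cap deliberately.  A
`require_connected = FALSE` flag admits feedforward submodules (which
can still share a core), and `ignore_theta = TRUE` treats biases as
free parameters of the family rather than data.

The structure-level variant `structure_s_feasible()` decides whether
*any* weight configuration with a given sign pattern is
s-decomposable.  Per paired entry position the condition reads
$x_A - x_{BA} - x_B + x_{AB} = 0$ with prescribed signs and free
positive magnitudes; writing the fixed term signs
$\sigma = (s_A, -s_{BA}, -s_B, s_{AB})$, the position is feasible iff
no sign is prescribed at all or terms of both signs are present to
balance.  (In particular a position with three nonzero prescribed
signs can still be infeasible when all three terms fall on the same
side — e.g. $s_A=0$, $s_{BA}=-1$, $s_B=-1$, $s_{AB}=+1$ forces a
strictly positive sum.  An early internal case table assumed three or
more nonzero signs were always balanceable; the brute-force magnitude
search used in the test suite is what caught that.)

## Numerical choices, in one place

* **Exact zero tests** on user-specified weights (structure, coupling
  nonzeroness); derived matrices like `w+` use a $10^{-12}$ sign
  tolerance.
* **Chaos vs. float comparison.**  On a chaotic orbit, two
  mathematically identical evaluation orders separate at rate
  $\lambda_1$ from a $10^{-16}$ seed; route-equivalence tests are
  therefore run either on regular orbits over 1,000 steps or on
  chaotic orbits over horizons short enough ($\le 40$ steps at
  $\lambda_1\approx0.38$) that the amplified rounding stays below
  tolerance.  This is a property of chaos, not of the implementations
  being compared.
* **Determinism.**  Every stochastic routine takes an explicit seed,
  derives any per-item streams from it, and restores the caller's RNG
  state on exit.  Identical seeds and settings give identical
  censuses, scans, and generated pairs.
* **Spec files** are YAML with numbers printed at up to 17 significant
  digits in a form YAML 1.1 parses as floats, so write-read
  round-trips are bit-exact; the key `n` is quoted on writing because
  YAML 1.1 would otherwise read it as a boolean, and the reader
  accepts both spellings.
* **Problem sizes.**  The shipped analyses use 500 initial conditions
  for the `theta1 = -4` census, 2,000 for `theta1 = -3`, $10^5$
  Lyapunov accumulation steps, and 200 random pairs per property
  check; the full test suite and the acceptance script each run in a
  couple of minutes on one CPU.

## Known limitations

* Census counts are lower bounds at the reported settings; basins
  below roughly $1/n_\mathrm{inits}$ of output-space volume are
  routinely missed, and chaotic-attractor counts near crises are
  sensitive to transient length.
* Quasiperiodic and long-periodic orbits beyond `max_period` are
  distinguished only by the exponent threshold, which is a labelling
  convention, not a proof of quasiperiodicity.
* Stability verdicts from sampled orbits are not rigorous global
  statements; no interval arithmetic is attempted.
* Anti-synchronization and partial synchronization (unequal module
  dimensions, or agreement up to a factor other than 1) are out of
  scope, as are couplings of more than two modules and any learning
  or continuous-time dynamics.
* The exhaustive decomposition search is factorial in the half
  dimension; it is an instrument for networks up to a dozen neurons,
  not a scalable graph algorithm.
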