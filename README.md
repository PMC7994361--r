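# syncore

Synchronization cores and modular dynamics of discrete-time recurrent
neural networks.

## The problem

Small recurrent networks of tanh neurons ("neuromodules") update their
activations by

```
a_i(t+1) = theta_i + sum_j w_ij * tanh(a_j(t))
```

where `theta_i` is the effective bias of neuron `i` and `w_ij` the
synaptic weight from neuron `j` to neuron `i`.  Coupling two such
modules A and B of equal dimension `n` through blocks `w_AB` (B to A)
and `w_BA` (A to B) gives a `2n`-neuron system.  When the
*synchronization condition*

```
theta_A = theta_B,    w_A - w_BA = w_B - w_AB,    w_AB != 0,    w_BA != 0
```

holds, the diagonal `a = b` (the synchronization manifold) is invariant:
modules that start together stay together.  On the manifold the system
behaves exactly like the `n`-neuron module with the *synchronization
matrix* `w+ = w_A + w_AB`; transversal deviations `eta = (a - b)/2`
follow the bias-free dynamics of the *obstruction matrix*
`w- = w_A - w_BA`.  The sign pattern of `w+` — the *synchronization
core* — labels a whole family of coupled systems with the same
synchronized dynamics.  A coupling is *generative* when `w+` has a
connection that neither module has on its own: the synchronized system
can then be dynamically richer than its parts.  Whether the
synchronized states are stable against desynchronization is controlled
by the eigenvalues of `w-` and by the largest transversal Lyapunov
exponent along each synchronized orbit.

`syncore` is for researchers in neurodynamics and recurrent-network
design who want to compose small modules into larger systems with a
prescribed synchronized behaviour, decide whether synchronization is
stable, enumerate the coexisting attractors of the composed system, and
decompose a given even-dimensional network into synchronizable
submodules.

## What the package does

* build, iterate, and inspect neuromodules (`neuromodule`, `nm_step`,
  `nm_iterate`, `structure_matrix`, `cycle_census`);
* assemble coupled pairs, check the synchronization condition, compute
  `w+` / `w-`, classify couplings (`coupled_pair`, `sync_matrix`,
  `obstruction_matrix`, `classify_coupling`, `sync_equivalent`);
* stability analysis: obstruction eigenvalues, the entrywise `1/n`
  global bound, QR-based Lyapunov spectra, and the split into
  synchronization and transversal exponents (`obstruction_eigen`,
  `theorem32_check`, `lyapunov_spectrum`, `split_spectrum`);
* attractor censuses from seeded random initial conditions with
  classification (fixed point / periodic / quasiperiodic / chaotic),
  synchronized-vs-asynchronous flags, basin hit counts, and
  bifurcation scans (`attractor_census`, `find_attractor`,
  `bifurcation_scan`);
* s-decomposition of even-dimensional networks into synchronizable
  submodules, at configuration and at sign-structure level
  (`s_decompose`, `is_basic`, `structure_s_feasible`);
* plain-text YAML specs for modules and pairs, CSV export, a bundled
  example catalog (`load_fixture`), a generator of random
  synchronizable pairs (`random_sync_pair`), and a CLI
  (`inst/cli/syncore.R`).

Long iterations and Lyapunov accumulation run in compiled code
(Rcpp/RcppArmadillo).

## Worked example

Two identical 2-neuron oscillators (`w12 = 1.6 = -w21`, an "odd
2-cycle", which by itself only ever shows a fixed point or a period-4
orbit) are coupled by a single inhibitory connection of weight −4
between their first neurons:

```r
library(syncore)
pair <- load_fixture("pair_generative")   # theta = (-4, 0) for both modules

sync_matrix(pair)
#> <synchronization core: 2 neurons>
#> w+:
#>      [,1] [,2]
#> [1,] -4.0  1.6
#> [2,] -1.6  0.0

classify_coupling(pair)$label
#> [1] "generative"

obstruction_eigen(obstruction_matrix(pair))$eigenvalues
#> [1] 3.2+0i 0.8+0i
```

The coupling is generative — the core gains a self-connection on
neuron 1 that the modules lack — and the obstruction eigenvalues 3.2
and 0.8 destabilize the manifold, so synchronized and asynchronous
attractors coexist.  A census over 500 seeded random initial
conditions finds exactly five:

```r
attractor_census(pair, n_inits = 500, seed = 1)
#> <attractor set: 5 attractors from 500 initial conditions (seed 1)>
#>       kind period synchronized  lyapunov1 basin_hits
#> 1  chaotic     NA        FALSE  0.3770872        208
#> 2 periodic      3         TRUE -0.3387079        110
#> 3  chaotic     NA        FALSE  0.3855866         76
#> 4 periodic      6        FALSE -0.3388438         62
#> 5  chaotic     NA         TRUE  0.3773514         44
```

a synchronized period-3 orbit and a synchronized chaotic attractor
(living on the manifold), an asynchronous period-6 orbit, and two
asynchronous chaotic attractors.  `lyapunov1` is the largest Lyapunov
exponent of each attractor; positive values mark chaos.  Along the
synchronized chaotic orbit the synchronization and transversal
exponents coincide (a symmetry of this configuration), so synchronized
chaos here is never stable against desynchronization:

```r
sp <- split_spectrum(pair, c(0.1, 0.2), n_transient = 10000, n_steps = 100000)
#> lambda1_sync = 0.380  lambda1_transversal = 0.380
```

To keep the same synchronized repertoire but make the manifold globally
attracting, choose the same core with a stable obstruction matrix:

```r
stable <- load_fixture("pair_conservative")
round(Re(obstruction_eigen(obstruction_matrix(stable))$eigenvalues), 3)
#> [1] -0.984 -0.366
classify_coupling(stable)$label
#> [1] "conservative"
```

Every attractor of this configuration is synchronized; its dynamics is
that of the shared core alone.

## Command line

```sh
Rscript inst/cli/syncore.R couple     --pair pair.yaml
Rscript inst/cli/syncore.R attractors --pair pair.yaml --theta1 -4 --inits 500 --seed 1
Rscript inst/cli/syncore.R decompose  --module net.yaml
Rscript inst/cli/syncore.R fixtures   dump pair_generative pair.yaml
```

See `vignettes/syncore-methods.Rmd` for the model, the numerical
choices, and the limitations of the census procedure.
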