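#' Catalog of built-in example systems
#'
#' Small reference systems used throughout the documentation and
#' tests.  Available names:
#'
#' * `"odd2cycle"`: the isolated 2-neuron odd cycle, `w12 = 1.6 =
#'   -w21`, zero bias.  Depending on the bias it has either a global
#'   fixed point or a global period-4 attractor.
#' * `"chaotic_core"`: the 2-neuron module with weights
#'   `[[-4, 1.6], [-1.6, 0]]` and bias `(-4, 0)` -- the
#'   synchronization core of `"pair_generative"`, placed in its
#'   chaotic bias range.
#' * `"pair_generative"`: two identical odd 2-cycles coupled through a
#'   single strong inhibitory connection (`w11_coup = -4`) between the
#'   first neurons.  The coupling is generative: the core acquires a
#'   self-connection absent from the modules.  Its obstruction matrix
#'   (`"obstruction_unstable"`, eigenvalues 3.2 and 0.8) destabilizes
#'   the synchronization manifold, so synchronized and asynchronous
#'   attractors coexist.
#' * `"pair_conservative"`: a coupled pair with the same
#'   synchronization core but obstruction matrix
#'   `"obstruction_stable"` (eigenvalues -0.984, -0.366): all its
#'   attractors are synchronized.
#' * `"obstruction_unstable"`, `"obstruction_stable"`: the two
#'   obstruction matrices above, returned as plain matrices.
#' * `"odd3cycle"`: a 3-neuron directed ring with one inhibitory
#'   connection.
#' * `"kii_structure_synthetic"`: a synthetic stand-in for the Freeman
#'   KII population motif (two excitatory, two inhibitory
#'   populations), encoded from its qualitative description only; the
#'   coupling joins the excitatory populations, giving a core with an
#'   additional positive self-connection.  Approximate by
#'   construction; not a reference connectivity.
#'
#' @param name one of the catalog names above.
#' @return A [neuromodule()], [coupled_pair()], or plain matrix,
#'   depending on the fixture.
#' @export
load_fixture <- function(name) {
  w2 <- rbind(c(0, 1.6), c(-1.6, 0))
  coup <- rbind(c(-4, 0), c(0, 0))
  switch(
    name,
    odd2cycle = neuromodule(c(0, 0), w2, name = "odd2cycle"),
    chaotic_core = neuromodule(c(-4, 0), rbind(c(-4, 1.6), c(-1.6, 0)),
                               name = "chaotic_core"),
    obstruction_unstable = rbind(c(4, 1.6), c(-1.6, 0)),
    obstruction_stable = rbind(c(-1.35, 0.6), c(-0.6, 0)),
    pair_generative = coupled_pair(c(-4, 0), c(-4, 0), w2, w2, coup, coup,
                                   name = "pair_generative"),
    pair_conservative = coupled_pair(
      c(-4, 0), c(-4, 0),
      rbind(c(-2.675, 1.1), c(-1.1, 0)), rbind(c(-2.675, 1.1), c(-1.1, 0)),
      rbind(c(-1.325, 0.5), c(-0.5, 0)), rbind(c(-1.325, 0.5), c(-0.5, 0)),
      name = "pair_conservative"),
    odd3cycle = neuromodule(c(0, 0, 0),
                            rbind(c(0, 0, -1), c(1, 0, 0), c(0, 1, 0)),
                            name = "odd3cycle"),
    kii_structure_synthetic = coupled_pair(
      c(0, 0), c(0, 0),
      rbind(c(0, -1), c(1, 0)), rbind(c(0, -1), c(1, 0)),
      rbind(c(0.5, 0), c(0, 0)), rbind(c(0.5, 0), c(0, 0)),
      name = "kii_structure_synthetic"),
    stop(sprintf(
      "unknown fixture '%s'; available: %s", name,
      paste(fixture_names(), collapse = ", ")))
  )
}

#' @rdname load_fixture
#' @export
fixture_names <- function() {
  c("odd2cycle", "chaotic_core", "obstruction_unstable",
    "obstruction_stable", "pair_generative", "pair_conservative",
    "odd3cycle", "kii_structure_synthetic")
}

#' Permute the neurons of a module
#'
#' Relabels neurons so that new neuron `k` is old neuron `perm[k]`
#' (weights and biases move together).  The dynamics is unchanged up
#' to coordinate relabeling.
#'
#' @inheritParams nm_step
#' @param perm a permutation of `1:module$n`.
#' @export
permute_module <- function(module, perm) {
  stopifnot_module(module)
  perm <- as.integer(perm)
  if (!identical(sort(perm), seq_len(module$n)))
    stop("perm must be a permutation of 1:n")
  neuromodule(module$theta[perm],
              module$weights[perm, perm, drop = FALSE],
              name = module$name)
}

# dyadic random magnitudes: k/64 with k in 8..64, exact in binary so
# that derived sums and differences carry zero floating-point residual
dyadic_mags <- function(k, scale = 1) {
  sample(8:64, k, replace = TRUE) / 64 * scale *
    sample(c(-1, 1), k, replace = TRUE)
}

#' Generate a random synchronizable coupled pair
#'
#' Draws a strongly connected module matrix `wA` (a directed ring plus
#' random extra edges), random coupling blocks, and completes `wB :=
#' wA + wAB - wBA` so the synchronization condition holds by
#' construction -- with zero floating-point residual, because all
#' weights are drawn on a dyadic grid (multiples of 1/64).
#'
#' The obstruction matrix `w- = wA - wBA` is rescaled by powers of two
#' until its operator norm (largest singular value) is below
#' `obstruction_cap` (default 0.9), so the generated pairs contract
#' transversal perturbations at every step: because `a' - b' =
#' w- (tanh(a) - tanh(b))` and tanh is 1-Lipschitz, an operator norm
#' below 1 makes the synchronization manifold globally attracting.
#' This is deliberate: dynamical tests of manifold invariance are only
#' numerically meaningful when transversal perturbations -- including
#' rounding noise -- contract, and a bound on the spectral radius
#' alone would not control transient growth of non-normal matrices.
#' Pass `obstruction_cap = NULL` to skip the rescaling.
#'
#' With `generative = TRUE` one coupling entry is forced at a position
#' where `wA` vanishes, with `wAB = wBA` there, so that `wB` also
#' vanishes at that position and the coupling is generative by
#' construction.
#'
#' @param n module dimension (>= 2).
#' @param density probability of each optional edge.
#' @param weight_scale multiplies all weights; keep it a power of two
#'   to preserve exact residuals.
#' @param seed integer seed; the draw is deterministic given it.
#' @param generative force a generative witness position.
#' @param obstruction_cap bound on the obstruction operator norm, or
#'   NULL to leave the obstruction uncontrolled.
#' @return A [coupled_pair()] satisfying the synchronization
#'   condition exactly.
#' @export
random_sync_pair <- function(n = 3L, density = 0.4, weight_scale = 1,
                             seed = 1L, generative = FALSE,
                             obstruction_cap = 0.9) {
  if (n < 2) stop("n must be >= 2")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  # module A: directed ring (strong connectivity guaranteed) + extras
  wA <- matrix(0, n, n)
  for (j in seq_len(n)) wA[j %% n + 1L, j] <- dyadic_mags(1, weight_scale)
  extra <- which(wA == 0 & stats::runif(n * n) < density)
  wA[extra] <- dyadic_mags(length(extra), weight_scale)
  # coupling A -> B
  wBA <- matrix(0, n, n)
  sel <- which(stats::runif(n * n) < density / 2)
  if (length(sel) == 0L) sel <- sample.int(n * n, 1L)
  wBA[sel] <- dyadic_mags(length(sel), weight_scale)
  gen_pos <- NULL
  if (generative) {
    zeros <- which(wA == 0)
    if (length(zeros) == 0L) {
      # make room off the ring so strong connectivity is preserved
      ring <- cbind(seq_len(n) %% n + 1L, seq_len(n))
      off_ring <- setdiff(seq_len(n * n),
                          (ring[, 2] - 1L) * n + ring[, 1])
      wA[sample(off_ring, 1L)] <- 0
      zeros <- which(wA == 0)
    }
    gen_pos <- if (length(zeros) == 1L) zeros else sample(zeros, 1L)
    wBA[gen_pos] <- dyadic_mags(1, weight_scale)
  }
  w_minus <- wA - wBA
  if (!is.null(obstruction_cap)) {
    for (k in 1:60) {
      if (norm(w_minus, type = "2") < obstruction_cap) break
      w_minus <- w_minus / 2
    }
    wBA <- wA - w_minus
  }
  # coupling B -> A; module B must come out strongly connected, which
  # an exact cancellation in wA + wAB - wBA can break -- redraw then
  for (try in 1:100) {
    wAB <- matrix(0, n, n)
    sel <- which(stats::runif(n * n) < density / 2)
    if (length(sel) == 0L) sel <- sample.int(n * n, 1L)
    wAB[sel] <- dyadic_mags(length(sel), weight_scale)
    if (generative) wAB[gen_pos] <- wBA[gen_pos]
    wB <- wA + wAB - wBA
    if (weights_strongly_connected(wB)) break
    if (try == 100L)
      stop("could not draw a coupling leaving module B strongly connected")
  }
  theta <- sample(-32:32, n, replace = TRUE) / 64
  coupled_pair(theta, theta, wA, wB, wAB, wBA,
               name = sprintf("random_sync_pair(seed=%d)", seed))
}
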