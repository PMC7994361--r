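#' Decompose an even-dimensional module into synchronizable submodules
#'
#' Searches all balanced bipartitions of the `2m` neurons into ordered
#' halves A and B, and all `m!` pairings of A-neurons with B-neurons,
#' for block splittings `[[wA, wAB], [wBA, wB]]` (under the permuted
#' index order) that satisfy the synchronization condition: equal
#' paired biases, `wA - wBA = wB - wAB`, both coupling blocks nonzero,
#' and (by default) both submodules strongly connected.  Every passing
#' splitting is an *s-decomposition*; a module admitting none is
#' *basic*.  Results are deduplicated under the A/B exchange symmetry
#' (the representative has neuron 1 in A).
#'
#' The search is exhaustive: the synchronization condition is a matrix
#' equation and depends on how A-neurons are matched with B-neurons,
#' so all pairings are enumerated rather than guessed.  The cost is
#' `C(2m, m)/2 * m!` candidates; inputs above `max_n` neurons are
#' refused (override deliberately if you accept the combinatorics).
#'
#' @inheritParams nm_step
#' @param tol entrywise tolerance for the synchronization condition.
#' @param require_connected require each submodule to be strongly
#'   connected (the module notion used throughout); set FALSE to
#'   allow feedforward submodules, which can still share a
#'   synchronization core.
#' @param ignore_theta skip the bias-equality test, treating theta as
#'   a free parameter of the family.
#' @param max_n refuse inputs with more neurons than this.
#' @return A list of `s_decomposition` objects, each with
#'   `partition_A`, `partition_B` (position k of A is paired with
#'   position k of B), `blocks` (thetaA, thetaB, wA, wB, wAB, wBA),
#'   `pair` (the corresponding [coupled_pair()]), `core` (its
#'   [sync_matrix()]), and `label` ("generative"/"conservative").
#'   Empty list if the module is basic.
#' @export
s_decompose <- function(module, tol = 1e-9, require_connected = TRUE,
                        ignore_theta = FALSE, max_n = 12L) {
  stopifnot_module(module)
  n <- module$n
  if (n %% 2L != 0L)
    stop("a neuromodule must be of even dimension to be s-decomposable")
  if (n > max_n)
    stop(sprintf(
      "refusing exhaustive search for %d neurons (C(%d,%d)/2 * %d! candidates); raise max_n to override",
      n, n, n %/% 2L, n %/% 2L))
  m <- n %/% 2L
  w <- module$weights
  theta <- module$theta
  out <- list()
  halves <- utils::combn(n, m)
  perms <- all_permutations(m)
  for (ci in seq_len(ncol(halves))) {
    A <- halves[, ci]
    if (A[1] != 1L) next      # exchange-symmetry representative: 1 in A
    B0 <- setdiff(seq_len(n), A)
    for (perm in perms) {
      B <- B0[perm]
      wA <- w[A, A, drop = FALSE]; wB <- w[B, B, drop = FALSE]
      wAB <- w[A, B, drop = FALSE]; wBA <- w[B, A, drop = FALSE]
      if (!any(wAB != 0) || !any(wBA != 0)) next
      if (max(abs((wA - wBA) - (wB - wAB))) > tol) next
      if (!ignore_theta && max(abs(theta[A] - theta[B])) > tol) next
      if (require_connected &&
          !(weights_strongly_connected(wA) && weights_strongly_connected(wB)))
        next
      pair <- coupled_pair(theta[A], theta[B], wA, wB, wAB, wBA)
      core <- sync_matrix(pair, tol = max(tol, 1e-9))
      cls <- classify_coupling(pair, tol = max(tol, 1e-9))
      out[[length(out) + 1L]] <- structure(
        list(partition_A = A, partition_B = B,
             blocks = list(thetaA = theta[A], thetaB = theta[B],
                           wA = wA, wB = wB, wAB = wAB, wBA = wBA),
             pair = pair, core = core, label = cls$label),
        class = "s_decomposition")
    }
  }
  out
}

#' @export
print.s_decomposition <- function(x, ...) {
  cat(sprintf("<s-decomposition: A = (%s) paired with B = (%s), %s>\n",
              paste(x$partition_A, collapse = ","),
              paste(x$partition_B, collapse = ","), x$label))
  invisible(x)
}

#' Is an even-dimensional module basic (not s-decomposable)?
#'
#' @inheritParams s_decompose
#' @export
is_basic <- function(module, tol = 1e-9, require_connected = TRUE,
                     ignore_theta = FALSE, max_n = 12L) {
  length(s_decompose(module, tol, require_connected, ignore_theta,
                     max_n)) == 0L
}

# Sign-feasibility of one paired entry position of the relation
# x_A - x_BA - x_B + x_AB = 0 with prescribed signs: can positive
# magnitudes be chosen consistently?  Each nonzero slot contributes a
# term of fixed sign sigma = (s_A, -s_BA, -s_B, s_AB) and free
# magnitude, so the sum can vanish iff no term is prescribed (all
# zero) or terms of both signs are present to balance each other.
signs_feasible <- function(sA, sBA, sB, sAB) {
  sigma <- c(sA, -sBA, -sB, sAB)
  sigma <- sigma[sigma != 0]
  length(sigma) == 0L || (any(sigma > 0) && any(sigma < 0))
}

#' Structure-level s-decomposability
#'
#' Given only a sign pattern, decides whether *some* weight
#' configuration with that structure is s-decomposable: a bipartition
#' and pairing is feasible when every paired entry position of the
#' synchronization condition is sign-feasible (magnitudes can be
#' chosen to satisfy `x_A - x_BA = x_B - x_AB` with the prescribed
#' signs), the coupling sign blocks are nonzero, and the submodule
#' sign blocks are strongly connected.
#'
#' @param structure a [signed_structure()] of even dimension.
#' @param require_connected as in [s_decompose()].
#' @param max_n as in [s_decompose()].
#' @return A list with `feasible` (logical) and `witnesses`, a list of
#'   `(partition_A, partition_B)` index pairs that are sign-feasible.
#' @export
structure_s_feasible <- function(structure, require_connected = TRUE,
                                 max_n = 12L) {
  if (!inherits(structure, "signed_structure"))
    stop("expected a 'signed_structure' object")
  n <- structure$n
  if (n %% 2L != 0L)
    stop("a neuromodule must be of even dimension to be s-decomposable")
  if (n > max_n)
    stop("refusing exhaustive search; raise max_n to override")
  s <- structure$entries
  m <- n %/% 2L
  witnesses <- list()
  halves <- utils::combn(n, m)
  perms <- all_permutations(m)
  for (ci in seq_len(ncol(halves))) {
    A <- halves[, ci]
    if (A[1] != 1L) next
    B0 <- setdiff(seq_len(n), A)
    for (perm in perms) {
      B <- B0[perm]
      sA <- s[A, A, drop = FALSE]; sB <- s[B, B, drop = FALSE]
      sAB <- s[A, B, drop = FALSE]; sBA <- s[B, A, drop = FALSE]
      if (!any(sAB != 0) || !any(sBA != 0)) next
      ok <- TRUE
      for (i in seq_len(m)) {
        for (j in seq_len(m)) {
          if (!signs_feasible(sA[i, j], sBA[i, j], sB[i, j], sAB[i, j])) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      if (!ok) next
      if (require_connected &&
          !(weights_strongly_connected(sA) && weights_strongly_connected(sB)))
        next
      witnesses[[length(witnesses) + 1L]] <-
        list(partition_A = A, partition_B = B)
    }
  }
  list(feasible = length(witnesses) > 0L, witnesses = witnesses)
}
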