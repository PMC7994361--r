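#' Construct a coupled pair of neuromodules
#'
#' Two neuromodules A and B of the same dimension `n`, joined by the
#' coupling blocks `wAB` (connections B -> A) and `wBA` (connections
#' A -> B).  The coupled system is the `2n`-neuron network with block
#' weight matrix `[[wA, wAB], [wBA, wB]]`; its state is the pair of
#' activation vectors `(a, b)`.  The coupling is *recurrent* when both
#' blocks contain at least one nonzero entry.
#'
#' Modules of unequal dimension are rejected: complete synchronization
#' as implemented here identifies neuron `i` of A with neuron `i` of B,
#' which requires equal dimensions (partial synchronization of
#' unequal-dimension modules is out of scope).
#'
#' @param thetaA,thetaB bias vectors of modules A and B (length `n`).
#' @param wA,wB module weight matrices (`n x n`).
#' @param wAB coupling block B -> A; `wAB[i, j]` is the weight from
#'   neuron `j` of B to neuron `i` of A.
#' @param wBA coupling block A -> B.
#' @param name optional label.
#' @return An object of class `coupled_pair`.
#' @export
coupled_pair <- function(thetaA, thetaB, wA, wB, wAB, wBA, name = NULL) {
  thetaA <- as.numeric(thetaA); thetaB <- as.numeric(thetaB)
  n <- length(thetaA)
  mats <- list(wA = as.matrix(wA), wB = as.matrix(wB),
               wAB = as.matrix(wAB), wBA = as.matrix(wBA))
  if (length(thetaB) != n)
    stop("modules of unequal dimension are not supported (partial synchronization is out of scope)")
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!all(dim(m) == c(n, n)))
      stop(sprintf("%s must be %dx%d", nm, n, n))
    if (!all(is.finite(m))) stop(sprintf("%s has non-finite entries", nm))
    dimnames(mats[[nm]]) <- NULL
  }
  structure(c(list(n = n, thetaA = thetaA, thetaB = thetaB), mats,
              list(name = name)),
            class = "coupled_pair")
}

#' @export
print.coupled_pair <- function(x, ...) {
  cat(sprintf("<coupled pair%s: 2 x %d neurons, %s coupling>\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              x$n, if (is_recurrent(x)) "recurrent" else "non-recurrent"))
  invisible(x)
}

stopifnot_pair <- function(pair) {
  if (!inherits(pair, "coupled_pair")) stop("expected a 'coupled_pair' object")
}

#' Is the coupling recurrent?
#'
#' TRUE when both coupling blocks have at least one nonzero entry.
#' @param pair a [coupled_pair()].
#' @export
is_recurrent <- function(pair) {
  stopifnot_pair(pair)
  any(pair$wAB != 0) && any(pair$wBA != 0)
}

#' Assemble the coupled pair into a single 2n-neuron module
#'
#' Iterating the assembled module reproduces the coupled dynamics
#' \deqn{a_i' = \theta^A_i + \sum_j w^A_{ij}\tanh(a_j) + \sum_j w^{AB}_{ij}\tanh(b_j),}
#' \deqn{b_i' = \theta^B_i + \sum_j w^B_{ij}\tanh(b_j) + \sum_j w^{BA}_{ij}\tanh(a_j).}
#'
#' @inheritParams is_recurrent
#' @return A [neuromodule()] of dimension `2 * pair$n`.
#' @export
assemble <- function(pair) {
  stopifnot_pair(pair)
  w <- rbind(cbind(pair$wA, pair$wAB), cbind(pair$wBA, pair$wB))
  neuromodule(c(pair$thetaA, pair$thetaB), w, name = pair$name)
}

#' Split a 2n-neuron module into its four blocks
#'
#' Inverse of [assemble()]: interprets neurons `1..n` as module A and
#' `n+1..2n` as module B.
#'
#' @param module a [neuromodule()] of even dimension.
#' @export
disassemble <- function(module) {
  stopifnot_module(module)
  if (module$n %% 2L != 0L) stop("module dimension must be even")
  n <- module$n %/% 2L
  iA <- seq_len(n); iB <- n + seq_len(n)
  coupled_pair(module$theta[iA], module$theta[iB],
               module$weights[iA, iA, drop = FALSE],
               module$weights[iB, iB, drop = FALSE],
               module$weights[iA, iB, drop = FALSE],
               module$weights[iB, iA, drop = FALSE],
               name = module$name)
}

#' Residual of the synchronization condition
#'
#' The synchronization condition requires `thetaA = thetaB` and
#' `wA - wBA = wB - wAB` (entrywise), with both coupling blocks
#' nonzero.  The residual reported is the maximum absolute violation
#' of the two equalities.
#'
#' @inheritParams is_recurrent
#' @return A list with `theta_residual`, `weight_residual`,
#'   `recurrent`.
#' @export
sync_residual <- function(pair) {
  stopifnot_pair(pair)
  list(theta_residual = max(abs(pair$thetaA - pair$thetaB)),
       weight_residual = max(abs((pair$wA - pair$wBA) - (pair$wB - pair$wAB))),
       recurrent = is_recurrent(pair))
}

#' Check the synchronization condition
#'
#' TRUE iff `max|thetaA - thetaB| <= tol`, `max|(wA - wBA) - (wB -
#' wAB)| <= tol`, and the coupling is recurrent.  When it holds, the
#' diagonal `a = b` (the synchronization manifold) is invariant under
#' the coupled dynamics.
#'
#' @inheritParams is_recurrent
#' @param tol absolute entrywise tolerance; the default 1e-9 treats
#'   weights as specified constants.
#' @export
check_sync_condition <- function(pair, tol = 1e-9) {
  r <- sync_residual(pair)
  r$recurrent && r$theta_residual <= tol && r$weight_residual <= tol
}

require_sync <- function(pair, tol = 1e-9) {
  r <- sync_residual(pair)
  if (!r$recurrent)
    stop("synchronization condition violated: coupling is not recurrent (a coupling block is identically zero)")
  if (r$theta_residual > tol || r$weight_residual > tol) {
    d <- (pair$wA - pair$wBA) - (pair$wB - pair$wAB)
    if (r$weight_residual >= r$theta_residual) {
      ij <- which(abs(d) == max(abs(d)), arr.ind = TRUE)[1, ]
      stop(sprintf(
        "synchronization condition violated: |(wA-wBA)-(wB-wAB)| = %g at entry (%d,%d) exceeds tol = %g",
        r$weight_residual, ij[1], ij[2], tol))
    }
    i <- which.max(abs(pair$thetaA - pair$thetaB))
    stop(sprintf(
      "synchronization condition violated: |thetaA-thetaB| = %g at neuron %d exceeds tol = %g",
      r$theta_residual, i, tol))
  }
  invisible(TRUE)
}

#' Synchronization matrix and core of a coupled pair
#'
#' For a pair satisfying the synchronization condition, the
#' synchronized dynamics on the manifold `a = b` is that of the
#' n-neuron module with weight matrix `w+ = wA + wAB` (equal to
#' `wB + wBA` within tolerance) and bias `thetaA`.  `sync_matrix()`
#' returns this "synchronization core" object; [synchronized_module()]
#' returns it as a runnable [neuromodule()]; [sync_core_structure()]
#' returns only its sign pattern, which labels the whole family of
#' synchronization-equivalent coupled systems.
#'
#' @inheritParams check_sync_condition
#' @param structure_tol tolerance used when taking the sign pattern of
#'   `w+` (a derived matrix).
#' @return `sync_matrix()`: a `sync_core` list with `w_plus`, `theta`,
#'   `structure`.
#' @export
sync_matrix <- function(pair, tol = 1e-9, structure_tol = 1e-12) {
  require_sync(pair, tol)
  w_plus <- pair$wA + pair$wAB
  s <- sign(w_plus); s[abs(w_plus) <= structure_tol] <- 0
  structure(list(w_plus = w_plus, theta = pair$thetaA,
                 structure = signed_structure(s)),
            class = "sync_core")
}

#' @export
print.sync_core <- function(x, ...) {
  cat(sprintf("<synchronization core: %d neurons>\nw+:\n", length(x$theta)))
  print(x$w_plus)
  invisible(x)
}

#' Obstruction matrix of a coupled pair
#'
#' `w- = wA - wBA` (equal to `wB - wAB` within tolerance) governs the
#' transversal dynamics `eta' = w- tanh(eta)` of deviations from the
#' synchronization manifold; its eigenvalues control whether
#' synchronization is stable.
#'
#' @inheritParams check_sync_condition
#' @export
obstruction_matrix <- function(pair, tol = 1e-9) {
  require_sync(pair, tol)
  pair$wA - pair$wBA
}

#' @rdname sync_matrix
#' @export
synchronized_module <- function(pair, tol = 1e-9) {
  core <- sync_matrix(pair, tol)
  neuromodule(core$theta, core$w_plus,
              name = if (is.null(pair$name)) "synchronized" else
                paste0(pair$name, " (synchronized)"))
}

#' @rdname sync_matrix
#' @export
sync_core_structure <- function(pair, tol = 1e-9, structure_tol = 1e-12) {
  sync_matrix(pair, tol, structure_tol)$structure
}

#' Recover identical modules and symmetric coupling from w+ and w-
#'
#' For identical modules (`wA = wB = w`) with symmetric coupling
#' (`wAB = wBA = w_coup`), the synchronization and obstruction
#' matrices are `w+ = w + w_coup` and `w- = w - w_coup`, so
#' `w = (w+ + w-)/2` and `w_coup = (w+ - w-)/2`.  This is the standard
#' way to realize a prescribed pair (w+, w-) as a concrete coupled
#' system.
#'
#' @param w_plus,w_minus square matrices of equal dimension.
#' @param theta optional bias vector for both modules (default zeros).
#' @return A [coupled_pair()]; a warning is issued if the recovered
#'   coupling is identically zero (non-recurrent, degenerate).
#' @export
identical_module_split <- function(w_plus, w_minus, theta = NULL) {
  w_plus <- as.matrix(w_plus); w_minus <- as.matrix(w_minus)
  if (!all(dim(w_plus) == dim(w_minus)))
    stop("w_plus and w_minus must have equal dimensions")
  w <- (w_plus + w_minus) / 2
  w_coup <- (w_plus - w_minus) / 2
  if (all(w_coup == 0))
    warning("recovered coupling is identically zero: the pair is non-recurrent")
  if (is.null(theta)) theta <- numeric(nrow(w_plus))
  coupled_pair(theta, theta, w, w, w_coup, w_coup)
}

#' Convert between (a, b) and (xi, eta) coordinates
#'
#' `xi = (a + b)/2` is the coordinate along the synchronization
#' manifold (`eta = 0` there); `eta = (a - b)/2` is the transversal
#' coordinate (`xi = 0` on the obstruction manifold).  The inverse is
#' `a = xi + eta`, `b = xi - eta`.
#'
#' @param a,b activation vectors of the two modules (equal length).
#' @return `to_xi_eta()`: a `xi_eta` list with `xi` and `eta`;
#'   `from_xi_eta()`: a list with `a` and `b`.
#' @export
to_xi_eta <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("a and b must have equal length")
  structure(list(xi = (a + b) / 2, eta = (a - b) / 2), class = "xi_eta")
}

#' @rdname to_xi_eta
#' @param s a `xi_eta` state.
#' @export
from_xi_eta <- function(s) {
  list(a = s$xi + s$eta, b = s$xi - s$eta)
}

#' One step of the coupled dynamics in (xi, eta) coordinates
#'
#' Evaluates the coupled map directly in manifold-adapted coordinates,
#' using `G+(x, y) = tanh(x + y)` and `G-(x, y) = tanh(x - y)`:
#' \deqn{\xi' = \tfrac12(\theta^A+\theta^B) + \tfrac12(w^A+w^{BA})G^+ + \tfrac12(w^B+w^{AB})G^-,}
#' \deqn{\eta' = \tfrac12(\theta^A-\theta^B) + \tfrac12(w^A-w^{BA})G^+ - \tfrac12(w^B-w^{AB})G^-.}
#' Does not require the synchronization condition; when it holds and
#' `eta = 0`, the `eta` component stays exactly zero.
#'
#' @inheritParams is_recurrent
#' @param s a `xi_eta` state as returned by [to_xi_eta()].
#' @export
xi_eta_step <- function(pair, s) {
  stopifnot_pair(pair)
  if (length(s$xi) != pair$n) stop("state dimension does not match pair")
  gp <- tanh(s$xi + s$eta)
  gm <- tanh(s$xi - s$eta)
  xi2 <- (pair$thetaA + pair$thetaB) / 2 +
    as.numeric((pair$wA + pair$wBA) %*% gp + (pair$wB + pair$wAB) %*% gm) / 2
  eta2 <- (pair$thetaA - pair$thetaB) / 2 +
    as.numeric((pair$wA - pair$wBA) %*% gp - (pair$wB - pair$wAB) %*% gm) / 2
  structure(list(xi = xi2, eta = eta2), class = "xi_eta")
}

#' Transversal (obstruction) dynamics map
#'
#' One step `eta' = w- tanh(eta)` of the dynamics transversal to the
#' synchronization manifold.  It has no bias term, so the origin is
#' always a fixed point: synchronization persists once reached.
#'
#' @inheritParams check_sync_condition
#' @param eta transversal coordinate vector.
#' @export
obstruction_map <- function(pair, eta, tol = 1e-9) {
  w_minus <- obstruction_matrix(pair, tol)
  as.numeric(w_minus %*% tanh(eta))
}

#' Classify a coupling as generative or conservative
#'
#' A coupling is *generative* when the synchronization matrix `w+` has
#' at least one nonzero entry at a position where both `wA` and `wB`
#' are zero: the synchronized dynamics then runs on a connection that
#' neither isolated module possesses, and can be qualitatively richer
#' than the module dynamics.  Otherwise the coupling is
#' *conservative*.
#'
#' @inheritParams check_sync_condition
#' @return A list with `label` ("generative" or "conservative") and
#'   `witnesses`, the matrix of (i, j) index pairs where `w+` is
#'   nonzero but both module matrices vanish (zero rows if
#'   conservative).
#' @export
classify_coupling <- function(pair, tol = 1e-9) {
  core <- sync_matrix(pair, tol)
  new_idx <- which(core$structure$entries != 0L & pair$wA == 0 & pair$wB == 0,
                   arr.ind = TRUE)
  colnames(new_idx) <- c("i", "j")
  list(label = if (nrow(new_idx) > 0) "generative" else "conservative",
       witnesses = new_idx)
}

#' Are two coupled systems synchronization equivalent?
#'
#' TRUE iff the two systems have the same synchronization core, i.e.
#' identical sign patterns of their synchronization matrices.  By
#' default the comparison is entrywise with neuron labels fixed; with
#' `up_to_permutation = TRUE` the cores are compared up to a
#' simultaneous row/column permutation (graph isomorphism of the
#' signed cores).
#'
#' @param pairX,pairY [coupled_pair()] objects satisfying the
#'   synchronization condition.
#' @param up_to_permutation compare cores up to neuron relabeling.
#' @inheritParams check_sync_condition
#' @export
sync_equivalent <- function(pairX, pairY, up_to_permutation = FALSE,
                            tol = 1e-9) {
  sx <- sync_core_structure(pairX, tol)$entries
  sy <- sync_core_structure(pairY, tol)$entries
  if (nrow(sx) != nrow(sy)) return(FALSE)
  if (identical(sx, sy)) return(TRUE)
  if (!up_to_permutation) return(FALSE)
  n <- nrow(sx)
  for (p in all_permutations(n)) {
    if (identical(sx[p, p, drop = FALSE], sy)) return(TRUE)
  }
  FALSE
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos)
    }
  }
  out
}
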