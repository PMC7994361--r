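#' Eigenvalue report for an obstruction matrix
#'
#' The synchronization manifold of a coupled pair is asymptotically
#' stable when all eigenvalues of the obstruction matrix `w-` have
#' modulus below 1 (the linearization of the transversal dynamics at
#' the synchronized state is `w- diag(tanh'(.))` with `0 < tanh' <=
#' 1`).  Eigenvalues are sorted by decreasing modulus, ties broken by
#' decreasing real then imaginary part; real eigenvalues carry a zero
#' imaginary part.
#'
#' @param w_minus square numeric matrix.
#' @return A list with `eigenvalues` (complex), `max_modulus`, and
#'   `stable` (`max_modulus < 1`).
#' @export
obstruction_eigen <- function(w_minus) {
  w_minus <- as.matrix(w_minus)
  if (nrow(w_minus) != ncol(w_minus)) stop("w_minus must be square")
  ev <- as.complex(eigen(w_minus, only.values = TRUE)$values)
  ev <- ev[order(-Mod(ev), -Re(ev), -Im(ev))]
  list(eigenvalues = ev, max_modulus = max(Mod(ev)),
       stable = max(Mod(ev)) < 1)
}

#' Entrywise sufficient condition for global transversal stability
#'
#' TRUE iff `max_ij |w-_ij| < 1/n`.  Under this bound the origin of
#' the transversal dynamics `eta' = w- tanh(eta)` is a *global* fixed
#' point attractor, so synchronization is reached from every initial
#' condition.  The bound is taken on absolute values: a contraction
#' estimate concerns magnitudes, and the signed reading would declare
#' arbitrarily negative matrices stable, contradicting the eigenvalue
#' criterion.  The condition is sufficient but far from necessary
#' (spectrally stable matrices often violate it).
#'
#' @inheritParams obstruction_eigen
#' @export
theorem32_check <- function(w_minus) {
  w_minus <- as.matrix(w_minus)
  max(abs(w_minus)) < 1 / nrow(w_minus)
}

#' Lyapunov spectrum of a module along one orbit
#'
#' Estimates all Lyapunov exponents by iterating the tangent map
#' `J(a) = w diag(1 - tanh(a)^2)` along the orbit from `a0`, with QR
#' re-orthonormalization at every step; exponents are the averaged
#' logs of the R-diagonals over `n_steps` after an `n_transient`
#' warm-up.  Deterministic given `(a0, n_transient, n_steps)`.
#'
#' @inheritParams nm_step
#' @param a0 initial activation vector.
#' @param n_transient steps discarded before accumulation.
#' @param n_steps accumulation steps (a few 1e4 gives ~1e-2 accuracy
#'   on low-dimensional systems).
#' @return A `lyapunov_spectrum` list: `exponents` (sorted
#'   descending), `n_steps`, `n_transient`, `a0`.
#' @export
lyapunov_spectrum <- function(module, a0, n_transient = 10000L,
                              n_steps = 100000L) {
  stopifnot_module(module)
  a0 <- as.numeric(a0)
  if (length(a0) != module$n) stop("dimension mismatch between a0 and module")
  if (n_steps < 1) stop("n_steps must be >= 1")
  ex <- lyap_cpp(module$theta, module$weights, a0,
                 as.integer(n_transient), as.integer(n_steps))
  structure(list(exponents = as.numeric(ex), n_steps = as.integer(n_steps),
                 n_transient = as.integer(n_transient), a0 = a0),
            class = "lyapunov_spectrum")
}

#' @export
print.lyapunov_spectrum <- function(x, ...) {
  cat("<Lyapunov spectrum>\n")
  cat("exponents:", paste(format(x$exponents, digits = 4), collapse = "  "),
      "\n")
  invisible(x)
}

#' Synchronization and transversal Lyapunov spectra
#'
#' Along the synchronized orbit `xi(t)` of the `w+` module started at
#' `xi0`, the tangent dynamics of the coupled system block-splits into
#' a synchronization part `w+ diag(tanh'(xi))` (perturbations within
#' the manifold) and a transversal part `w- diag(tanh'(xi))`
#' (perturbations off the manifold).  Both spectra are estimated with
#' per-step QR re-orthonormalization over the same orbit.  The
#' synchronized orbit is asymptotically stable against
#' desynchronization iff the largest transversal exponent is negative;
#' stability of the manifold as a whole requires this for every orbit
#' in it, which in practice is sampled over the attractors found by a
#' census.
#'
#' @inheritParams check_sync_condition
#' @param xi0 initial state on the synchronization manifold (length
#'   `pair$n`).
#' @inheritParams lyapunov_spectrum
#' @return A list with `sync` and `transversal`, each a
#'   `lyapunov_spectrum`.
#' @export
split_spectrum <- function(pair, xi0, n_transient = 10000L,
                           n_steps = 100000L, tol = 1e-9) {
  core <- sync_matrix(pair, tol)
  w_minus <- obstruction_matrix(pair, tol)
  xi0 <- as.numeric(xi0)
  if (length(xi0) != pair$n) stop("xi0 must have length pair$n")
  r <- lyap_split_cpp(core$theta, core$w_plus, w_minus, xi0,
                      as.integer(n_transient), as.integer(n_steps))
  mk <- function(ex) structure(
    list(exponents = as.numeric(ex), n_steps = as.integer(n_steps),
         n_transient = as.integer(n_transient), a0 = xi0),
    class = "lyapunov_spectrum")
  list(sync = mk(r$sync), transversal = mk(r$transversal))
}
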