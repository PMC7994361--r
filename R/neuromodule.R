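#' Construct a neuromodule
#'
#' A neuromodule is a discrete-time recurrent neural network with
#' hyperbolic-tangent transfer function.  Its state is the activation
#' vector `a`, updated as
#' \deqn{a_i(t+1) = \theta_i + \sum_j w_{ij} \tanh(a_j(t)),}
#' where `theta` collects the effective bias of each neuron (fixed bias
#' plus stationary external input, stored as a single number) and
#' `weights[i, j]` is the synaptic weight from neuron `j` to neuron `i`.
#' All neuron indices in this package are 1-based.
#'
#' @param theta numeric vector of effective biases, one per neuron.
#' @param weights square numeric matrix, `weights[i, j]` the synapse
#'   from neuron `j` to neuron `i`.
#' @param name optional label carried through reports.
#' @return An object of class `neuromodule` with fields `n`, `theta`,
#'   `weights`, `name`.
#' @examples
#' m <- neuromodule(c(0, 0), rbind(c(0, 1.6), c(-1.6, 0)))
#' nm_step(m, c(0, 0))
#' @export
neuromodule <- function(theta, weights, name = NULL) {
  weights <- as.matrix(weights)
  theta <- as.numeric(theta)
  n <- length(theta)
  if (nrow(weights) != ncol(weights))
    stop("weights must be a square matrix")
  if (nrow(weights) != n)
    stop(sprintf("dimension mismatch: length(theta) = %d but weights is %dx%d",
                 n, nrow(weights), ncol(weights)))
  if (n < 1) stop("a neuromodule needs at least one neuron")
  if (!all(is.finite(weights)) || !all(is.finite(theta)))
    stop("theta and weights must be finite")
  dimnames(weights) <- NULL
  structure(list(n = n, theta = theta, weights = weights, name = name),
            class = "neuromodule")
}

#' @export
print.neuromodule <- function(x, ...) {
  cat(sprintf("<neuromodule%s: %d neurons>\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"), x$n))
  cat("theta:  ", paste(format(x$theta), collapse = "  "), "\n")
  cat("weights:\n")
  print(x$weights)
  invisible(x)
}

stopifnot_module <- function(module) {
  if (!inherits(module, "neuromodule"))
    stop("expected a 'neuromodule' object")
}

#' Apply one step of the module dynamics
#'
#' @param module a [neuromodule()].
#' @param a activation vector of length `module$n`.
#' @return The next activation vector.
#' @export
nm_step <- function(module, a) {
  stopifnot_module(module)
  a <- as.numeric(a)
  if (length(a) != module$n)
    stop(sprintf("dimension mismatch: state has length %d, module has %d neurons",
                 length(a), module$n))
  as.numeric(module$theta + module$weights %*% tanh(a))
}

#' Iterate the module dynamics and record a trajectory
#'
#' Applies the map `n_transient` times without recording, then records
#' `n_record` consecutive states (the first recorded state is the state
#' reached after the transient).  Activations are bounded by
#' `|theta_i| + sum_j |w_ij|` because `|tanh| < 1`, so the orbit cannot
#' overflow for finite parameters.
#'
#' @inheritParams nm_step
#' @param a0 initial activation vector.
#' @param n_transient number of steps to discard (>= 0).
#' @param n_record number of states to record (>= 1).
#' @return A `trajectory` object: matrix `states` (one row per time
#'   step) plus `start_time`.
#' @export
nm_iterate <- function(module, a0, n_transient = 0L, n_record = 1L) {
  stopifnot_module(module)
  a0 <- as.numeric(a0)
  if (length(a0) != module$n)
    stop("dimension mismatch between a0 and module")
  if (n_transient < 0) stop("n_transient must be >= 0")
  if (n_record < 1) stop("n_record must be >= 1")
  states <- iterate_cpp(module$theta, module$weights, a0,
                        as.integer(n_transient), as.integer(n_record))
  structure(list(states = states, start_time = as.integer(n_transient)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d states of dimension %d, from t = %d>\n",
              nrow(x$states), ncol(x$states), x$start_time))
  invisible(x)
}

#' Signed structure matrix helpers
#'
#' `structure_matrix()` returns the sign pattern of the weight matrix
#' (entries in -1/0/+1, self-connections included): the polarity
#' description of the network.  `adjacency_matrix()` returns the 0/1
#' connectivity with self-connections ignored (zero diagonal).
#'
#' @inheritParams nm_step
#' @param tol entries with absolute value `<= tol` count as absent.
#'   Defaults to exact zero, appropriate for user-specified weights;
#'   set a small positive value for matrices derived by arithmetic.
#' @return A `signed_structure` object wrapping the integer matrix.
#' @export
structure_matrix <- function(module, tol = 0) {
  stopifnot_module(module)
  s <- sign(module$weights)
  s[abs(module$weights) <= tol] <- 0
  signed_structure(s)
}

#' @rdname structure_matrix
#' @export
adjacency_matrix <- function(module, tol = 0) {
  s <- abs(unclass(structure_matrix(module, tol))$entries)
  diag(s) <- 0
  signed_structure(s)
}

#' Construct a signed structure from a -1/0/+1 matrix
#'
#' @param entries square matrix with entries in -1, 0, +1.
#' @export
signed_structure <- function(entries) {
  entries <- as.matrix(entries)
  if (nrow(entries) != ncol(entries)) stop("structure must be square")
  if (!all(entries %in% c(-1, 0, 1)))
    stop("structure entries must be -1, 0 or +1")
  storage.mode(entries) <- "integer"
  dimnames(entries) <- NULL
  structure(list(n = nrow(entries), entries = entries),
            class = "signed_structure")
}

#' @export
print.signed_structure <- function(x, ...) {
  cat(sprintf("<signed structure: %d nodes>\n", x$n))
  print(x$entries)
  invisible(x)
}

#' Export a signed structure as an edge list
#'
#' One row per nonzero entry, for external graph viewers: `from`, `to`
#' (1-based neuron indices; `weights[i, j]` becomes the edge `j -> i`)
#' and `sign`.
#'
#' @param structure a [signed_structure()].
#' @return data.frame with columns `from`, `to`, `sign`.
#' @export
structure_edges <- function(structure) {
  if (!inherits(structure, "signed_structure"))
    stop("expected a 'signed_structure' object")
  idx <- which(structure$entries != 0L, arr.ind = TRUE)
  df <- data.frame(from = as.integer(idx[, "col"]),
                   to = as.integer(idx[, "row"]),
                   sign = structure$entries[idx])
  df[order(df$from, df$to), , drop = FALSE]
}

#' Is the module's connection graph strongly connected?
#'
#' Tests strong connectivity of the directed graph of nonzero
#' off-diagonal weights (self-connections do not affect reachability).
#' A single neuron counts as strongly connected.
#'
#' @inheritParams nm_step
#' @export
is_strongly_connected <- function(module) {
  stopifnot_module(module)
  weights_strongly_connected(module$weights)
}

weights_strongly_connected <- function(w) {
  n <- nrow(w)
  if (n == 1L) return(TRUE)
  adj <- (w != 0)
  diag(adj) <- FALSE
  # edge j -> i for w[i, j] != 0
  g <- igraph::graph_from_adjacency_matrix(t(adj), mode = "directed")
  igraph::is_connected(g, mode = "strong")
}

#' Enumerate elementary cycles with inhibition parity
#'
#' Enumerates all elementary directed cycles of length `<= max_length`
#' in the nonzero-weight digraph (self-connections are length-1
#' cycles).  Each cycle is annotated with the number of inhibitory
#' (negative-weight) connections it traverses and its parity: a cycle
#' is even (odd) if that count is even (odd).  Odd cycles are the
#' source of oscillatory dynamics in these networks.  Cycles are
#' reported rotated to start at their smallest neuron index and sorted
#' by (length, node sequence).
#'
#' @inheritParams nm_step
#' @param max_length maximum cycle length to report; defaults to
#'   `module$n`.
#' @return data.frame with columns `length`, `nodes` (list column of
#'   integer vectors), `n_inhibitory`, `parity`.
#' @export
cycle_census <- function(module, max_length = module$n) {
  stopifnot_module(module)
  if (max_length < 1) stop("max_length must be >= 1")
  w <- module$weights
  n <- module$n
  # successors of j are the i with w[i, j] != 0 (edge j -> i)
  succ <- lapply(seq_len(n), function(j) which(w[, j] != 0))
  cycles <- list()
  # classic elementary-cycle DFS: root s, explore only nodes >= s,
  # so every cycle is found exactly once, anchored at its minimum node
  for (s in seq_len(n)) {
    stack <- list(list(path = s, blocked = rep(FALSE, n)))
    dfs <- function(path) {
      v <- path[length(path)]
      for (u in succ[[v]]) {
        if (u == s && length(path) <= max_length) {
          cycles[[length(cycles) + 1L]] <<- path
        } else if (u > s && !(u %in% path) && length(path) < max_length) {
          dfs(c(path, u))
        }
      }
    }
    dfs(s)
  }
  if (length(cycles) == 0L) {
    return(data.frame(length = integer(0), nodes = I(list()),
                      n_inhibitory = integer(0), parity = character(0)))
  }
  ord <- order(lengths(cycles),
               vapply(cycles, function(p) paste(sprintf("%06d", p), collapse = ""), ""))
  cycles <- cycles[ord]
  n_inh <- vapply(cycles, function(p) {
    to <- c(p[-1], p[1])                       # edges p[k] -> p[k+1]
    sum(w[cbind(to, p)] < 0)
  }, integer(1))
  data.frame(length = lengths(cycles), nodes = I(cycles),
             n_inhibitory = n_inh,
             parity = ifelse(n_inh %% 2L == 0L, "even", "odd"))
}
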