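#' Settings for attractor search and classification
#'
#' Bundle of lengths and tolerances used by [find_attractor()],
#' [attractor_census()] and [bifurcation_scan()].
#'
#' @param n_transient steps discarded before an orbit is considered to
#'   be on its attractor.
#' @param n_record states recorded after the transient.
#' @param max_period largest minimal period tested for by recurrence;
#'   any period below this wins over a near-zero Lyapunov label.
#' @param point_tol recurrence tolerance for period detection.
#' @param chaos_tol threshold on the largest Lyapunov exponent
#'   separating chaotic (above) from quasiperiodic (within) orbits.
#' @param sync_tol tolerance on `max_i |a_i - b_i|` below which a
#'   sampled attractor of a coupled system counts as synchronized.
#' @param dedup_tol average nearest-neighbour distance (in output
#'   space) below which two sampled attractors are considered the
#'   same.  Distinct coexisting attractors of the systems studied
#'   here are separated by upwards of 0.3 on this metric, while
#'   independent finite samples of the same attractor fall below
#'   0.05; the default 0.1 sits between with a factor >= 2 margin on
#'   either side.  The average (rather than maximum) nearest-neighbour
#'   distance is used because the maximum is dominated by the largest
#'   coverage gap of a finite chaotic sample and never gets small at
#'   practical sample sizes.
#' @param dedup_points sample clouds are thinned to at most this many
#'   points before comparison.
#' @param lyap_steps,lyap_transient accumulation/warm-up lengths for
#'   the per-attractor largest-exponent estimate.
#' @return A named list of class `attractor_settings`.
#' @export
attractor_settings <- function(n_transient = 10000L, n_record = 2000L,
                               max_period = 64L, point_tol = 1e-6,
                               chaos_tol = 5e-3, sync_tol = 1e-6,
                               dedup_tol = 0.1, dedup_points = 1000L,
                               lyap_steps = 4000L, lyap_transient = 0L) {
  s <- list(n_transient = as.integer(n_transient),
            n_record = as.integer(n_record),
            max_period = as.integer(max_period),
            point_tol = point_tol, chaos_tol = chaos_tol,
            sync_tol = sync_tol, dedup_tol = dedup_tol,
            dedup_points = as.integer(dedup_points),
            lyap_steps = as.integer(lyap_steps),
            lyap_transient = as.integer(lyap_transient))
  stopifnot(all(vapply(s[c("point_tol", "chaos_tol", "sync_tol",
                           "dedup_tol")], function(x) x > 0, logical(1))))
  class(s) <- "attractor_settings"
  s
}

thin_rows <- function(m, k) {
  if (nrow(m) <= k) return(m)
  m[unique(round(seq(1, nrow(m), length.out = k))), , drop = FALSE]
}

#' Find and classify the attractor reached from one initial state
#'
#' Iterates past the transient, then classifies the recorded orbit:
#' first by minimal-period recurrence (testing periods in increasing
#' order enforces minimality), otherwise by the largest Lyapunov
#' exponent -- chaotic if above `chaos_tol`, quasiperiodic if within
#' `chaos_tol` of zero.  A clearly negative exponent without a
#' detected period indicates an unresolved orbit (e.g. a very long
#' transient); it is labeled quasiperiodic with `low_confidence =
#' TRUE`.
#'
#' @inheritParams nm_step
#' @param a0 initial activation vector.
#' @param settings an [attractor_settings()] bundle.
#' @return An `attractor` object: `kind` (fixed_point, periodic,
#'   quasiperiodic, chaotic), `period` (minimal period, `NA` unless a
#'   period was detected; 1 for fixed points), `sample_points`
#'   (matrix of activation states on the attractor), `lyapunov1`,
#'   `synchronized` (set by [attractor_census()] for coupled systems),
#'   `basin_hits`, `low_confidence`.
#' @export
find_attractor <- function(module, a0, settings = attractor_settings()) {
  stopifnot_module(module)
  states <- nm_iterate(module, a0, settings$n_transient,
                       settings$n_record)$states
  T_ <- nrow(states)
  window <- min(200L, T_ - settings$max_period)
  period <- NA_integer_
  for (p in seq_len(min(settings$max_period, T_ - window))) {
    idx <- (T_ - window + 1L):T_
    if (max(abs(states[idx, , drop = FALSE] -
                states[idx - p, , drop = FALSE])) < settings$point_tol) {
      period <- p
      break
    }
  }
  lam1 <- lyap_cpp(module$theta, module$weights, states[T_, ],
                   settings$lyap_transient, settings$lyap_steps)[1]
  low_confidence <- FALSE
  if (!is.na(period)) {
    kind <- if (period == 1L) "fixed_point" else "periodic"
    samples <- states[(T_ - period + 1L):T_, , drop = FALSE]
  } else {
    samples <- states
    if (lam1 > settings$chaos_tol) {
      kind <- "chaotic"
    } else {
      kind <- "quasiperiodic"
      low_confidence <- lam1 < -settings$chaos_tol
    }
  }
  structure(list(kind = kind, period = period, sample_points = samples,
                 lyapunov1 = as.numeric(lam1), synchronized = NA,
                 basin_hits = 1L, low_confidence = low_confidence),
            class = "attractor")
}

#' @export
print.attractor <- function(x, ...) {
  cat(sprintf("<attractor: %s%s, lambda1 = %.4g%s%s>\n", x$kind,
              if (!is.na(x$period) && x$period > 1L)
                paste0(" (period ", x$period, ")") else "",
              x$lyapunov1,
              if (!is.na(x$synchronized))
                paste0(", ", if (x$synchronized) "synchronized" else
                  "asynchronous") else "",
              if (x$low_confidence) ", low confidence" else ""))
  invisible(x)
}

#' Output-space sample cloud of an attractor
#' @param attractor an `attractor`.
#' @param k thin to at most `k` points.
#' @keywords internal
attractor_cloud <- function(attractor, k = 300L) {
  tanh(thin_rows(attractor$sample_points, k))
}

#' Distance between two attractors' output clouds
#'
#' Set distance between the (thinned) output-space sample clouds.
#' `"mean_nn"` (the deduplication metric of [attractor_census()]) is
#' the average distance from each sample point to its nearest
#' neighbour in the other cloud, averaged over both directions;
#' `"hausdorff"` is the classical symmetric Hausdorff maximum, which
#' upper-bounds it but is dominated by the largest sampling gap.
#'
#' @param x,y `attractor` objects from the same system.
#' @param metric `"mean_nn"` or `"hausdorff"`.
#' @param dedup_points thinning bound per cloud.
#' @export
attractor_distance <- function(x, y, metric = c("mean_nn", "hausdorff"),
                               dedup_points = 1000L) {
  metric <- match.arg(metric)
  cx <- attractor_cloud(x, dedup_points)
  cy <- attractor_cloud(y, dedup_points)
  if (metric == "mean_nn") meannn_cpp(cx, cy) else hausdorff_cpp(cx, cy)
}

#' Does a sampled attractor lie on the synchronization manifold?
#'
#' For an attractor sampled from an assembled coupled system (even
#' dimension `2n`, neurons `1..n` module A, `n+1..2n` module B): TRUE
#' iff every sample point satisfies `max_i |a_i - b_i| < sync_tol`.
#'
#' @param attractor an `attractor` sampled from a coupled system.
#' @param sync_tol tolerance on the activation mismatch.
#' @export
is_synchronized_attractor <- function(attractor, sync_tol = 1e-6) {
  s <- attractor$sample_points
  if (ncol(s) %% 2L != 0L)
    stop("attractor does not come from a coupled system (odd dimension)")
  n <- ncol(s) %/% 2L
  max(abs(s[, seq_len(n), drop = FALSE] -
          s[, n + seq_len(n), drop = FALSE])) < sync_tol
}

#' Swap the two module blocks of a sampled attractor
#'
#' Exchanges the (a, b) blocks of every sample point.  For coupled
#' identical modules the dynamics commutes with this swap, so the set
#' of attractors is closed under it: the swap image of every census
#' member must again be (within deduplication distance of) a census
#' member.  Synchronized attractors are their own images.
#'
#' @param attractor an `attractor` from a coupled system.
#' @export
swap_image <- function(attractor) {
  s <- attractor$sample_points
  if (ncol(s) %% 2L != 0L) stop("swap_image needs an even-dimensional system")
  n <- ncol(s) %/% 2L
  out <- attractor
  out$sample_points <- s[, c(n + seq_len(n), seq_len(n)), drop = FALSE]
  out
}

#' Census of coexisting attractors from random initial conditions
#'
#' Draws `n_inits` initial conditions by sampling outputs uniformly in
#' `(-1, 1)^dim` and mapping them through `artanh` into activation
#' space, classifies the attractor reached from each with
#' [find_attractor()], and deduplicates by the symmetric Hausdorff
#' distance between output-space sample clouds.  Deterministic given
#' `seed`.  The attractor count is a lower bound at the reported
#' `n_inits` and settings: small basins can be missed, and
#' chaotic-attractor counts can be sensitive to transient lengths
#' near crises.
#'
#' For coupled systems a fraction `manifold_frac` of the initial
#' conditions is placed exactly on the synchronization manifold
#' (`a0 = b0`).  Attractors of the synchronized dynamics whose
#' transversal Lyapunov exponent is positive are genuine attractors of
#' the manifold-restricted dynamics but repel generic orbits, so
#' purely generic sampling can never reach them; stratifying over the
#' invariant subspace is the standard way to census an equivariant
#' system.  Attractors found this way are still flagged
#' `synchronized` by their sampled states, and asynchronous
#' attractors still collect their basin hits from the generic
#' initial conditions.
#'
#' @param x a [neuromodule()], or a [coupled_pair()] (assembled
#'   automatically, and attractors then carry a `synchronized` flag).
#' @param n_inits number of random initial conditions.
#' @param seed integer seed for the initial conditions.
#' @param settings an [attractor_settings()] bundle.
#' @param manifold_frac fraction of initial conditions drawn on the
#'   diagonal `a0 = b0` (coupled systems only; ignored otherwise).
#' @return An `attractor_set`: list of deduplicated attractors with
#'   basin hit counts, plus `n_inits`, `seed`, `settings`.
#' @export
attractor_census <- function(x, n_inits = 500L, seed = 1L,
                             settings = attractor_settings(),
                             manifold_frac = 0.2) {
  coupled <- inherits(x, "coupled_pair")
  module <- if (coupled) assemble(x) else x
  stopifnot_module(module)
  if (n_inits < 1) stop("n_inits must be >= 1")
  dim <- module$n
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  outs <- matrix(stats::runif(n_inits * dim, -1, 1), nrow = n_inits)
  outs <- pmin(pmax(outs, -(1 - 1e-9)), 1 - 1e-9)
  inits <- atanh(outs)
  if (coupled && manifold_frac > 0) {
    n_man <- min(n_inits, ceiling(manifold_frac * n_inits))
    half <- dim %/% 2L
    for (k in seq_len(n_man))
      inits[k, half + seq_len(half)] <- inits[k, seq_len(half)]
  }
  found <- list()
  clouds <- list()
  for (k in seq_len(n_inits)) {
    att <- find_attractor(module, inits[k, ], settings)
    if (coupled)
      att$synchronized <- is_synchronized_attractor(att, settings$sync_tol)
    cloud <- attractor_cloud(att, settings$dedup_points)
    hit <- 0L
    for (j in seq_along(found)) {
      if (meannn_cpp(cloud, clouds[[j]]) < settings$dedup_tol) {
        hit <- j
        break
      }
    }
    if (hit > 0L) {
      found[[hit]]$basin_hits <- found[[hit]]$basin_hits + 1L
    } else {
      found[[length(found) + 1L]] <- att
      clouds[[length(clouds) + 1L]] <- cloud
    }
  }
  # merge any clouds that ended up overlapping (e.g. chaotic samples
  # that explored the attractor unevenly early in the census)
  repeat {
    merged <- FALSE
    for (i in seq_along(found)) {
      for (j in seq_along(found)) {
        if (j <= i) next
        if (meannn_cpp(clouds[[i]], clouds[[j]]) < settings$dedup_tol) {
          found[[i]]$basin_hits <- found[[i]]$basin_hits + found[[j]]$basin_hits
          found[[j]] <- NULL
          clouds[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  ord <- order(vapply(found, function(a) -a$basin_hits, numeric(1)),
               vapply(found, function(a) a$kind, character(1)))
  structure(list(attractors = found[ord], n_inits = as.integer(n_inits),
                 seed = as.integer(seed), settings = settings,
                 coupled = coupled,
                 parameters = list(theta = module$theta,
                                   weights = module$weights)),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  cat(sprintf("<attractor set: %d attractors from %d initial conditions (seed %d)>\n",
              length(x$attractors), x$n_inits, x$seed))
  print(summary(x))
  invisible(x)
}

#' @export
summary.attractor_set <- function(object, ...) {
  atts <- object$attractors
  data.frame(
    kind = vapply(atts, function(a) a$kind, character(1)),
    period = vapply(atts, function(a) as.integer(a$period), integer(1)),
    synchronized = vapply(atts, function(a) as.logical(a$synchronized),
                          logical(1)),
    lyapunov1 = vapply(atts, function(a) a$lyapunov1, numeric(1)),
    basin_hits = vapply(atts, function(a) a$basin_hits, integer(1)))
}

#' Bifurcation scan over one bias term
#'
#' Sweeps `theta[neuron]` over `values` and records, at each grid
#' point, the asymptotic mean output `obar = mean_i tanh(a_i)` over
#' `n_record` post-transient steps.  Two kinds of branches are
#' recorded: a "sweep" branch that continues the state from the
#' previous grid point (following one attractor through the
#' parameter change), and `n_inits` fresh random-restart branches per
#' grid point that expose coexisting attractors.
#'
#' @inheritParams nm_step
#' @param neuron 1-based index of the bias entry to vary.
#' @param values strictly monotone grid of bias values.
#' @param n_transient,n_record per-grid-point transient and recording
#'   lengths (shorter than census defaults; a scan needs density, not
#'   certainty).
#' @param n_inits fresh random initial conditions per grid point (0
#'   disables restarts).
#' @param seed seed for the restart draws.
#' @param sweep keep a continuation branch across the grid.
#' @return A `bifurcation_data` data.frame with columns `theta`,
#'   `obar`, `branch`; attributes record the scan configuration.
#' @export
bifurcation_scan <- function(module, neuron = 1L, values,
                             n_transient = 2000L, n_record = 100L,
                             n_inits = 3L, seed = 1L, sweep = TRUE) {
  stopifnot_module(module)
  values <- as.numeric(values)
  if (length(values) < 1) stop("empty grid")
  dv <- diff(values)
  if (length(dv) > 0 && !(all(dv > 0) || all(dv < 0)))
    stop("values must be strictly monotone")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  dim <- module$n
  rows <- vector("list", length(values) * (n_inits + as.integer(sweep)))
  r <- 0L
  sweep_state <- NULL
  for (v in values) {
    m <- module
    m$theta[neuron] <- v
    if (sweep) {
      if (is.null(sweep_state))
        sweep_state <- atanh(pmin(pmax(stats::runif(dim, -1, 1),
                                       -(1 - 1e-9)), 1 - 1e-9))
      st <- nm_iterate(m, sweep_state, n_transient, n_record)$states
      sweep_state <- st[nrow(st), ]
      r <- r + 1L
      rows[[r]] <- data.frame(theta = v, obar = rowMeans(tanh(st)),
                              branch = "sweep")
    }
    for (k in seq_len(n_inits)) {
      a0 <- atanh(pmin(pmax(stats::runif(dim, -1, 1), -(1 - 1e-9)),
                       1 - 1e-9))
      st <- nm_iterate(m, a0, n_transient, n_record)$states
      r <- r + 1L
      rows[[r]] <- data.frame(theta = v, obar = rowMeans(tanh(st)),
                              branch = paste0("init", k))
    }
  }
  out <- do.call(rbind, rows[seq_len(r)])
  attr(out, "neuron") <- as.integer(neuron)
  attr(out, "config") <- list(n_transient = as.integer(n_transient),
                              n_record = as.integer(n_record),
                              n_inits = as.integer(n_inits),
                              seed = as.integer(seed), sweep = sweep)
  class(out) <- c("bifurcation_data", "data.frame")
  out
}

#' @export
plot.bifurcation_data <- function(x, ...) {
  graphics::plot(x$theta, x$obar, pch = ".", cex = 2,
                 xlab = sprintf("theta[%d]", attr(x, "neuron")),
                 ylab = "mean output", ...)
  invisible(x)
}
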