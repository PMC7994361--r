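#' Read and write network spec files
#'
#' Plain-text YAML description of a module: fields `name` (optional),
#' `n`, `theta` (list of `n` numbers), and `weights`, either a dense
#' row-major list of `n` rows, or an edge list of `[i, j, value]`
#' triples meaning a connection from neuron `j` to neuron `i`
#' (1-based, i.e. `weights[i, j] = value`).  An edge list is
#' recognized by its row shape; when `n = 3` the dense reading wins,
#' so write the edge list under an explicit `edges:` sub-key to force
#' it (`weights: {edges: [[i, j, value], ...]}`).  Numbers are
#' written with enough significant digits (up to 17) that writing and
#' re-reading reproduces every weight bit-exactly.
#'
#' @param path file path.
#' @return `read_network_spec()`: a [neuromodule()].
#' @export
read_network_spec <- function(path) {
  spec <- normalize_spec_names(yaml::read_yaml(path))
  for (f in c("n", "theta", "weights"))
    if (is.null(spec[[f]]))
      stop(sprintf("network spec '%s': missing field '%s'", path, f))
  n <- as.integer(spec$n)
  theta <- as.numeric(unlist(spec$theta))
  if (length(theta) != n)
    stop(sprintf("network spec '%s': theta has length %d, expected n = %d",
                 path, length(theta), n))
  w <- parse_weights(spec$weights, n, path)
  neuromodule(theta, w, name = spec$name)
}

# YAML 1.1 parses a bare `n` key as the boolean FALSE; map it back so
# hand-written specs with an unquoted key still load
normalize_spec_names <- function(spec) {
  names(spec)[names(spec) %in% c("FALSE", "no")] <- "n"
  spec
}

parse_weights <- function(ww, n, path) {
  if (is.list(ww) && !is.null(ww$edges)) {
    rows <- lapply(ww$edges, function(r) as.numeric(unlist(r)))
    return(parse_edges(rows, n, path))
  }
  rows <- lapply(ww, function(r) as.numeric(unlist(r)))
  if (all(lengths(rows) == n) && length(rows) == n) {
    return(do.call(rbind, rows))
  }
  if (all(lengths(rows) == 3)) {           # edge list [i, j, value]
    return(parse_edges(rows, n, path))
  }
  stop(sprintf(
    "weights in '%s' must be %d dense rows of length %d, an 'edges:' mapping, or an edge list of [i, j, value] triples",
    path, n, n))
}

parse_edges <- function(rows, n, path) {
  if (!all(lengths(rows) == 3))
    stop(sprintf("edge list in '%s': every entry must be [i, j, value]",
                 path))
  w <- matrix(0, n, n)
  for (e in rows) {
    i <- as.integer(e[1]); j <- as.integer(e[2])
    if (i < 1 || i > n || j < 1 || j > n)
      stop(sprintf("weights edge list in '%s': index (%d,%d) out of 1..%d",
                   path, i, j, n))
    w[i, j] <- e[3]
  }
  w
}

num17 <- function(x) {
  # shortest decimal representation that still round-trips a double,
  # forced into a shape YAML 1.1 recognizes as a float (exponent forms
  # need a decimal point, else the scalar is read back as a string)
  vapply(x, function(v) {
    s <- formatC(v, digits = 17, format = "g")
    for (d in 1:16) {
      cand <- formatC(v, digits = d, format = "g")
      if (as.numeric(cand) == v) { s <- cand; break }
    }
    if (grepl("e", s, fixed = TRUE) && !grepl(".", s, fixed = TRUE))
      s <- sub("e", ".0e", s, fixed = TRUE)
    s
  }, character(1))
}

yaml_num_row <- function(x) paste0("[", paste(num17(x), collapse = ", "), "]")

#' @rdname read_network_spec
#' @inheritParams nm_step
#' @export
write_network_spec <- function(module, path) {
  stopifnot_module(module)
  lines <- c(
    if (!is.null(module$name)) sprintf("name: %s", module$name),
    sprintf("'n': %d", module$n),
    sprintf("theta: %s", yaml_num_row(module$theta)),
    "weights:",
    sprintf("  - %s", apply(module$weights, 1, yaml_num_row)))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write coupled-pair spec files
#'
#' YAML description of a coupled pair: `name` (optional), `n`,
#' `thetaA`, `thetaB`, and the four blocks `wA`, `wB`, `wAB`, `wBA`
#' in the same dense/edge-list dialect as network specs.  The reader
#' validates dimensions and reports the synchronization-condition
#' residuals as a message when they are nonzero.
#'
#' @param path file path.
#' @return `read_pair_spec()`: a [coupled_pair()].
#' @export
read_pair_spec <- function(path) {
  spec <- normalize_spec_names(yaml::read_yaml(path))
  for (f in c("n", "thetaA", "thetaB", "wA", "wB", "wAB", "wBA"))
    if (is.null(spec[[f]]))
      stop(sprintf("pair spec '%s': missing field '%s'", path, f))
  n <- as.integer(spec$n)
  pair <- coupled_pair(as.numeric(unlist(spec$thetaA)),
                       as.numeric(unlist(spec$thetaB)),
                       parse_weights(spec$wA, n, path),
                       parse_weights(spec$wB, n, path),
                       parse_weights(spec$wAB, n, path),
                       parse_weights(spec$wBA, n, path),
                       name = spec$name)
  r <- sync_residual(pair)
  if (r$theta_residual > 0 || r$weight_residual > 0)
    message(sprintf(
      "pair spec '%s': synchronization-condition residuals: theta %g, weights %g",
      path, r$theta_residual, r$weight_residual))
  pair
}

#' @rdname read_pair_spec
#' @inheritParams is_recurrent
#' @export
write_pair_spec <- function(pair, path) {
  stopifnot_pair(pair)
  block <- function(label, m)
    c(sprintf("%s:", label), sprintf("  - %s", apply(m, 1, yaml_num_row)))
  lines <- c(
    if (!is.null(pair$name)) sprintf("name: %s", pair$name),
    sprintf("'n': %d", pair$n),
    sprintf("thetaA: %s", yaml_num_row(pair$thetaA)),
    sprintf("thetaB: %s", yaml_num_row(pair$thetaB)),
    block("wA", pair$wA), block("wB", pair$wB),
    block("wAB", pair$wAB), block("wBA", pair$wBA))
  writeLines(lines, path)
  invisible(path)
}

#' End-to-end synchronization report for a coupled pair
#'
#' Runs the full analysis chain on one coupled pair across a set of
#' bias values for its first neuron (applied to both modules):
#' synchronization-condition residuals, synchronization and
#' obstruction matrices, core sign pattern, generative/conservative
#' verdict, obstruction eigenvalues with the entrywise and spectral
#' stability verdicts, an attractor census per bias value, and the
#' largest synchronization and transversal Lyapunov exponents along
#' each synchronized attractor.
#'
#' @inheritParams is_recurrent
#' @param thetas bias values applied to neuron 1 of both modules.
#' @param n_inits,seed,settings census configuration, see
#'   [attractor_census()].
#' @param split_steps accumulation length for the per-attractor
#'   exponent split.
#' @return A `sync_report` list; its print method gives a plain-text
#'   summary, and `report$census[[k]]` holds the per-theta censuses.
#' @export
run_report <- function(pair, thetas = NULL, n_inits = 200L, seed = 1L,
                       settings = attractor_settings(),
                       split_steps = 20000L) {
  stopifnot_pair(pair)
  core <- sync_matrix(pair)
  w_minus <- obstruction_matrix(pair)
  eig <- obstruction_eigen(w_minus)
  cls <- classify_coupling(pair)
  if (is.null(thetas)) thetas <- pair$thetaA[1]
  censuses <- list()
  splits <- list()
  for (k in seq_along(thetas)) {
    p <- pair
    p$thetaA[1] <- p$thetaB[1] <- thetas[k]
    censuses[[k]] <- attractor_census(p, n_inits = n_inits, seed = seed,
                                      settings = settings)
    atts <- censuses[[k]]$attractors
    sync_idx <- which(vapply(atts, function(a) isTRUE(a$synchronized),
                             logical(1)))
    splits[[k]] <- lapply(sync_idx, function(i) {
      xi0 <- atts[[i]]$sample_points[1, seq_len(pair$n)]
      sp <- split_spectrum(p, xi0, n_transient = 1000L,
                           n_steps = as.integer(split_steps))
      list(attractor = i, lambda1_sync = sp$sync$exponents[1],
           lambda1_transversal = sp$transversal$exponents[1])
    })
  }
  structure(list(pair = pair, residual = sync_residual(pair),
                 w_plus = core$w_plus, w_minus = w_minus,
                 core_structure = core$structure,
                 coupling_class = cls, obstruction_eigen = eig,
                 entrywise_global = theorem32_check(w_minus),
                 thetas = thetas, census = censuses, splits = splits),
            class = "sync_report")
}

#' @export
print.sync_report <- function(x, ...) {
  cat("== coupled-pair synchronization report ==\n")
  cat(sprintf("residuals: theta %g, weights %g\n",
              x$residual$theta_residual, x$residual$weight_residual))
  cat("w+ (synchronization matrix):\n"); print(x$w_plus)
  cat("w- (obstruction matrix):\n"); print(x$w_minus)
  cat("core sign pattern:\n"); print(x$core_structure$entries)
  cat(sprintf("coupling: %s\n", x$coupling_class$label))
  cat(sprintf("obstruction eigenvalues: %s (max modulus %.4g)\n",
              paste(format(x$obstruction_eigen$eigenvalues, digits = 4),
                    collapse = ", "),
              x$obstruction_eigen$max_modulus))
  cat(sprintf("entrywise global-stability bound: %s; spectral stability: %s\n",
              x$entrywise_global, x$obstruction_eigen$stable))
  for (k in seq_along(x$thetas)) {
    cat(sprintf("\n-- census at theta1 = %g --\n", x$thetas[k]))
    print(summary(x$census[[k]]))
    for (s in x$splits[[k]])
      cat(sprintf("attractor %d: lambda1_sync = %.4f, lambda1_transversal = %.4f\n",
                  s$attractor, s$lambda1_sync, s$lambda1_transversal))
  }
  invisible(x)
}

#' Write census and bifurcation results as CSV
#'
#' Floats are serialized with up to 17 significant digits so re-runs
#' with identical configuration produce byte-identical files.
#'
#' @param x an `attractor_set` or `bifurcation_data` object.
#' @param path output CSV path.
#' @export
write_results_csv <- function(x, path) {
  if (inherits(x, "attractor_set")) {
    df <- summary(x)
    df$lyapunov1 <- num17(df$lyapunov1)
  } else if (inherits(x, "bifurcation_data")) {
    df <- data.frame(theta = num17(x$theta), obar = num17(x$obar),
                     branch = x$branch)
  } else stop("unsupported object for CSV export")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
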