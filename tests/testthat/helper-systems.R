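# Reference systems used across test files.

odd2 <- function(theta = c(0, 0), w = 1.6)
  neuromodule(theta, rbind(c(0, w), c(-w, 0)))

# the showcase pair: two identical odd 2-cycles, one strong inhibitory
# coupling connection between the first neurons
showcase_pair <- function(theta1 = -4) {
  w2 <- rbind(c(0, 1.6), c(-1.6, 0))
  coup <- rbind(c(-4, 0), c(0, 0))
  coupled_pair(c(theta1, 0), c(theta1, 0), w2, w2, coup, coup)
}

# the conservative counterpart with the same core but a spectrally
# stable obstruction matrix
stable_pair <- function(theta1 = -4) {
  w <- rbind(c(-2.675, 1.1), c(-1.1, 0))
  coup <- rbind(c(-1.325, 0.5), c(-0.5, 0))
  coupled_pair(c(theta1, 0), c(theta1, 0), w, w, coup, coup)
}

# brute-force elementary-cycle enumeration: try every subset and every
# rotationally-canonical ordering; independent of the package's DFS
brute_cycles <- function(w, max_length = nrow(w)) {
  n <- nrow(w)
  found <- list()
  for (len in seq_len(min(max_length, n))) {
    subsets <- utils::combn(n, len, simplify = FALSE)
    for (sub in subsets) {
      perms <- if (len == 1L) list(sub) else {
        # orderings starting at the smallest element
        rest <- sub[-1]
        lapply(perms_of(rest), function(p) c(sub[1], p))
      }
      for (p in perms) {
        edges <- cbind(c(p[-1], p[1]), p)   # p[k] -> p[k+1] is w[to, from]
        if (all(w[edges] != 0)) {
          n_inh <- sum(w[edges] < 0)
          found[[length(found) + 1L]] <-
            list(nodes = p, length = len, n_inhibitory = n_inh)
        }
      }
    }
  }
  found
}

perms_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in perms_of(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], p)
  out
}

# plain-R average nearest-neighbour distance, independent of the
# compiled kernel
mean_nn_r <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  (mean(apply(d, 1, min)) + mean(apply(d, 2, min))) / 2
}

# quick settings for cheap census calls in unit tests
fast_settings <- function(...)
  attractor_settings(n_transient = 2000L, n_record = 500L,
                     lyap_steps = 1500L, ...)
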