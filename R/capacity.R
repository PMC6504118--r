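# Information-processing capacity: state harvesting, Legendre target
# functions, linear-readout capacity scores, memory curves, total
# capacity and the optimal input-resolution scan.

#' Normalized Legendre polynomial
#'
#' Evaluates the Legendre polynomial of degree `d` on `[-1, 1]` via the
#' three-term recurrence, scaled by `sqrt(2d + 1)` so the family is
#' orthonormal under the uniform measure on `[-1, 1]`.
#'
#' @param d integer degree `>= 0`.
#' @param s evaluation points in `[-1, 1]` (vectorized).
#' @param normalized multiply by `sqrt(2d+1)`?
#' @return numeric vector.
#' @export
legendre_poly <- function(d, s, normalized = TRUE) {
  if (!is.numeric(d) || length(d) != 1 || d < 0 || d != round(d))
    stop("d must be a nonnegative integer")
  p0 <- rep(1, length(s))
  if (d == 0) return(if (normalized) p0 else p0)
  p1 <- s
  if (d >= 2) {
    for (k in 2:d) {
      p2 <- ((2 * k - 1) * s * p1 - (k - 1) * p0) / k
      p0 <- p1; p1 <- p2
    }
  }
  if (normalized) sqrt(2 * d + 1) * p1 else p1
}

#' Harvest a state matrix from a driven circuit
#'
#' Runs the circuit for `(T + washout)` input steps with a
#' piecewise-constant uniform signal injected into a subset of E neurons,
#' samples every E neuron's membrane potential at the last grid point of
#' each input step, and discards the washout columns.
#'
#' @param circuit a `microcircuit`.
#' @param T_steps number of retained input steps.
#' @param delta_t input step (ms), multiple of the resolution.
#' @param rho_u injected-current scale (pA).
#' @param nu_in background rate (spikes/s).
#' @param washout leading input steps discarded.
#' @param seed integer seed (initial states `V ~ U[E_leak, V_thresh]`,
#'   background, signal, target choice).
#' @param target_fraction fraction of E neurons driven.
#' @return list with `X` (N_E x T matrix), `u` (length T), `delta_t`,
#'   `washout`, `targets`.
#' @export
harvest_states <- function(circuit, T_steps, delta_t, rho_u, nu_in = 5,
                           washout = 100, seed = 1,
                           target_fraction = 0.25) {
  stopifnot(T_steps >= 1)
  total <- T_steps + washout
  sig <- make_input_signal(total, delta_t, rho_u, seed = seed + 7L,
                           resolution = circuit$resolution)
  prog <- stimulus_program(nu_in = nu_in, u = sig$u, delta_t = delta_t,
                           rho_u = rho_u,
                           target_fraction = target_fraction)
  ne <- circuit$sizes[["E"]]
  res <- simulate_circuit(circuit, prog, duration = total * delta_t,
                          seed = seed, init = "random",
                          record = "V", record_every = delta_t,
                          record_v_idx = seq_len(ne))
  X <- res$V
  stopifnot(ncol(X) == total)
  keep <- (washout + 1):total
  list(X = X[, keep, drop = FALSE], u = sig$u[keep], delta_t = delta_t,
       washout = washout, targets = res$targets, nu_in = nu_in,
       rho_u = rho_u)
}

#' Precompute the readout basis of a state matrix
#'
#' Mean-centers the state rows and computes a thin QR decomposition of the
#' transposed state matrix, so that many capacity scores against the same
#' states cost one matrix-vector product each.
#'
#' @param X state matrix (rows = state variables, columns = time).
#' @return a `state_basis` object.
#' @export
state_basis <- function(X) {
  Xc <- t(X - rowMeans(X))           # T x N, centered columns
  keep <- apply(Xc, 2, function(col) any(col != 0))
  qr_ <- qr(Xc[, keep, drop = FALSE])
  structure(list(qr = qr_, T = nrow(Xc), n_state = nrow(X),
                 rank = qr_$rank), class = "state_basis")
}

#' Capacity to reconstruct a target from circuit states
#'
#' Ordinary least-squares linear readout of `z` from the mean-centered
#' state variables; the score is the captured fraction of the target's
#' variance, \eqn{1 - \|z - \hat z\|^2 / \|z\|^2} (computed on the
#' centered target), clipped to `[0, 1]`. A score of 1 means a linear
#' combination of the states equals the target.
#'
#' @param X state matrix (`n_state` x `T`) or a [state_basis()].
#' @param z target sequence (length `T`).
#' @return capacity in `[0, 1]`.
#' @export
capacity_score <- function(X, z) {
  sb <- if (inherits(X, "state_basis")) X else state_basis(X)
  if (length(z) != sb$T) stop("target length must match state columns")
  zc <- z - mean(z)
  ss <- sum(zc^2)
  if (ss == 0) stop("target is constant; capacity undefined")
  fit <- qr.fitted(sb$qr, zc)
  min(max(sum(fit^2) / ss, 0), 1)
}

#' Target function from products of Legendre polynomials
#'
#' Builds \eqn{z[n] = \prod_k P_{d_k}(2 u[n-k] - 1)} for a basis
#' specification mapping delays to degrees. The input is remapped from
#' `[0,1]` to `[-1,1]` so the family is orthonormal under the i.i.d.
#' uniform input measure; entries with insufficient history are dropped.
#'
#' @param u input sequence in `[0, 1]`.
#' @param basis named list or vector: names are delays (`"0"`, `"3"`,
#'   ...), values are degrees `>= 1`.
#' @return list with `z` (length `length(u) - max_delay`) and `offset`
#'   (the number of dropped leading entries = max delay).
#' @export
build_target <- function(u, basis) {
  delays <- as.integer(names(basis))
  degrees <- as.integer(unlist(basis))
  if (!length(delays) || any(is.na(delays)))
    stop("basis must be a named delay -> degree map")
  stopifnot(all(degrees >= 1), all(delays >= 0))
  kmax <- max(delays)
  if (kmax >= length(u)) stop("max delay exceeds input length")
  s <- 2 * u - 1
  n <- length(u)
  idx <- (kmax + 1):n
  z <- rep(1, length(idx))
  for (j in seq_along(delays))
    z <- z * legendre_poly(degrees[j], s[idx - delays[j]])
  list(z = z, offset = kmax)
}

#' Linear memory curve and memory capacity
#'
#' Capacity to reconstruct the input delayed by `k` steps (degree-1
#' Legendre target) for `k = 0..k_max`; scores below the finite-sample
#' significance threshold (`2 * n_state / T` by default) are zeroed. The
#' memory capacity `C_M` is the sum of the retained scores.
#'
#' @param X state matrix (`n_state` x `T`).
#' @param u input sequence (length `T`).
#' @param k_max maximum delay tested.
#' @param threshold significance floor; `NULL` for the default, 0 to
#'   disable.
#' @return list with `k`, `curve`, `C_M`, `threshold`.
#' @export
memory_capacity <- function(X, u, k_max = 100, threshold = NULL) {
  stopifnot(ncol(X) == length(u), k_max < length(u))
  # one common alignment window so a single QR serves all delays
  win <- (k_max + 1):length(u)
  sb <- state_basis(X[, win, drop = FALSE])
  if (is.null(threshold)) threshold <- 2 * nrow(X) / length(win)
  s <- 2 * u - 1
  curve <- vapply(0:k_max, function(k)
    capacity_score(sb, sqrt(3) * s[win - k]), numeric(1))
  curve[curve < threshold] <- 0
  list(k = 0:k_max, curve = curve, C_M = sum(curve), threshold = threshold)
}

# enumerate basis specs (delay -> degree maps) with total degree `deg`,
# delays within [0, k_max], at most `max_vars` factors
enumerate_bases <- function(deg, k_max, max_vars = 3) {
  out <- list()
  # partitions of deg into at most max_vars parts, each >= 1
  parts <- list()
  gen_part <- function(rem, maxp, cur) {
    if (rem == 0) { parts[[length(parts) + 1]] <<- cur; return(invisible()) }
    for (p in seq_len(min(rem, maxp)))
      gen_part(rem - p, p, c(cur, p))
  }
  gen_part(deg, deg, integer(0))
  delays <- 0:k_max
  for (part in parts) {
    if (length(part) > max_vars) next
    combs <- utils::combn(delays, length(part), simplify = FALSE)
    for (dl in combs) {
      if (length(unique(part)) == 1) {
        out[[length(out) + 1]] <- stats::setNames(as.list(part), dl)
      } else {
        # distinct degree assignments over the chosen delays
        perms <- unique(combinat_perms(part))
        for (pp in perms)
          out[[length(out) + 1]] <- stats::setNames(as.list(pp), dl)
      }
    }
  }
  out
}

combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    rest <- combinat_perms(x[-i])
    for (r in rest) out[[length(out) + 1]] <- c(x[i], r)
  }
  unique(out)
}

#' Total information-processing capacity
#'
#' Sums thresholded capacity scores over products of normalized Legendre
#' polynomials of the delayed input, enumerated by total degree 1..`d_max`
#' with delays in `[0, k_max]` and at most `max_vars` simultaneous
#' factors. Per degree, delay combinations are scanned in lexicographic
#' order with an early stop once a full sweep at the current maximum delay
#' adds less than `eps`; an enumeration budget caps the number of bases
#' per degree. The capacity space explored is therefore (deliberately)
#' incomplete for high degrees, and `C_T` is a lower bound.
#'
#' @param X state matrix.
#' @param u input sequence.
#' @param d_max largest total degree.
#' @param k_max largest delay for the linear terms.
#' @param k_max_nl largest delay for nonlinear (degree >= 2) terms.
#' @param max_vars maximum simultaneous polynomial factors.
#' @param max_bases_per_degree enumeration budget.
#' @param threshold significance floor (default `2 n_state / T`).
#' @return a `capacity_result` list: `by_degree` totals, `C_T`, the
#'   degree-1 memory curve, counts of bases evaluated, metadata.
#' @export
total_capacity <- function(X, u, d_max = 4, k_max = 100, k_max_nl = 20,
                           max_vars = 3, max_bases_per_degree = 3000,
                           threshold = NULL) {
  stopifnot(ncol(X) == length(u), d_max >= 1)
  kall <- max(k_max, k_max_nl)
  win <- (kall + 1):length(u)
  sb <- state_basis(X[, win, drop = FALSE])
  if (is.null(threshold)) threshold <- 2 * nrow(X) / length(win)
  s <- 2 * u - 1
  score_basis <- function(basis) {
    delays <- as.integer(names(basis))
    degrees <- as.integer(unlist(basis))
    z <- rep(1, length(win))
    for (j in seq_along(delays))
      z <- z * legendre_poly(degrees[j], s[win - delays[j]])
    if (sd(z) == 0) return(0)
    capacity_score(sb, z)
  }
  by_degree <- stats::setNames(numeric(d_max), paste0("d", 1:d_max))
  n_bases <- stats::setNames(integer(d_max), paste0("d", 1:d_max))
  truncated <- FALSE
  mem <- memory_capacity(X, u, k_max = min(k_max, length(u) - 1),
                         threshold = threshold)
  by_degree[1] <- mem$C_M
  n_bases[1] <- length(mem$curve)
  if (d_max >= 2) {
    for (deg in 2:d_max) {
      bases <- enumerate_bases(deg, k_max_nl, max_vars)
      if (length(bases) > max_bases_per_degree) {
        bases <- bases[seq_len(max_bases_per_degree)]
        truncated <- TRUE
      }
      tot <- 0
      for (bs in bases) {
        cs <- score_basis(bs)
        if (cs >= threshold) tot <- tot + cs
      }
      by_degree[deg] <- tot
      n_bases[deg] <- length(bases)
    }
  }
  structure(list(by_degree = by_degree, C_T = sum(by_degree),
                 memory_curve = mem$curve, C_M = mem$C_M,
                 n_bases = n_bases, threshold = threshold,
                 truncated = truncated, n_state = nrow(X),
                 T = length(win)),
            class = "capacity_result")
}

#' @export
print.capacity_result <- function(x, ...) {
  cat(sprintf("<capacity_result> C_T = %.3f (C_M = %.3f); by degree: %s\n",
              x$C_T, x$C_M,
              paste(sprintf("%s=%.2f", names(x$by_degree), x$by_degree),
                    collapse = " ")))
  invisible(x)
}

#' Optimal input resolution
#'
#' For each candidate input step, harvests states and measures the
#' capacity to reconstruct the instantaneous input (degree 1, delay 0);
#' returns the smallest step whose mean capacity over seeds reaches
#' `criterion` (0.99), together with the full capacity-vs-resolution
#' curve. If the criterion is never met the returned `delta_t_star` is
#' `NA` and the curve is still provided.
#'
#' @param circuit a `microcircuit` (or a function(seed) returning one).
#' @param dt_grid candidate input steps (ms), sorted ascending.
#' @param T_steps input steps per evaluation.
#' @param rho_u,nu_in drive parameters.
#' @param seeds seeds to average over.
#' @param criterion capacity criterion (0.99).
#' @return list with `delta_t_star`, `curve` (grid x seeds matrix of
#'   capacities) and `mean_curve`.
#' @export
optimal_resolution <- function(circuit, dt_grid, T_steps = 2000, rho_u,
                               nu_in = 5, seeds = 1, criterion = 0.99) {
  stopifnot(!is.unsorted(dt_grid))
  curve <- matrix(NA_real_, length(dt_grid), length(seeds),
                  dimnames = list(dt_grid, seeds))
  for (gi in seq_along(dt_grid)) {
    for (si in seq_along(seeds)) {
      hv <- harvest_states(circuit, T_steps, dt_grid[gi], rho_u,
                           nu_in = nu_in, seed = seeds[si])
      mem <- memory_capacity(hv$X, hv$u, k_max = 0)
      curve[gi, si] <- mem$curve[1]
    }
  }
  mc <- rowMeans(curve)
  hit <- which(mc >= criterion)
  list(delta_t_star = if (length(hit)) dt_grid[hit[1]] else NA_real_,
       curve = curve, mean_curve = mc, criterion = criterion)
}
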