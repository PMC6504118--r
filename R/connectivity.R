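# Generation of the nine connection blocks: uniform Bernoulli graphs,
# skewed-degree heterogeneity and pre/post weight-correlation biasing.

#' Truncated exponential index distribution
#'
#' Normalized probability mass over neuron indices `0..n-1`,
#' \eqn{P(j) \propto e^{-j k / n}}; uniform when `k = 0`. Index 0 is by
#' convention the most-connected end.
#'
#' @param n number of neurons.
#' @param k skewness parameter (`>= 0`).
#' @return numeric vector of length `n` summing to 1.
#' @export
truncexp_pmf <- function(n, k) {
  stopifnot(n >= 1, k >= 0)
  if (k == 0) return(rep(1 / n, n))
  w <- exp(-(0:(n - 1)) * k / n)
  w / sum(w)
}

new_connection_block <- function(pre_class, post_class, pre, post,
                                 weights = numeric(0), delays = numeric(0)) {
  structure(list(pre_class = pre_class, post_class = post_class,
                 pre = as.integer(pre), post = as.integer(post),
                 weights = weights, delays = delays),
            class = "connection_block")
}

#' @export
print.connection_block <- function(x, ...) {
  cat(sprintf("<connection_block> %s -> %s, %d edges\n",
              x$pre_class, x$post_class, length(x$pre)))
  invisible(x)
}

#' Uniform (Bernoulli) connection block
#'
#' Connects each ordered (pre, post) pair independently with probability
#' `p`. Autapses are excluded when pre and post refer to the same
#' population (`same_pop = TRUE`).
#'
#' @param n_pre,n_post population sizes.
#' @param p connection probability in `[0, 1]`.
#' @param same_pop do pre and post index the same population (exclude the
#'   diagonal)?
#' @param seed optional integer seed.
#' @param pre_class,post_class class labels carried on the block.
#' @return a `connection_block` with 1-based `pre`, `post` index vectors.
#' @export
build_block_uniform <- function(n_pre, n_post, p, same_pop = FALSE,
                                seed = NULL, pre_class = "E",
                                post_class = "E") {
  stopifnot(p >= 0, p <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (p == 0 || n_pre == 0 || n_post == 0)
    return(new_connection_block(pre_class, post_class, integer(0), integer(0)))
  hit <- which(runif(n_pre * n_post) < p)
  pre <- ((hit - 1) %% n_pre) + 1
  post <- ((hit - 1) %/% n_pre) + 1
  if (same_pop) {
    keep <- pre != post
    pre <- pre[keep]; post <- post[keep]
  }
  new_connection_block(pre_class, post_class, pre, post)
}

#' Skewed-degree connection block
#'
#' Draws a fixed number of edges, `floor(p * n_pre * n_post)`, with pre-
#' and postsynaptic indices drawn independently from normalized truncated
#' exponential distributions with skewness `k_out` and `k_in`. Duplicate
#' ordered pairs and autapses are resampled, so the realized edge count is
#' exact. `k_out = k_in = 0` reduces to uniform index sampling (same edge
#' count convention).
#'
#' @inheritParams build_block_uniform
#' @param k_out,k_in skewness of the out-/in-degree distributions.
#' @return a `connection_block`.
#' @export
build_block_skewed <- function(n_pre, n_post, p, k_out = 0, k_in = 0,
                               same_pop = FALSE, seed = NULL,
                               pre_class = "E", post_class = "E") {
  stopifnot(p >= 0, p <= 1, k_out >= 0, k_in >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_edges <- floor(p * n_pre * n_post)
  if (n_edges == 0)
    return(new_connection_block(pre_class, post_class, integer(0), integer(0)))
  cdf_pre <- cumsum(truncexp_pmf(n_pre, k_out))
  cdf_post <- cumsum(truncexp_pmf(n_post, k_in))
  draw <- function(m) {
    pre <- findInterval(runif(m), cdf_pre) + 1L
    post <- findInterval(runif(m), cdf_post) + 1L
    cbind(pre, post)
  }
  ed <- draw(n_edges)
  for (it in 1:10000) {
    key <- (ed[, 1] - 1) * n_post + ed[, 2]
    bad <- duplicated(key) | (same_pop & ed[, 1] == ed[, 2])
    if (!any(bad)) break
    ed[bad, ] <- draw(sum(bad))
  }
  new_connection_block(pre_class, post_class, ed[, 1], ed[, 2])
}

#' Pre/postsynaptic weight correlations
#'
#' Rescales each weight by per-neuron lognormal factors:
#' \eqn{w_{ij} \leftarrow w_{ij}\,\zeta_i\,\zeta_j} with
#' \eqn{\zeta_i \sim \mathrm{logN}(-c_{in}^2/2,\, c_{in})} per postsynaptic
#' neuron and \eqn{\zeta_j \sim \mathrm{logN}(-c_{out}^2/2,\, c_{out})} per
#' presynaptic neuron (shape parameterization, so `E[zeta] = 1`). `c = 0`
#' leaves weights exactly unchanged.
#'
#' @param block a `connection_block` with weights assigned.
#' @param c_in,c_out correlation strengths (`>= 0`).
#' @param n_pre,n_post population sizes (defaults: max index in block).
#' @param seed optional integer seed.
#' @return the block with rescaled weights.
#' @export
apply_weight_correlations <- function(block, c_in, c_out,
                                      n_pre = max(block$pre, 0),
                                      n_post = max(block$post, 0),
                                      seed = NULL) {
  stopifnot(c_in >= 0, c_out >= 0, length(block$weights) == length(block$pre))
  if (!is.null(seed)) set.seed(seed)
  if (c_in == 0 && c_out == 0) return(block)
  zi <- if (c_in > 0) rlnorm(n_post, -c_in^2 / 2, c_in) else rep(1, n_post)
  zj <- if (c_out > 0) rlnorm(n_pre, -c_out^2 / 2, c_out) else rep(1, n_pre)
  block$weights <- block$weights * zi[block$post] * zj[block$pre]
  block
}

#' Export a connection block as a plain-text edge table
#'
#' Four columns: pre, post (1-based indices), weight, delay (ms).
#'
#' @param block a `connection_block`.
#' @param file output path.
#' @export
write_edge_list <- function(block, file) {
  df <- data.frame(pre = block$pre, post = block$post,
                   weight = block$weights, delay = block$delays)
  write.table(df, file, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(file)
}
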