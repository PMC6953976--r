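#' Parameters of the preferential-attachment network model
#'
#' @param mu Mean-like parameter of the censored Poisson distribution of
#'   new-edge counts (dimensionless, \code{> 0}).
#' @param gamma Mixture parameter in \code{[0, 1]} governing the degree of
#'   preferential attachment: 0 gives pure degree-proportional attachment,
#'   1 gives pure recency weighting.
#' @return Object of class \code{netsi_pa_params}.
#' @export
pa_params <- function(mu, gamma = 0) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu <= 0)
    stop("'mu' must be a single positive number")
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma < 0 || gamma > 1)
    stop("'gamma' must lie in [0, 1]")
  structure(list(mu = mu, gamma = gamma), class = "netsi_pa_params")
}

#' Censored Poisson log-pmf for new-edge counts
#'
#' When the i-th node enters a network of \code{i - 1} existing nodes it
#' brings \code{X} new edges, where \code{X} is Poisson with mean \code{mu},
#' with the mass at 0 moved to 1 and the upper tail at and beyond
#' \code{i - 1} lumped onto \code{i - 1}, so the support is
#' \code{1..(i - 1)}.
#'
#' @param x Integer count (vectorised).
#' @param mu Poisson parameter, \code{>= 0} (the value 0 is admitted as the
#'   degenerate limit with all mass at \code{x = 1}).
#' @param i Entry position, integer \code{>= 3}.
#' @return Log-probability; \code{-Inf} outside the support.
#' @export
#' @examples
#' exp(cpois_logpmf(1, 4, 10)) # 5 * exp(-4)
cpois_logpmf <- function(x, mu, i) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0)
    stop("'mu' must be a single non-negative number")
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 3L)
    stop("'i' must be a single integer >= 3")
  if (any(x != floor(x))) stop("'x' must be integer-valued")
  x <- as.integer(x)
  out <- rep(-Inf, length(x))
  out[x == 1L] <- -mu + log1p(mu)
  mid <- x >= 2L & x <= i - 2L
  if (any(mid)) out[mid] <- stats::dpois(x[mid], mu, log = TRUE)
  tail <- x == i - 1L
  if (any(tail))
    # Poisson survival function: computed through the regularised
    # incomplete gamma function inside ppois(), stable for large i
    out[tail] <- stats::ppois(i - 2L, mu, lower.tail = FALSE, log.p = TRUE)
  out
}

#' Draw censored Poisson new-edge counts
#'
#' @inheritParams cpois_logpmf
#' @param n Number of draws.
#' @return Integer vector in \code{1..(i - 1)}.
#' @export
cpois_sample <- function(mu, i, n = 1L) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu <= 0)
    stop("'mu' must be a single positive number")
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 3L)
    stop("'i' must be a single integer >= 3")
  pmin.int(pmax.int(stats::rpois(n, mu), 1L), i - 1L)
}

#' Mean connectivity summary mu*
#'
#' The large-network mean of the censored Poisson new-edge count,
#' \eqn{\mu^* = \mu + e^{-\mu}}, bounded below by 1 with the minimum at
#' \eqn{\mu = 0}.
#'
#' @param mu Non-negative numeric (vectorised).
#' @return \code{mu + exp(-mu)}.
#' @export
#' @examples
#' mu_star(6) # 6.002479
mu_star <- function(mu) {
  if (!is.numeric(mu) || anyNA(mu) || any(mu < 0))
    stop("'mu' must be non-negative")
  mu + exp(-mu)
}

#' Attachment weights for a new node
#'
#' The probability weights with which an entering node picks each existing
#' node: a mixture of the degree-proportional (preferential-attachment)
#' component and a recency component proportional to the entry rank.
#'
#' @param prefix_degrees Integer vector: current degrees of the existing
#'   nodes, listed in entry order.
#' @param gamma Mixture parameter in \code{[0, 1]}.
#' @return Weight vector summing to 1.
#' @export
#' @examples
#' attachment_weights(c(2, 1, 1), 0) # c(1/2, 1/4, 1/4)
attachment_weights <- function(prefix_degrees, gamma) {
  n <- length(prefix_degrees)
  if (n < 1L) stop("empty prefix")
  if (any(prefix_degrees < 0)) stop("degrees must be non-negative")
  if (gamma < 0 || gamma > 1) stop("'gamma' must lie in [0, 1]")
  d <- sum(prefix_degrees)
  if (d == 0) stop("all-zero degrees: not a valid growth prefix")
  (1 - gamma) * prefix_degrees / d + gamma * seq_len(n) / (n * (n + 1) / 2)
}

#' Weighted sample of attachment targets without replacement
#'
#' Draws \code{x} distinct indices by successive sampling: one index at a
#' time with probability proportional to its weight, removing it and
#' renormalising before the next draw.
#'
#' @param w Weight vector (positive entries, any scale).
#' @param x Number of indices to draw, \code{1 <= x <= length(w)}.
#' @return Integer vector of \code{x} distinct indices (in draw order).
#' @export
sample_attachment_set <- function(w, x) {
  x <- as.integer(x)
  if (x < 1L || x > length(w)) stop("'x' must lie in 1..length(w)")
  sample.int(length(w), size = x, replace = FALSE, prob = w)
}

#' Exact log-probability that successive sampling yields a given set
#'
#' The probability that \code{x} successive weighted draws without
#' replacement produce exactly the unordered index set \code{set}.  It is
#' computed by a subset recursion over the set (equivalently, a sum over all
#' draw orders), which involves only positive terms and is exact to machine
#' precision; the cost is \code{O(2^x)}, so the set size is capped.
#'
#' @param w Weight vector of all candidates (positive, any scale).
#' @param set Integer vector of distinct indices into \code{w}.
#' @param max_size Largest admissible set size (guards the exponential cost).
#' @return Log-probability of drawing exactly \code{set}.
#' @export
attachment_set_logprob <- function(w, set, max_size = 16L) {
  set <- as.integer(set)
  x <- length(set)
  if (x < 1L || anyDuplicated(set) || any(set < 1L | set > length(w)))
    stop("'set' must be distinct indices into 'w'")
  if (x > max_size)
    stop("exact set probability restricted to sets of size <= ", max_size)
  if (any(w <= 0)) stop("weights must be positive")
  w <- w / sum(w)
  if (x == length(w)) return(0)
  ws <- w[set]
  # g[mask] = P(first draws are exactly the sub-set 'mask', any order)
  nmask <- bitwShiftL(1L, x)
  g <- numeric(nmask)
  g[1L] <- 1
  wsum <- numeric(nmask)
  for (mask in seq_len(nmask - 1L)) {
    lo <- bitwAnd(mask, -mask)
    j <- which(bitwShiftL(1L, seq_len(x) - 1L) == lo)
    wsum[mask + 1L] <- wsum[bitwXor(mask, lo) + 1L] + ws[j]
  }
  for (mask in seq_len(nmask - 1L)) {
    acc <- 0
    rem <- mask
    while (rem != 0L) {
      lo <- bitwAnd(rem, -rem)
      rem <- bitwXor(rem, lo)
      prev <- bitwXor(mask, lo)
      j <- which(bitwShiftL(1L, seq_len(x) - 1L) == lo)
      acc <- acc + g[prev + 1L] * ws[j] / (1 - wsum[prev + 1L])
    }
    g[mask + 1L] <- acc
  }
  log(g[nmask])
}

#' Simulate a preferential-attachment contact network
#'
#' Grows the network by the modified preferential-attachment rule: an
#' initial connected dyad, then each entering node draws a censored-Poisson
#' number of new edges and attaches them to existing nodes chosen by
#' successive weighted sampling without replacement.
#'
#' @param m Number of nodes, \code{>= 2}.
#' @param params A \code{netsi_pa_params} object.
#' @param order Either a \code{netsi_order} (or permutation vector) fixing
#'   the entry order, or \code{"random"} to draw it uniformly (the uniform
#'   prior on orders).
#' @return List with elements \code{graph} (a \code{netsi_graph}) and
#'   \code{order} (a \code{netsi_order}).  The graph is always connected and
#'   its backward degrees along \code{order} satisfy the growth-support
#'   predicate.
#' @export
#' @examples
#' set.seed(1)
#' net <- generate_pa_network(20, pa_params(mu = 6, gamma = 0))
generate_pa_network <- function(m, params, order = "random") {
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 2L) stop("'m' must be >= 2")
  if (!inherits(params, "netsi_pa_params")) stop("'params' must be pa_params()")
  sigma <- if (identical(order, "random")) sample.int(m) else as.integer(order)
  sigma <- network_order(sigma)
  adj <- matrix(FALSE, m, m)
  adj[sigma[1L], sigma[2L]] <- adj[sigma[2L], sigma[1L]] <- TRUE
  deg <- numeric(m) # degree within the current prefix, indexed by entry rank
  deg[1:2] <- 1
  if (m >= 3L) {
    for (i in 3:m) {
      x <- cpois_sample(params$mu, i)
      w <- attachment_weights(deg[seq_len(i - 1L)], params$gamma)
      targets <- sample_attachment_set(w, x)
      adj[sigma[i], sigma[targets]] <- TRUE
      adj[sigma[targets], sigma[i]] <- TRUE
      deg[targets] <- deg[targets] + 1
      deg[i] <- x
    }
  }
  g <- structure(list(m = m, adj = adj, edge_count = sum(adj) %/% 2L),
                 class = "netsi_graph")
  list(graph = g, order = sigma)
}

#' Exact log-probability of a graph given the entry order
#'
#' The probability of the contact graph under the preferential-attachment
#' growth model for a fixed entry order: the product, over entry positions
#' \code{i = 3..m}, of the censored-Poisson probability of the backward
#' degree and the exact successive-sampling probability of the realised
#' attachment set.  Orders under which the graph cannot be grown (backward
#' degree 0 at some position, or missing initial dyad edge) yield
#' \code{-Inf}.
#'
#' @param g A \code{netsi_graph} or adjacency matrix.
#' @param order Entry order (permutation of \code{1..m}).
#' @param params A \code{netsi_pa_params} object.
#' @param max_set_size Cap on exact set-probability computation; see
#'   \code{\link{attachment_set_logprob}}.
#' @return Log-probability (\code{-Inf} encodes zero support).
#' @export
log_graph_given_order <- function(g, order, params, max_set_size = 16L) {
  g <- as_contact_graph(g)
  sigma <- as.integer(order)
  if (length(sigma) != g$m) stop("graph and order sizes differ")
  m <- g$m
  if (!g$adj[sigma[1L], sigma[2L]]) return(-Inf)
  if (m == 2L) return(0)
  x <- back_degrees(g, sigma)
  if (any(x[-1L] < 1L)) return(-Inf)
  total <- 0
  deg <- numeric(m)
  deg[1:2] <- 1
  for (i in 3:m) {
    xi <- x[i - 1L]
    targets <- which(g$adj[sigma[i], sigma[seq_len(i - 1L)]])
    w <- attachment_weights(deg[seq_len(i - 1L)], params$gamma)
    total <- total + cpois_logpmf(xi, params$mu, i) +
      attachment_set_logprob(w, targets, max_size = max_set_size)
    deg[targets] <- deg[targets] + 1
    deg[i] <- xi
  }
  total
}

# Ordered (draw-order-augmented) log-density of a graph: the successive-
# sampling probability of each attachment set *in the recorded draw order*.
# Marginalising the orders recovers log_graph_given_order().  This is the
# density the MCMC sampler targets (with the orders as latent variables);
# kept in R as an independent cross-check of the compiled implementation.
# `orders` is a list of length m whose element i (i >= 3) holds the entry
# ranks (positions within the prefix, 1-based) attached by the i-th
# entrant, in draw order.
augmented_graph_logdens <- function(adj, sigma, orders, mu, gamma) {
  m <- length(sigma)
  if (!adj[sigma[1L], sigma[2L]]) return(-Inf)
  if (m == 2L) return(0)
  total <- 0
  deg <- numeric(m)
  deg[1:2] <- 1
  for (i in 3:m) {
    o <- orders[[i]]
    xi <- length(o)
    if (xi < 1L) return(-Inf)
    w <- attachment_weights(deg[seq_len(i - 1L)], gamma)
    rem <- 1
    for (r in seq_len(xi)) {
      total <- total + log(w[o[r]] / rem)
      rem <- rem - w[o[r]]
    }
    total <- total + cpois_logpmf(xi, mu, i)
    deg[o] <- deg[o] + 1
    deg[i] <- xi
  }
  total
}
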