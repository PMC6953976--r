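#' Simulate an SI epidemic on a fixed contact graph
#'
#' A Markovian susceptible-infectious epidemic: each edge between an
#' infected and a susceptible node carries an independent exponential clock
#' with rate \code{beta}; the next infection happens at the minimum clock
#' and the clock's edge determines the infector.  Infected nodes stay
#' infectious, so on a connected graph the epidemic runs until every node is
#' infected (the observation period is assumed to cover all infections).
#'
#' @param g A \code{netsi_graph} (must be connected) or adjacency matrix.
#' @param beta Per-edge infection rate (\code{> 0}, per unit time).
#' @param start Label of the index case (default 1).
#' @param relabel Rename nodes into infection order so that the returned
#'   object satisfies the epidemic invariants (default \code{TRUE}).  The
#'   attribute \code{node_map} gives, for each new label, the original one.
#' @return A \code{netsi_epidemic} (when \code{relabel = TRUE}), or a plain
#'   list with \code{times}/\code{parent} in original labels otherwise.
#' @export
#' @examples
#' set.seed(1)
#' g <- contact_graph(3, rbind(c(1, 2), c(2, 3)))
#' ep <- simulate_si(g, beta = 0.5)
simulate_si <- function(g, beta, start = 1L, relabel = TRUE) {
  g <- as_contact_graph(g)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("'beta' must be a single positive number")
  m <- g$m
  # connectivity check (SI on a disconnected graph never infects everyone)
  seen <- logical(m)
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nb <- which(g$adj[, frontier, drop = FALSE] %*% rep(1, length(frontier)) > 0)
    frontier <- nb[!seen[nb]]
    seen[frontier] <- TRUE
  }
  if (!all(seen)) stop("graph is disconnected: SI epidemic cannot reach all nodes")

  infected <- logical(m)
  infected[start] <- TRUE
  times <- rep(NA_real_, m)
  parent <- rep(NA_integer_, m)
  times[start] <- 0
  t_now <- 0
  ninf <- as.numeric(g$adj[, start]) # infected-neighbour count per node
  order_inf <- integer(m)
  order_inf[1L] <- start
  for (k in seq_len(m - 1L)) {
    rates <- ifelse(infected, 0, ninf) * beta
    total <- sum(rates)
    t_now <- t_now + stats::rexp(1L, total)
    j <- sample.int(m, 1L, prob = rates)
    src <- which(g$adj[, j] & infected)
    infector <- if (length(src) == 1L) src else sample(src, 1L)
    infected[j] <- TRUE
    times[j] <- t_now
    parent[j] <- infector
    ninf <- ninf + g$adj[, j]
    order_inf[k + 1L] <- j
  }
  if (!relabel)
    return(list(m = m, times = times, parent = parent))
  new_lab <- integer(m)
  new_lab[order_inf] <- seq_len(m)
  ep <- epidemic(times[order_inf],
                 new_lab[parent[order_inf]][-1L])
  attr(ep, "node_map") <- order_inf
  ep
}

#' Relabel a graph into the infection order of a simulated epidemic
#'
#' @param g The graph the epidemic was simulated on.
#' @param ep The relabelled epidemic returned by \code{\link{simulate_si}}
#'   (its \code{node_map} attribute is used).
#' @return The same graph with nodes renamed into epidemic order.
#' @export
relabel_graph <- function(g, ep) {
  g <- as_contact_graph(g)
  map <- attr(ep, "node_map")
  if (is.null(map)) stop("'ep' carries no node_map attribute")
  contact_graph(g$m, edges = {
    e <- graph_edges(g)
    inv <- integer(g$m)
    inv[map] <- seq_len(g$m)
    cbind(inv[e[, 1L]], inv[e[, 2L]])
  })
}

#' Log-probability of the transmission tree given the graph
#'
#' Each newly infected node is equally likely to have been infected by any
#' of its already-infected neighbours, so the tree probability is the
#' product over non-index nodes of one over the number of earlier-infected
#' graph neighbours; it is zero (log \code{-Inf}) if any tree edge is
#' missing from the graph.
#'
#' @param ep A valid \code{netsi_epidemic}.
#' @param g A \code{netsi_graph} or adjacency matrix.
#' @return Log-probability.
#' @export
log_tree_given_graph <- function(ep, g) {
  g <- as_contact_graph(g)
  bad <- validate_epidemic(ep)
  if (length(bad)) stop("invalid epidemic: ", paste(bad, collapse = "; "))
  if (g$m != ep$m) stop("graph and epidemic sizes differ")
  total <- 0
  for (j in 2:ep$m) {
    if (!g$adj[ep$parent[j], j]) return(-Inf)
    total <- total - log(sum(g$adj[seq_len(j - 1L), j]))
  }
  total
}

#' Log-density of the infection times given the graph
#'
#' The exponential-race path density of the observed (shifted) infection
#' times: \code{(m - 1) log(beta) - beta * E}, where \code{E} is the total
#' edge exposure, the sum over graph edges of the time both endpoints were
#' not yet jointly infected (\code{|I_j - I_i|}).
#'
#' @inheritParams log_tree_given_graph
#' @param beta Per-edge infection rate.
#' @return Log-density.
#' @export
log_times_given_graph <- function(ep, g, beta) {
  g <- as_contact_graph(g)
  bad <- validate_epidemic(ep)
  if (length(bad)) stop("invalid epidemic: ", paste(bad, collapse = "; "))
  if (beta <= 0) stop("'beta' must be positive")
  (ep$m - 1) * log(beta) - beta * total_exposure(ep, g)
}

#' Per-pair edge exposure
#'
#' The time during which an edge between nodes \code{i} and \code{j}
#' (epidemic labels, \code{i < j}) could have transmitted but the later node
#' was still susceptible: \code{times[j] - times[i]}.  Summed over graph
#' edges it gives the exponent of the times likelihood, and it is the exact
#' amount by which one edge flip changes that exponent.
#'
#' @param ep A valid \code{netsi_epidemic}.
#' @param i,j Node labels with \code{i < j}.
#' @return Non-negative number.
#' @export
edge_exposure <- function(ep, i, j) {
  if (any(i >= j)) stop("'i' must be smaller than 'j'")
  ep$times[j] - ep$times[i]
}

#' Total edge exposure of a graph
#'
#' @inheritParams log_tree_given_graph
#' @return Sum of \code{edge_exposure} over all graph edges.
#' @export
total_exposure <- function(ep, g) {
  g <- as_contact_graph(g)
  e <- graph_edges(g)
  if (nrow(e) == 0L) return(0)
  sum(ep$times[e[, 2L]] - ep$times[e[, 1L]])
}

#' Posterior-predictive cumulative infection counts
#'
#' For each simulation a parameter pair is drawn from the supplied posterior
#' sample, a preferential-attachment network is generated (uniformly random
#' entry order), an SI epidemic is simulated on it, and the cumulative
#' number of infected is read off a time grid.  Pointwise quantiles across
#' simulations form the predictive band.
#'
#' @param draws Data frame (or matrix) of posterior draws with columns
#'   \code{beta} and \code{mu}.
#' @param m Population size for the predictive epidemics.
#' @param time_grid Numeric vector of times (from 0).
#' @param n_sims Number of predictive simulations.
#' @param gamma Preferential-attachment mixture parameter used for network
#'   generation (default 0, the pure PA model).
#' @param probs Quantile levels of the band.
#' @return Data frame with columns \code{time}, \code{lower}, \code{median},
#'   \code{upper} (the requested quantiles of the cumulative count).
#' @export
predictive_counts <- function(draws, m, time_grid, n_sims = 200L,
                              gamma = 0, probs = c(0.025, 0.5, 0.975)) {
  draws <- as.data.frame(draws)
  if (nrow(draws) == 0L) stop("'draws' must contain at least one posterior draw")
  if (!all(c("beta", "mu") %in% names(draws)))
    stop("'draws' must have columns 'beta' and 'mu'")
  counts <- matrix(NA_real_, n_sims, length(time_grid))
  for (s in seq_len(n_sims)) {
    d <- draws[sample.int(nrow(draws), 1L), ]
    net <- generate_pa_network(m, pa_params(mu = d$mu, gamma = gamma))
    ep <- simulate_si(net$graph, beta = d$beta)
    counts[s, ] <- vapply(time_grid,
                          function(t) sum(ep$times <= t), numeric(1L))
  }
  q <- apply(counts, 2L, stats::quantile, probs = probs, names = FALSE)
  data.frame(time = time_grid, lower = q[1L, ], median = q[2L, ],
             upper = q[3L, ])
}
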