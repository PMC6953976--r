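#' Construct a contact graph
#'
#' A contact graph is the undirected, simple (hollow, symmetric) social
#' network \eqn{\mathcal{G}} over which an epidemic can spread.  Nodes are
#' labelled \code{1..m} in epidemic (infection-time) order.
#'
#' @param m Number of nodes (integer, at least 2).
#' @param edges Two-column integer matrix of undirected edges, one row per
#'   edge, in any orientation.  \code{NULL} gives the empty graph.
#' @return An object of class \code{netsi_graph}: a list with elements
#'   \code{m}, \code{adj} (logical \code{m x m} symmetric matrix with zero
#'   diagonal) and \code{edge_count}.
#' @export
#' @examples
#' g <- contact_graph(3, rbind(c(1, 2), c(2, 3)))
#' g$edge_count
contact_graph <- function(m, edges = NULL) {
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 2L)
    stop("'m' must be a single integer >= 2")
  adj <- matrix(FALSE, m, m)
  if (!is.null(edges)) {
    edges <- matrix(as.integer(edges), ncol = 2L)
    if (any(is.na(edges)) || any(edges < 1L) || any(edges > m))
      stop("edge endpoints must be node labels in 1..m")
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loops are not allowed")
    adj[edges] <- TRUE
    adj[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  structure(list(m = m, adj = adj, edge_count = sum(adj) %/% 2L),
            class = "netsi_graph")
}

#' @export
print.netsi_graph <- function(x, ...) {
  cat("<netsi_graph> ", x$m, " nodes, ", x$edge_count, " edges\n", sep = "")
  invisible(x)
}

as_contact_graph <- function(g) {
  if (inherits(g, "netsi_graph")) return(g)
  if (is.matrix(g)) {
    if (!isTRUE(all.equal(unname(g != 0), unname(t(g != 0)))) ||
        any(diag(g) != 0))
      stop("adjacency matrix must be symmetric with zero diagonal")
    adj <- g != 0
    return(structure(list(m = nrow(g), adj = adj,
                          edge_count = sum(adj) %/% 2L),
                     class = "netsi_graph"))
  }
  stop("cannot interpret 'g' as a contact graph")
}

#' Edge list of a contact graph
#'
#' @param g A \code{netsi_graph}.
#' @return Two-column integer matrix with one row per undirected edge,
#'   \code{i < j}.
#' @export
graph_edges <- function(g) {
  g <- as_contact_graph(g)
  idx <- which(upper.tri(g$adj) & g$adj, arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Construct a network entry order
#'
#' The entry order \eqn{\sigma} records the sequence in which nodes joined
#' the network during preferential-attachment growth; \code{sigma[i]} is the
#' epidemic label of the i-th node to enter.  It is distinct from the
#' epidemic order.
#'
#' @param sigma Permutation of \code{1..m}.
#' @return Integer vector of class \code{netsi_order}.
#' @export
network_order <- function(sigma) {
  sigma <- as.integer(sigma)
  m <- length(sigma)
  if (m < 2L || !identical(sort(sigma), seq_len(m)))
    stop("'sigma' must be a permutation of 1..m with m >= 2")
  structure(sigma, class = "netsi_order")
}

#' Construct an epidemic (infection times plus transmission tree)
#'
#' Nodes are labelled in epidemic order: the index case is node 1 with
#' shifted infection time 0, and times are strictly increasing (the
#' continuous-time model gives ties probability zero, so tied times are
#' rejected rather than jittered).  The transmission tree records, for each
#' non-index node, the node that infected it.
#'
#' @param times Numeric vector of shifted infection times, \code{times[1] == 0}.
#' @param parents Integer vector of length \code{m - 1}: \code{parents[j - 1]}
#'   is the infector of node \code{j} for \code{j = 2..m}.  Alternatively a
#'   named list such as \code{list(`2` = 1, `3` = 2)}.
#' @param validate Check invariants and stop on violation (default \code{TRUE}).
#' @return Object of class \code{netsi_epidemic} with elements \code{m},
#'   \code{times} and \code{parent} (length \code{m}; \code{parent[1]} is
#'   \code{NA}).
#' @export
#' @examples
#' ep <- epidemic(c(0, 1.2, 3.4), c(1, 1))
epidemic <- function(times, parents, validate = TRUE) {
  times <- as.numeric(times)
  m <- length(times)
  if (is.list(parents)) {
    p <- rep(NA_integer_, m)
    p[as.integer(names(parents)) ] <- as.integer(unlist(parents))
    parents <- p[-1L]
  }
  parent <- c(NA_integer_, as.integer(parents))
  ep <- structure(list(m = m, times = times, parent = parent),
                  class = "netsi_epidemic")
  if (validate) {
    bad <- validate_epidemic(ep)
    if (length(bad)) stop("invalid epidemic: ", paste(bad, collapse = "; "))
  }
  ep
}

#' @export
print.netsi_epidemic <- function(x, ...) {
  cat("<netsi_epidemic> m = ", x$m, ", duration = ",
      format(max(x$times)), "\n", sep = "")
  invisible(x)
}

#' Check the invariants of an epidemic
#'
#' The index case must be infected at time 0, infection times must be
#' strictly increasing in the node label, every non-index node must have a
#' single infector with a smaller label (no self-infection), and the parent
#' map must form a tree rooted at node 1 spanning all nodes.
#'
#' @param ep A \code{netsi_epidemic} (not necessarily valid).
#' @return Character vector of violations; empty when the epidemic is valid.
#' @export
validate_epidemic <- function(ep) {
  v <- character()
  m <- ep$m
  if (m < 2L) v <- c(v, "epidemic must contain at least 2 nodes")
  if (length(ep$times) != m || length(ep$parent) != m)
    return(c(v, "times/parent length inconsistent with m"))
  if (!isTRUE(ep$times[1L] == 0)) v <- c(v, "index-case time not 0")
  if (anyNA(ep$times)) v <- c(v, "missing infection times")
  d <- diff(ep$times)
  if (any(d == 0, na.rm = TRUE))
    v <- c(v, paste0("tied infection times at j=",
                     which(d == 0)[1L] + 1L))
  if (any(d < 0, na.rm = TRUE))
    v <- c(v, paste0("times not increasing at j=", which(d < 0)[1L] + 1L))
  for (j in seq_len(m)[-1L]) {
    pj <- ep$parent[j]
    if (is.na(pj)) { v <- c(v, paste0("missing infector at j=", j)); next }
    if (pj == j)   { v <- c(v, paste0("self-infection at j=", j)); next }
    if (pj < 1L || pj > m)
      v <- c(v, paste0("infector out of range at j=", j))
    else if (pj >= j)
      v <- c(v, paste0("infector not earlier than infectee at j=", j))
  }
  # parent(j) < j for all j >= 2 already implies a spanning tree rooted at 1
  v
}

#' Transmission tree as an undirected graph
#'
#' Returns the undirected graph whose edges are exactly the parent-child
#' pairs of the transmission tree; the epidemic can only travel along edges
#' of the contact graph, so this is always a spanning subgraph of it.
#'
#' @param ep A valid \code{netsi_epidemic}.
#' @param m Optional node count override (defaults to \code{ep$m}).
#' @return A \code{netsi_graph} with \code{m - 1} edges.
#' @export
tree_subgraph <- function(ep, m = ep$m) {
  bad <- validate_epidemic(ep)
  if (length(bad)) stop("invalid epidemic: ", paste(bad, collapse = "; "))
  if (m != ep$m) stop("'m' inconsistent with epidemic size")
  contact_graph(m, cbind(ep$parent[-1L], seq_len(m)[-1L]))
}

#' Backward degrees along an entry order
#'
#' For each entry position \code{i = 2..m}, the number of edges the i-th
#' entering node has to nodes that entered before it.  These are the
#' realised new-edge counts of the preferential-attachment growth under the
#' given order; position 2 must equal 1 (the initial dyad) and positions
#' \code{i >= 3} must lie in \code{1..(i-1)} for the order to be supported.
#'
#' @param g A \code{netsi_graph} or adjacency matrix.
#' @param order A \code{netsi_order} (or permutation vector) of the same size.
#' @return Integer vector \code{x} of length \code{m - 1}; \code{x[i - 1]}
#'   is the backward degree of entry position \code{i}.
#' @export
back_degrees <- function(g, order) {
  g <- as_contact_graph(g)
  sigma <- as.integer(order)
  if (length(sigma) != g$m) stop("'g' and 'order' have inconsistent sizes")
  vapply(2:g$m, function(i) {
    sum(g$adj[sigma[i], sigma[seq_len(i - 1L)]])
  }, integer(1L))
}

#' Is an entry order supported for a graph?
#'
#' @inheritParams back_degrees
#' @return \code{TRUE} iff the backward degrees satisfy \code{x[2] == 1} and
#'   \code{x[i] >= 1} for \code{i >= 3}, i.e. iff the graph has positive
#'   probability under the growth model for this order.
#' @export
order_supported <- function(g, order) {
  x <- back_degrees(g, order)
  x[1L] == 1L && all(x >= 1L)
}

#' Partial observation of the contact graph
#'
#' Records, for every unordered node pair, whether the edge status is known
#' to be present, known to be absent, or unknown.  Transmission-tree pairs
#' are always known-present.
#'
#' @param m Node count.
#' @param present,absent Two-column matrices of node pairs (any orientation)
#'   whose status is known.
#' @return Object of class \code{netsi_observation}: a list with \code{m}
#'   and \code{status}, an \code{m x m} integer matrix coded 0 = unknown,
#'   1 = known-present, 2 = known-absent.
#' @export
graph_observation <- function(m, present = NULL, absent = NULL) {
  m <- as.integer(m)
  status <- matrix(0L, m, m)
  fill <- function(status, pairs, code) {
    if (is.null(pairs) || nrow(pairs) == 0L) return(status)
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    if (any(pairs < 1L | pairs > m) || any(pairs[, 1L] == pairs[, 2L]))
      stop("observation pairs must be distinct node labels in 1..m")
    status[pairs] <- code
    status[pairs[, 2:1, drop = FALSE]] <- code
    status
  }
  status <- fill(status, present, 1L)
  both <- status == 1L
  status <- fill(status, absent, 2L)
  if (any(both & status == 2L))
    stop("a pair cannot be both known-present and known-absent")
  structure(list(m = m, status = status), class = "netsi_observation")
}

#' @export
print.netsi_observation <- function(x, ...) {
  up <- upper.tri(x$status)
  cat("<netsi_observation> ", x$m, " nodes: ",
      sum(x$status[up] == 1L), " known-present, ",
      sum(x$status[up] == 2L), " known-absent, ",
      sum(x$status[up] == 0L), " unknown pairs\n", sep = "")
  invisible(x)
}
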