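#' Read an epidemic from a delimited file
#'
#' The file is comma-delimited with header \code{node,infector,time}, one
#' row per individual; \code{#} lines are comments.  The index case has an
#' empty (or 0) infector.  Rows may be in any order; they are sorted by
#' time, node labels are checked to be the epidemic order, and times are
#' shifted so the index case is at 0.
#'
#' @param path File path.
#' @return A validated \code{netsi_epidemic}.
#' @export
read_epidemic <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                        colClasses = c("integer", "character", "numeric"))
  if (!all(c("node", "infector", "time") %in% names(df)))
    stop("epidemic file must have header node,infector,time")
  if (anyNA(df$time)) stop("non-numeric time at row ", which(is.na(df$time))[1L])
  df <- df[order(df$time), , drop = FALSE]
  m <- nrow(df)
  if (anyDuplicated(df$time))
    stop("tied infection times at row ", anyDuplicated(df$time))
  if (!identical(sort(df$node), seq_len(m)))
    stop("node labels must be 1..m (epidemic order)")
  if (!identical(df$node, seq_len(m)))
    stop("node labels disagree with the time ordering at row ",
         which(df$node != seq_len(m))[1L])
  inf <- df$infector
  inf[inf == "" | is.na(inf)] <- "0"
  inf <- suppressWarnings(as.integer(inf))
  if (anyNA(inf)) stop("non-integer infector at row ", which(is.na(inf))[1L])
  roots <- which(inf == 0L)
  if (length(roots) != 1L)
    stop(if (length(roots) == 0L) "missing root (no empty infector)"
         else paste0("multiple roots at rows ", paste(roots, collapse = ",")))
  if (roots != 1L) stop("the earliest-infected row must be the root")
  bad <- which(inf[-1L] >= df$node[-1L]) + 1L
  if (length(bad))
    stop("infector not infected earlier than infectee at row ", bad[1L])
  epidemic(df$time - df$time[1L], inf[-1L])
}

#' Write an epidemic to a delimited file
#'
#' @param ep A valid \code{netsi_epidemic}.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_epidemic <- function(ep, path) {
  bad <- validate_epidemic(ep)
  if (length(bad)) stop("invalid epidemic: ", paste(bad, collapse = "; "))
  df <- data.frame(node = seq_len(ep$m),
                   infector = c("", as.character(ep$parent[-1L])),
                   time = ep$times)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a partial graph observation from an edge-status file
#'
#' Comma-delimited with header \code{i,j,status}; \code{status} is
#' \code{present} or \code{absent}; unlisted pairs are unknown.  Pairs must
#' satisfy \code{i < j} and appear at most once.
#'
#' @param path File path.
#' @param m Node count of the graph the statuses refer to.
#' @return A \code{netsi_observation}.
#' @export
read_edge_status <- function(path, m) {
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  if (!all(c("i", "j", "status") %in% names(df)))
    stop("edge-status file must have header i,j,status")
  if (any(df$i >= df$j)) stop("edge-status rows must have i < j")
  key <- paste(df$i, df$j)
  if (anyDuplicated(key)) stop("duplicate pair at row ", anyDuplicated(key))
  if (!all(df$status %in% c("present", "absent")))
    stop("status must be 'present' or 'absent'")
  graph_observation(m,
                    present = as.matrix(df[df$status == "present", c("i", "j")]),
                    absent = as.matrix(df[df$status == "absent", c("i", "j")]))
}

#' Write a partial graph observation to an edge-status file
#'
#' @param obs A \code{netsi_observation}.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_edge_status <- function(obs, path) {
  up <- which(upper.tri(obs$status) & obs$status != 0L, arr.ind = TRUE)
  up <- up[order(up[, 1L], up[, 2L]), , drop = FALSE]
  df <- data.frame(i = up[, 1L], j = up[, 2L],
                   status = c("present", "absent")[obs$status[up]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a graph as an undirected edge list
#'
#' Comma-delimited with header \code{i,j}, one row per edge, \code{i < j}.
#'
#' @param g A \code{netsi_graph}.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_graph <- function(g, path) {
  e <- graph_edges(g)
  utils::write.csv(as.data.frame(e), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a graph from an undirected edge list
#'
#' @param path File path.
#' @param m Node count.
#' @return A \code{netsi_graph}.
#' @export
read_graph <- function(path, m) {
  df <- utils::read.csv(path, comment.char = "#")
  contact_graph(m, as.matrix(df[, c("i", "j")]))
}

#' Write MCMC scalar draws to a trace file
#'
#' Comma-delimited, one row per kept iteration, columns \code{iter} plus
#' the scalar draws (\code{beta,mu,gamma,logpost} for the PA model,
#' \code{beta,p,logpost} for the BRG model) and \code{chain}.
#'
#' @param trace A \code{netsi_trace}.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace$draws, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace file written by \code{\link{write_trace}}
#'
#' @param path File path.
#' @return Data frame of draws.
#' @export
read_trace <- function(path) utils::read.csv(path, comment.char = "#")

#' Write posterior edge-inclusion probabilities
#'
#' Comma-delimited triplets \code{i,j,prob} with \code{i < j}.
#'
#' @param trace A \code{netsi_trace} (or a data frame with columns
#'   \code{i}, \code{j}, \code{prob}).
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_edge_probs <- function(trace, path) {
  df <- if (inherits(trace, "netsi_trace")) trace$edge_prob else trace
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an edge-probability file
#'
#' @param path File path.
#' @return Data frame with columns \code{i}, \code{j}, \code{prob}.
#' @export
read_edge_probs <- function(path) utils::read.csv(path, comment.char = "#")

#' Reveal a random fraction of the true contact graph
#'
#' Builds the partial observation used in the simulation studies: all
#' transmission-tree pairs are known-present, and a uniformly random
#' fraction \code{proportion} of the remaining potential pairs (those not
#' implied by the tree) have their true status revealed.
#'
#' @param g_true The true \code{netsi_graph}.
#' @param ep The epidemic observed on it (epidemic labels).
#' @param proportion Fraction in \code{[0, 1]} of non-tree pairs revealed.
#' @return A \code{netsi_observation}.
#' @export
make_observation <- function(g_true, ep, proportion) {
  if (proportion < 0 || proportion > 1)
    stop("'proportion' must lie in [0, 1]")
  g_true <- as_contact_graph(g_true)
  m <- ep$m
  tree <- tree_subgraph(ep)
  up <- which(upper.tri(g_true$adj), arr.ind = TRUE)
  nontree <- up[!tree$adj[up], , drop = FALSE]
  k <- round(proportion * nrow(nontree))
  sel <- nontree[sample.int(nrow(nontree), k), , drop = FALSE]
  present <- rbind(graph_edges(tree), sel[g_true$adj[sel], , drop = FALSE])
  absent <- sel[!g_true$adj[sel], , drop = FALSE]
  graph_observation(m, present = present, absent = absent)
}
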