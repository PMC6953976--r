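#' Prior specification
#'
#' Independent, vaguely informative priors: Gamma (shape/rate) on the
#' infection rate \code{beta} and on the network parameter \code{mu}, a
#' Uniform(0, 1) prior on \code{gamma}, a uniform prior over permutations on
#' the entry order, and (for the Bernoulli-random-graph comparison model) a
#' Beta prior on the edge-inclusion probability \code{p}.
#'
#' @param a_beta,b_beta Gamma shape and rate for \code{beta}.
#' @param a_mu,b_mu Gamma shape and rate for \code{mu}.
#' @param a_p,b_p Beta parameters for the BRG edge probability.
#' @return Object of class \code{netsi_priors}.
#' @export
prior_spec <- function(a_beta = 1, b_beta = 0.001, a_mu = 1, b_mu = 0.001,
                       a_p = 1, b_p = 1) {
  hp <- c(a_beta = a_beta, b_beta = b_beta, a_mu = a_mu, b_mu = b_mu,
          a_p = a_p, b_p = b_p)
  if (any(hp <= 0)) stop("all prior hyperparameters must be positive")
  structure(as.list(hp), class = "netsi_priors")
}

#' Sampler configuration
#'
#' @param n_iter Total iterations per chain.
#' @param n_burnin Burn-in iterations discarded (must be \code{< n_iter}).
#' @param thin Thinning interval for kept iterations.
#' @param gamma_fixed Keep \code{gamma} fixed (default \code{TRUE}; the
#'   preferential-attachment mixture parameter is not identifiable from a
#'   single epidemic, so the default reduces to the pure PA model).
#' @param gamma_value Value at which \code{gamma} is fixed (default 0).
#' @param proposal_sd_mu,proposal_sd_gamma Initial random-walk proposal
#'   standard deviations.
#' @param adapt Tune proposal standard deviations during burn-in only
#'   (batches of 50, targeting acceptance 0.25); the post-burn-in kernel is
#'   fixed.
#' @param edges_per_iter Number of potential-edge updates per iteration;
#'   \code{NULL} sweeps every free pair once per iteration.
#' @param sigma_moves_per_iter Number of entry-order transpositions per
#'   iteration; \code{NULL} uses \code{m}.
#' @param order_moves Number of draw-order shuffle passes per iteration.
#' @param seed Integer seed; each chain uses \code{seed + chain - 1}.
#' @param init_beta,init_mu,init_gamma Optional initial values;
#'   \code{init_beta = NULL} uses the method-of-moments start
#'   \code{(m - 1) / E} on the initial graph and \code{init_mu} defaults
#'   to 1 (both shorten burn-in; any start with finite posterior is valid).
#' @return Object of class \code{netsi_config}.
#' @export
mcmc_config <- function(n_iter = 2000L, n_burnin = 1000L, thin = 1L,
                        gamma_fixed = TRUE, gamma_value = 0,
                        proposal_sd_mu = 0.5, proposal_sd_gamma = 0.1,
                        adapt = TRUE, edges_per_iter = NULL,
                        sigma_moves_per_iter = NULL, order_moves = 1L,
                        seed = NULL, init_beta = NULL, init_mu = 1,
                        init_gamma = NULL) {
  if (n_burnin >= n_iter) stop("'n_burnin' must be smaller than 'n_iter'")
  if (proposal_sd_mu <= 0 || proposal_sd_gamma <= 0)
    stop("proposal standard deviations must be positive")
  if (thin < 1L) stop("'thin' must be >= 1")
  structure(list(n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin), gamma_fixed = isTRUE(gamma_fixed),
                 gamma_value = gamma_value,
                 proposal_sd_mu = proposal_sd_mu,
                 proposal_sd_gamma = proposal_sd_gamma, adapt = isTRUE(adapt),
                 edges_per_iter = edges_per_iter,
                 sigma_moves_per_iter = sigma_moves_per_iter,
                 order_moves = as.integer(order_moves), seed = seed,
                 init_beta = init_beta, init_mu = init_mu,
                 init_gamma = init_gamma),
            class = "netsi_config")
}

#' Joint log-posterior density (up to a constant)
#'
#' The sum of the tree, times and graph log-likelihood components and the
#' log priors on \code{beta} and \code{mu} (the uniform priors on
#' \code{gamma} and the entry order contribute constants).
#'
#' @param state List with elements \code{beta}, \code{mu}, \code{gamma},
#'   \code{order} (entry order) and \code{graph} (a \code{netsi_graph}).
#' @param ep A valid \code{netsi_epidemic}.
#' @param priors A \code{netsi_priors} object.
#' @return Log-density; \code{-Inf} off the support.
#' @export
log_posterior <- function(state, ep, priors = prior_spec()) {
  if (state$beta <= 0 || state$mu <= 0 ||
      state$gamma < 0 || state$gamma > 1) return(-Inf)
  lt <- log_tree_given_graph(ep, state$graph)
  if (!is.finite(lt)) return(-Inf)
  lt + log_times_given_graph(ep, state$graph, state$beta) +
    log_graph_given_order(state$graph, state$order,
                          pa_params(state$mu, state$gamma)) +
    stats::dgamma(state$beta, priors$a_beta, priors$b_beta, log = TRUE) +
    stats::dgamma(state$mu, priors$a_mu, priors$b_mu, log = TRUE)
}

#' Gibbs update of the infection rate
#'
#' The full conditional of \code{beta} is conjugate:
#' \code{Gamma(a_beta + m - 1, b_beta + E)} with \code{E} the total edge
#' exposure of the current graph; the draw is always accepted.
#'
#' @inheritParams log_posterior
#' @return New value of \code{beta}.
#' @export
update_beta <- function(state, ep, priors = prior_spec()) {
  E <- total_exposure(ep, state$graph)
  if (ep$m < 2L || E <= 0) stop("zero exposure: no infections to inform beta")
  stats::rgamma(1L, priors$a_beta + ep$m - 1, rate = priors$b_beta + E)
}

#' Random-walk Metropolis update of mu
#'
#' Symmetric Gaussian proposal; non-positive proposals have zero prior
#' support and are rejected outright.  Only the censored-Poisson factors of
#' the graph density and the Gamma prior enter the acceptance ratio.
#'
#' @inheritParams log_posterior
#' @param proposal_sd Gaussian proposal standard deviation.
#' @return List with elements \code{mu} and \code{accepted}.
#' @export
update_mu <- function(state, ep, priors = prior_spec(), proposal_sd = 0.5) {
  if (proposal_sd <= 0) stop("'proposal_sd' must be positive")
  mu2 <- state$mu + stats::rnorm(1L, sd = proposal_sd)
  if (mu2 <= 0) return(list(mu = state$mu, accepted = FALSE))
  x <- back_degrees(state$graph, state$order)
  lr <- stats::dgamma(mu2, priors$a_mu, priors$b_mu, log = TRUE) -
    stats::dgamma(state$mu, priors$a_mu, priors$b_mu, log = TRUE)
  m <- state$graph$m
  if (m >= 3L)
    for (i in 3:m)
      lr <- lr + cpois_logpmf(x[i - 1L], mu2, i) -
        cpois_logpmf(x[i - 1L], state$mu, i)
  acc <- is.finite(lr) && log(stats::runif(1L)) < lr
  list(mu = if (acc) mu2 else state$mu, accepted = acc)
}

#' Random-walk Metropolis update of gamma
#'
#' @inheritParams update_mu
#' @param gamma_fixed Set in the sampler configuration; calling this update
#'   with \code{gamma_fixed = TRUE} is an error.
#' @return List with elements \code{gamma} and \code{accepted}.
#' @export
update_gamma <- function(state, ep, priors = prior_spec(),
                         proposal_sd = 0.1, gamma_fixed = FALSE) {
  if (gamma_fixed) stop("'gamma' is fixed: update_gamma must not be called")
  g2 <- state$gamma + stats::rnorm(1L, sd = proposal_sd)
  if (g2 < 0 || g2 > 1) return(list(gamma = state$gamma, accepted = FALSE))
  lr <- log_graph_given_order(state$graph, state$order,
                              pa_params(state$mu, g2)) -
    log_graph_given_order(state$graph, state$order,
                          pa_params(state$mu, state$gamma))
  acc <- is.finite(lr) && log(stats::runif(1L)) < lr
  list(gamma = if (acc) g2 else state$gamma, accepted = acc)
}

#' Metropolis update of the entry order by random transposition
#'
#' Proposes swapping two uniformly chosen positions of the entry order (a
#' symmetric proposal); orders under which the graph has no growth support
#' are rejected automatically.
#'
#' @inheritParams log_posterior
#' @return List with elements \code{order} and \code{accepted}.
#' @export
update_sigma <- function(state, ep, priors = prior_spec()) {
  m <- state$graph$m
  idx <- sample.int(m, 2L, replace = TRUE)
  sig2 <- as.integer(state$order)
  sig2[idx] <- sig2[rev(idx)]
  if (identical(idx[1L], idx[2L]))
    return(list(order = state$order, accepted = TRUE))
  pp <- pa_params(state$mu, state$gamma)
  lr <- log_graph_given_order(state$graph, sig2, pp) -
    log_graph_given_order(state$graph, state$order, pp)
  acc <- is.finite(lr) && log(stats::runif(1L)) < lr
  list(order = if (acc) network_order(sig2) else state$order, accepted = acc)
}

#' Metropolis sweep over the free potential edges
#'
#' Proposes flipping each unknown-status pair in a random order, accepting
#' with the exact posterior ratio (tree, times and graph factors).  Pairs
#' that are known present (including every transmission-tree pair) or known
#' absent are never proposed.  This reference implementation recomputes the
#' full graph density per flip and is intended for small problems and
#' testing; \code{\link{run_mwg}} uses the incremental compiled sampler.
#'
#' @inheritParams log_posterior
#' @param obs A \code{netsi_observation} (or \code{NULL}: only tree pairs
#'   known).
#' @return List with elements \code{graph}, \code{accepted}, \code{attempted}.
#' @export
update_edges <- function(state, ep, priors = prior_spec(), obs = NULL) {
  status <- observation_status(ep, obs)
  free <- which(upper.tri(status) & status == 0L, arr.ind = TRUE)
  g <- state$graph
  acc <- 0L
  pp <- pa_params(state$mu, state$gamma)
  lp_graph <- log_graph_given_order(g, state$order, pp)
  lp_tree <- log_tree_given_graph(ep, g)
  for (r in sample.int(nrow(free))) {
    i <- free[r, 1L]; j <- free[r, 2L]
    adj2 <- g$adj
    adj2[i, j] <- adj2[j, i] <- !adj2[i, j]
    g2 <- structure(list(m = g$m, adj = adj2, edge_count = sum(adj2) %/% 2L),
                    class = "netsi_graph")
    lp_graph2 <- log_graph_given_order(g2, state$order, pp)
    lp_tree2 <- log_tree_given_graph(ep, g2)
    d <- lp_graph2 - lp_graph + lp_tree2 - lp_tree +
      (if (adj2[i, j]) -1 else 1) * state$beta * edge_exposure(ep, i, j)
    if (is.finite(d) && log(stats::runif(1L)) < d) {
      g <- g2; lp_graph <- lp_graph2; lp_tree <- lp_tree2
      acc <- acc + 1L
    }
  }
  list(graph = g, accepted = acc, attempted = nrow(free))
}

# Merge transmission-tree constraints and a partial observation into a
# status matrix: 0 unknown, 1 known-present, 2 known-absent.
observation_status <- function(ep, obs = NULL) {
  m <- ep$m
  status <- matrix(0L, m, m)
  if (!is.null(obs)) {
    if (!inherits(obs, "netsi_observation")) stop("'obs' must be graph_observation()")
    if (obs$m != m) stop("observation size differs from epidemic size")
    status <- obs$status
  }
  for (j in 2:m) {
    pj <- ep$parent[j]
    if (status[pj, j] == 2L)
      stop("observation marks transmission-tree pair (", pj, ",", j,
           ") as absent")
    status[pj, j] <- status[j, pj] <- 1L
  }
  status
}

#' Metropolis-within-Gibbs sampler for the latent-network SI model
#'
#' Jointly samples the infection rate \code{beta}, the network parameters
#' \code{mu} (and optionally \code{gamma}), the network entry order and the
#' latent contact graph, given the infection times and transmission tree
#' and an optional partial observation of the graph.  One iteration
#' performs, in order: a conjugate Gibbs draw of \code{beta}; random-walk
#' Metropolis on \code{mu} (and \code{gamma}); random transpositions of the
#' entry order; a Metropolis sweep over the free potential edges; and
#' shuffles of the latent attachment draw orders.
#'
#' @param ep A valid \code{netsi_epidemic}.
#' @param priors A \code{netsi_priors}.
#' @param config A \code{netsi_config}.
#' @param obs Optional \code{netsi_observation} fixing the status of some
#'   potential edges (tree pairs are always known-present).
#' @param chains Number of chains, run sequentially from seeds
#'   \code{seed, seed + 1, ...} and pooled after burn-in.
#' @return Object of class \code{netsi_trace}: a list with \code{draws}
#'   (data frame: \code{chain}, \code{iter}, \code{beta}, \code{mu},
#'   \code{gamma}, \code{logpost}), \code{edge_prob} (data frame \code{i},
#'   \code{j}, \code{prob} over all unordered pairs), \code{acceptance}
#'   (per update type), \code{model}, \code{m}, \code{config} and
#'   \code{final} (final sampler state, for diagnostics).
#' @export
run_mwg <- function(ep, priors = prior_spec(), config = mcmc_config(),
                    obs = NULL, chains = 1L) {
  bad <- validate_epidemic(ep)
  if (length(bad)) stop("invalid epidemic: ", paste(bad, collapse = "; "))
  m <- ep$m
  status <- observation_status(ep, obs)
  g0 <- contact_graph(m, which(upper.tri(status) & status == 1L, arr.ind = TRUE))
  E0 <- total_exposure(ep, g0)
  beta0 <- if (is.null(config$init_beta)) (m - 1) / E0 else config$init_beta
  mu0 <- if (is.null(config$init_mu)) 1 else config$init_mu
  gamma0 <- if (config$gamma_fixed) config$gamma_value
            else if (is.null(config$init_gamma)) 0.5 else config$init_gamma
  sig_moves <- if (is.null(config$sigma_moves_per_iter)) m
               else as.integer(config$sigma_moves_per_iter)
  epi <- if (is.null(config$edges_per_iter)) 0L
         else as.integer(config$edges_per_iter)

  all_draws <- NULL
  efreq_sum <- matrix(0, m, m)
  acc <- NULL
  fin <- NULL
  for (ch in seq_len(chains)) {
    if (!is.null(config$seed)) set.seed(config$seed + ch - 1L)
    res <- cpp_mwg_pa(m, ep$times, ep$parent, status, beta0, mu0, gamma0,
                      config$gamma_fixed, priors$a_beta, priors$b_beta,
                      priors$a_mu, priors$b_mu, config$n_iter,
                      config$n_burnin, config$thin, config$proposal_sd_mu,
                      config$proposal_sd_gamma, config$adapt, sig_moves,
                      epi, config$order_moves)
    tr <- as.data.frame(res$trace)
    names(tr) <- c("beta", "mu", "gamma", "logpost")
    tr <- cbind(chain = ch, iter = seq_len(nrow(tr)), tr)
    all_draws <- rbind(all_draws, tr)
    efreq_sum <- efreq_sum + res$edge_freq
    if (is.null(acc)) acc <- res$acceptance
    else for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + res$acceptance[[nm]]
    fin <- res$final
  }
  up <- which(upper.tri(efreq_sum), arr.ind = TRUE)
  up <- up[order(up[, 1L], up[, 2L]), , drop = FALSE]
  edge_prob <- data.frame(i = up[, 1L], j = up[, 2L],
                          prob = efreq_sum[up] / chains)
  structure(list(draws = all_draws, edge_prob = edge_prob,
                 acceptance = lapply(acc, function(v)
                   c(accepted = v[1L], attempted = v[2L],
                     rate = if (v[2L] > 0) v[1L] / v[2L] else NA_real_)),
                 model = "pa", m = m, config = config, priors = priors,
                 final = fin),
            class = "netsi_trace")
}

#' Metropolis-within-Gibbs sampler for the Bernoulli-random-graph model
#'
#' The comparison model: the same epidemic likelihood, but every potential
#' edge is present independently with common probability \code{p}.  Both
#' \code{beta} and \code{p} have conjugate Gibbs updates; the free edges
#' are updated by per-pair Metropolis flips.
#'
#' @inheritParams run_mwg
#' @return A \code{netsi_trace} with draws of \code{beta}, \code{p} and
#'   \code{logpost}, and posterior edge-inclusion probabilities.
#' @export
run_brg_mwg <- function(ep, priors = prior_spec(), config = mcmc_config(),
                        obs = NULL, chains = 1L) {
  bad <- validate_epidemic(ep)
  if (length(bad)) stop("invalid epidemic: ", paste(bad, collapse = "; "))
  m <- ep$m
  status <- observation_status(ep, obs)
  g0 <- contact_graph(m, which(upper.tri(status) & status == 1L, arr.ind = TRUE))
  beta0 <- if (is.null(config$init_beta)) (m - 1) / total_exposure(ep, g0)
           else config$init_beta
  p0 <- g0$edge_count / choose(m, 2)
  all_draws <- NULL
  efreq_sum <- matrix(0, m, m)
  acc <- NULL
  for (ch in seq_len(chains)) {
    if (!is.null(config$seed)) set.seed(config$seed + ch - 1L)
    res <- cpp_mwg_brg(m, ep$times, ep$parent, status, beta0, p0,
                       priors$a_beta, priors$b_beta, priors$a_p, priors$b_p,
                       config$n_iter, config$n_burnin, config$thin)
    tr <- as.data.frame(res$trace)
    names(tr) <- c("beta", "p", "logpost")
    tr <- cbind(chain = ch, iter = seq_len(nrow(tr)), tr)
    all_draws <- rbind(all_draws, tr)
    efreq_sum <- efreq_sum + res$edge_freq
    if (is.null(acc)) acc <- res$acceptance
    else for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + res$acceptance[[nm]]
  }
  up <- which(upper.tri(efreq_sum), arr.ind = TRUE)
  up <- up[order(up[, 1L], up[, 2L]), , drop = FALSE]
  edge_prob <- data.frame(i = up[, 1L], j = up[, 2L],
                          prob = efreq_sum[up] / chains)
  structure(list(draws = all_draws, edge_prob = edge_prob,
                 acceptance = lapply(acc, function(v)
                   c(accepted = v[1L], attempted = v[2L],
                     rate = if (v[2L] > 0) v[1L] / v[2L] else NA_real_)),
                 model = "brg", m = m, config = config, priors = priors),
            class = "netsi_trace")
}

#' @export
print.netsi_trace <- function(x, ...) {
  cat("<netsi_trace> model = ", x$model, ", m = ", x$m, ", ",
      nrow(x$draws), " kept draws\n", sep = "")
  invisible(x)
}

#' Network-scaled epidemic rate per posterior draw
#'
#' The identifiable product \eqn{\alpha = \beta \mu^*} of the per-edge
#' infection rate and the mean network connectivity
#' \eqn{\mu^* = \mu + e^{-\mu}}.
#'
#' @param trace A \code{netsi_trace} from \code{\link{run_mwg}} (or any data
#'   frame with \code{beta} and \code{mu} columns).
#' @return Numeric vector of per-draw \code{alpha} values.
#' @export
#' @examples
#' alpha_trace(data.frame(beta = 0.4, mu = 6)) # 2.401
alpha_trace <- function(trace) {
  d <- if (inherits(trace, "netsi_trace")) trace$draws else as.data.frame(trace)
  if (nrow(d) == 0L) stop("empty trace")
  d$beta * mu_star(d$mu)
}

#' Posterior summary of a sampler trace
#'
#' Posterior means, standard deviations, the correlation between
#' \code{beta} and the connectivity summary (\code{mu*} for the PA model,
#' \code{p} for the BRG model), acceptance rates, and the edge-inclusion
#' probabilities.
#'
#' @param trace A \code{netsi_trace}.
#' @return A list of class \code{netsi_summary} with elements \code{table}
#'   (data frame of means and SDs), \code{correlation}, \code{acceptance}
#'   and \code{edge_prob}.
#' @export
summarize_trace <- function(trace) {
  if (!inherits(trace, "netsi_trace")) stop("'trace' must be a netsi_trace")
  d <- trace$draws
  if (nrow(d) == 0L) stop("empty trace")
  msd <- function(v) c(mean = mean(v), sd = stats::sd(v))
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  if (trace$model == "pa") {
    al <- alpha_trace(trace)
    tab <- rbind(beta = msd(d$beta), mu = msd(d$mu), gamma = msd(d$gamma),
                 alpha = msd(al))
    corr <- c(beta_mustar = safe_cor(d$beta, mu_star(d$mu)),
              beta_mu = safe_cor(d$beta, d$mu),
              beta_gamma = safe_cor(d$beta, d$gamma))
  } else {
    tab <- rbind(beta = msd(d$beta), p = msd(d$p))
    corr <- c(beta_p = safe_cor(d$beta, d$p))
  }
  structure(list(model = trace$model, m = trace$m,
                 table = as.data.frame(tab), correlation = corr,
                 acceptance = trace$acceptance,
                 edge_prob = trace$edge_prob),
            class = "netsi_summary")
}

#' @export
summary.netsi_trace <- function(object, ...) summarize_trace(object)

#' @export
print.netsi_summary <- function(x, ...) {
  cat("Posterior summary (", x$model, " model, m = ", x$m, ")\n", sep = "")
  print(round(x$table, 4))
  cat("correlations:\n")
  print(round(x$correlation, 3))
  rates <- vapply(x$acceptance, function(a) a[["rate"]], numeric(1L))
  cat("acceptance rates:\n")
  print(round(rates, 3))
  invisible(x)
}

#' Upper tail of the Bernoulli-random-graph degree distribution
#'
#' Under a Bernoulli random graph each node's degree is Binomial with
#' \code{n} trials and success probability \code{mean_degree / n}.  Returns
#' \eqn{P(X \ge k)} through the numerically stable survival function.
#'
#' @param n Number of potential neighbours (population size minus one).
#' @param mean_degree Expected degree, in \code{(0, n)}.
#' @param k Degree threshold, \code{0 <= k <= n}.
#' @return Tail probability.
#' @export
#' @examples
#' binomial_degree_tail(334, 2.158, 18)
binomial_degree_tail <- function(n, mean_degree, k) {
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1")
  if (mean_degree <= 0 || mean_degree >= n)
    stop("'mean_degree' must lie in (0, n)")
  if (k < 0 || k > n) stop("'k' must lie in 0..n")
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, mean_degree / n, lower.tail = FALSE)
}
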