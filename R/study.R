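#' Run one simulation-study cell
#'
#' Simulates a preferential-attachment network and an SI epidemic at the
#' given truth, optionally reveals part of the graph, fits the model by
#' MCMC and returns one row of posterior summaries.
#'
#' @param m Population size.
#' @param beta,mu,gamma True parameter values for the simulation.
#' @param proportion Fraction of non-tree potential pairs revealed (0 = only
#'   the transmission tree is known, 1 = the whole graph is known).
#' @param estimate_gamma Estimate \code{gamma} (otherwise fixed at 0).
#' @param config A \code{netsi_config}; its seed governs both the
#'   simulation and the chain.
#' @param priors A \code{netsi_priors}.
#' @return One-row data frame with the truth, posterior means/SDs of
#'   \code{beta}, \code{mu}, \code{gamma}, \code{alpha}, and the
#'   \code{beta}-\code{mu*} correlation.
#' @export
study_cell <- function(m, beta, mu, gamma = 0, proportion = 0,
                       estimate_gamma = FALSE,
                       config = mcmc_config(), priors = prior_spec()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  net <- generate_pa_network(m, pa_params(mu, gamma))
  ep <- simulate_si(net$graph, beta)
  g_ep <- relabel_graph(net$graph, ep)
  obs <- make_observation(g_ep, ep, proportion)
  cfg <- config
  cfg$gamma_fixed <- !estimate_gamma
  tr <- run_mwg(ep, priors, cfg, obs = obs)
  s <- summarize_trace(tr)
  data.frame(m = m, beta_true = beta, mu_true = mu, gamma_true = gamma,
             proportion = proportion,
             alpha_true = beta * mu_star(mu),
             beta_mean = s$table["beta", "mean"], beta_sd = s$table["beta", "sd"],
             mu_mean = s$table["mu", "mean"], mu_sd = s$table["mu", "sd"],
             gamma_mean = s$table["gamma", "mean"],
             gamma_sd = s$table["gamma", "sd"],
             alpha_mean = s$table["alpha", "mean"],
             alpha_sd = s$table["alpha", "sd"],
             corr_beta_mustar = unname(s$correlation["beta_mustar"]))
}

#' Parameter-recovery study over a (mu, gamma) grid
#'
#' The first simulation study: a factorial grid of true \code{mu} and
#' \code{gamma} values at fixed \code{m} and \code{beta}, with the graph
#' latent and \code{gamma} estimated.  The returned table is the tabular
#' analogue of plotting each true value against its posterior.
#'
#' @param m Population size (default 70).
#' @param beta True infection rate (default 0.4).
#' @param mu,gamma Vectors of true values forming the grid.
#' @param config A \code{netsi_config} (its seed is offset per cell).
#' @param priors A \code{netsi_priors}.
#' @return Data frame with one row per grid cell.
#' @export
run_study1 <- function(m = 70, beta = 0.4, mu = c(4, 6, 8, 10),
                       gamma = c(0, 0.2, 0.5, 0.8, 1),
                       config = mcmc_config(), priors = prior_spec()) {
  grid <- expand.grid(mu = mu, gamma = gamma)
  out <- NULL
  for (r in seq_len(nrow(grid))) {
    cfg <- config
    if (!is.null(cfg$seed)) cfg$seed <- cfg$seed + r - 1L
    out <- rbind(out, study_cell(m, beta, grid$mu[r], grid$gamma[r],
                                 proportion = 0, estimate_gamma = TRUE,
                                 config = cfg, priors = priors))
  }
  out
}

#' Recovery study over population size and graph-observation proportion
#'
#' The second simulation study: \code{gamma} is fixed at 0 and the grid
#' varies \code{m}, true \code{mu} and the proportion of the graph revealed
#' in addition to the transmission tree.  The posterior of \code{mu}
#' converges towards its true value as the proportion grows.
#'
#' @param m Vector of population sizes.
#' @param beta True infection rate.
#' @param mu Vector of true \code{mu} values.
#' @param proportions Vector of revealed proportions.
#' @param config A \code{netsi_config} (seed offset per cell).
#' @param priors A \code{netsi_priors}.
#' @return Data frame with one row per grid cell.
#' @export
run_study2 <- function(m = c(30, 50, 70), beta = 0.4, mu = c(4, 6, 8, 10),
                       proportions = c(0, 0.25, 0.5, 1),
                       config = mcmc_config(), priors = prior_spec()) {
  grid <- expand.grid(m = m, mu = mu, proportion = proportions)
  out <- NULL
  for (r in seq_len(nrow(grid))) {
    cfg <- config
    if (!is.null(cfg$seed)) cfg$seed <- cfg$seed + r - 1L
    out <- rbind(out, study_cell(grid$m[r], beta, grid$mu[r], gamma = 0,
                                 proportion = grid$proportion[r],
                                 estimate_gamma = FALSE,
                                 config = cfg, priors = priors))
  }
  out
}
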