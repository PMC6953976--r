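test_that("log_posterior composes the likelihood and prior terms", {
  ep <- epidemic(c(0, 1, 2), c(1, 1))
  pri <- prior_spec()
  st <- list(beta = 0.5, mu = 2, gamma = 0, order = 1:3,
             graph = graph_triangle())
  lp <- log_posterior(st, ep, pri)
  expect_equal(lp,
               log_tree_given_graph(ep, st$graph) +
                 log_times_given_graph(ep, st$graph, 0.5) +
                 log_graph_given_order(st$graph, 1:3, pa_params(2, 0)) +
                 dgamma(0.5, 1, 0.001, log = TRUE) +
                 dgamma(2, 1, 0.001, log = TRUE))
  # a missing tree edge kills the posterior
  st$graph <- contact_graph(3, rbind(c(1, 2), c(2, 3)))
  expect_identical(log_posterior(st, ep, pri), -Inf)
})

test_that("m = 2 posterior reduces to the conjugate gamma form", {
  ep <- epidemic(c(0, 2.5), 1L)
  g <- contact_graph(2, rbind(c(1, 2)))
  st <- list(beta = 0.7, mu = 1, gamma = 0, order = 1:2, graph = g)
  # graph term is zero for the initial dyad, so the posterior in beta is
  # Gamma(a + 1, b + t2) up to the mu prior constant
  lp <- log_posterior(st, ep, prior_spec())
  expect_equal(lp, log(0.7) - 0.7 * 2.5 +
                 dgamma(0.7, 1, 0.001, log = TRUE) +
                 dgamma(1, 1, 0.001, log = TRUE))
})

test_that("time origin does not matter (only gaps enter the density)", {
  ep1 <- epidemic(c(0, 1, 3), c(1, 2))
  g <- graph_triangle()
  # shifting all times by a constant leaves every exposure unchanged
  expect_equal(total_exposure(ep1, g),
               sum(c(1, 3, 2))) # pairwise gaps 1, 3, 2
  expect_equal(log_times_given_graph(ep1, g, 0.8),
               2 * log(0.8) - 0.8 * total_exposure(ep1, g))
})

test_that("beta Gibbs draws follow the conjugate gamma", {
  set.seed(1)
  ep <- epidemic(c(0, 1, 3), c(1, 2))
  st <- list(beta = 1, mu = 1, gamma = 0, order = 1:3,
             graph = graph_triangle())
  E <- total_exposure(ep, st$graph)
  pri <- prior_spec()
  draws <- replicate(4e3, update_beta(st, ep, pri))
  expect_equal(E, 6)
  expect_lt(abs(mean(draws) - 3 / (0.001 + E)), 4 * sd(draws) / sqrt(4e3))
  expect_gt(ks.test(draws, pgamma, 3, 0.001 + E)$p.value, 1e-3)
  # worked value: E = 4 gives posterior Gamma(3, 4.001) with mean 0.74981
  expect_equal(3 / 4.001, 0.74981, tolerance = 1e-5)
})

test_that("mu random walk rejects non-positive proposals and targets mu", {
  set.seed(2)
  st <- list(beta = 1, mu = 0.05, gamma = 0, order = 1:3,
             graph = graph_triangle())
  ep <- epidemic(c(0, 1, 2), c(1, 1))
  # with a tiny current mu, huge-sd proposals frequently go negative and
  # must be rejected without error
  out <- replicate(200, update_mu(st, ep, proposal_sd = 10)$mu)
  expect_true(all(out > 0))
})

test_that("gamma update respects the unit interval and the fixed flag", {
  st <- list(beta = 1, mu = 2, gamma = 0.5, order = 1:3,
             graph = graph_triangle())
  ep <- epidemic(c(0, 1, 2), c(1, 1))
  expect_error(update_gamma(st, ep, gamma_fixed = TRUE), "fixed")
  set.seed(3)
  out <- replicate(200, update_gamma(st, ep, proposal_sd = 5)$gamma)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("sigma transpositions leave the complete graph uniform", {
  # all 6 entry orders of the triangle have equal graph probability
  set.seed(4)
  st <- list(beta = 1, mu = 2, gamma = 0, order = network_order(1:3),
             graph = graph_triangle())
  ep <- epidemic(c(0, 1, 2), c(1, 1))
  counts <- integer(6)
  keys <- vapply(all_permutations(1:3), paste, "", collapse = "")
  for (it in 1:4000) {
    st$order <- update_sigma(st, ep)$order
    k <- match(paste(st$order, collapse = ""), keys)
    counts[k] <- counts[k] + 1L
  }
  # consecutive states are dependent, so compare frequencies with a margin
  # rather than an iid goodness-of-fit statistic
  expect_true(all(abs(counts / 4000 - 1 / 6) < 0.04))
})

test_that("edge sweep targets the exact posterior on the free pair", {
  set.seed(5)
  ep <- path_epidemic3()
  st <- list(beta = 0.5, mu = 2, gamma = 0, order = network_order(1:3),
             graph = tree_subgraph(ep))
  pri <- prior_spec()
  # conditional odds of the extra edge given (beta, mu, sigma): ratio of
  # the three posterior factors, computed directly
  g1 <- graph_triangle()
  g0 <- tree_subgraph(ep)
  lodds <- (log_tree_given_graph(ep, g1) + log_times_given_graph(ep, g1, 0.5) +
              log_graph_given_order(g1, 1:3, pa_params(2, 0))) -
    (log_tree_given_graph(ep, g0) + log_times_given_graph(ep, g0, 0.5) +
       log_graph_given_order(g0, 1:3, pa_params(2, 0)))
  p1 <- 1 / (1 + exp(-lodds))
  hits <- 0
  for (it in 1:4000) {
    st$graph <- update_edges(st, ep, pri)$graph
    hits <- hits + st$graph$adj[1, 3]
  }
  expect_lt(abs(hits / 4000 - p1), 0.05)
})

test_that("partial edge scans and pooled chains keep the contract", {
  set.seed(10)
  net <- generate_pa_network(10, pa_params(2, 0))
  ep <- simulate_si(net$graph, 0.5)
  cfg <- mcmc_config(n_iter = 300, n_burnin = 100, seed = 3,
                     edges_per_iter = 3L, sigma_moves_per_iter = 2L)
  tr <- run_mwg(ep, config = cfg, chains = 2L)
  expect_equal(sort(unique(tr$draws$chain)), 1:2)
  expect_equal(nrow(tr$draws), 2L * 200L)
  tree <- tree_subgraph(ep)$adj[cbind(tr$edge_prob$i, tr$edge_prob$j)]
  expect_true(all(tr$edge_prob$prob[tree] == 1))
  expect_true(all(tr$edge_prob$prob >= 0 & tr$edge_prob$prob <= 1))
})

test_that("the sampler is deterministic given a seed", {
  ep <- path_epidemic3()
  cfg <- mcmc_config(n_iter = 400, n_burnin = 100, seed = 9)
  t1 <- run_mwg(ep, config = cfg)
  t2 <- run_mwg(ep, config = cfg)
  expect_identical(t1$draws, t2$draws)
  expect_identical(t1$edge_prob, t2$edge_prob)
})

test_that("known edges are pinned in the trace frequencies", {
  set.seed(6)
  net <- generate_pa_network(12, pa_params(2, 0))
  ep <- simulate_si(net$graph, 0.5)
  g_ep <- relabel_graph(net$graph, ep)
  obs <- make_observation(g_ep, ep, 0.5)
  tr <- run_mwg(ep, config = mcmc_config(n_iter = 400, n_burnin = 100,
                                         seed = 2), obs = obs)
  stat <- obs$status[cbind(tr$edge_prob$i, tr$edge_prob$j)]
  tree <- tree_subgraph(ep)$adj[cbind(tr$edge_prob$i, tr$edge_prob$j)]
  expect_true(all(tr$edge_prob$prob[stat == 1 | tree] == 1))
  expect_true(all(tr$edge_prob$prob[stat == 2] == 0))
  expect_true(all(tr$edge_prob$prob >= 0 & tr$edge_prob$prob <= 1))
})

test_that("compiled incremental caches equal a full R recomputation", {
  set.seed(7)
  net <- generate_pa_network(12, pa_params(2.5, 0.4))
  ep <- simulate_si(net$graph, 0.5)
  for (sd in 1:3) {
    cfg <- mcmc_config(n_iter = 400, n_burnin = 100, seed = sd,
                       gamma_fixed = FALSE, init_gamma = 0.3)
    tr <- run_mwg(ep, config = cfg)
    fin <- tr$final
    orders <- lapply(seq_along(fin$orders),
                     function(i) match(fin$orders[[i]], fin$entry))
    lp_graph <- netsi:::augmented_graph_logdens(fin$adj != 0, fin$entry,
                                                orders, fin$mu, fin$gamma)
    g <- netsi:::as_contact_graph(fin$adj != 0)
    lp_full <- log_tree_given_graph(ep, g) +
      (ep$m - 1) * log(fin$beta) - fin$beta * total_exposure(ep, g) +
      lp_graph +
      dgamma(fin$beta, 1, 0.001, log = TRUE) +
      dgamma(fin$mu, 1, 0.001, log = TRUE)
    expect_equal(tail(tr$draws$logpost, 1), lp_full, tolerance = 1e-9)
    expect_equal(fin$graph_lp, lp_graph, tolerance = 1e-9)
    expect_equal(fin$exposure, total_exposure(ep, g), tolerance = 1e-9)
  }
})

test_that("alpha summarises the per-draw scaled rate", {
  expect_equal(alpha_trace(data.frame(beta = 0.4, mu = 6)), 2.4009915,
               tolerance = 1e-6)
  expect_equal(alpha_trace(data.frame(beta = 0.7, mu = 0)), 0.7)
  expect_equal(alpha_trace(data.frame(beta = 0.4, mu = 4)), 1.60733,
               tolerance = 1e-5)
})

test_that("BRG conjugacies and pinned tree edges hold", {
  # Beta full conditional with a flat prior: |G| = 5 edges among C(5,2)
  # pairs gives Beta(6, 6) with mean one half
  expect_equal((1 + 5) / (1 + 5 + 1 + choose(5, 2) - 5), 0.5)
  set.seed(8)
  net <- generate_pa_network(12, pa_params(2, 0))
  ep <- simulate_si(net$graph, 0.5)
  tr <- run_brg_mwg(ep, config = mcmc_config(n_iter = 500, n_burnin = 100,
                                             seed = 3))
  tree <- tree_subgraph(ep)$adj[cbind(tr$edge_prob$i, tr$edge_prob$j)]
  expect_true(all(tr$edge_prob$prob[tree] == 1))
  expect_true(all(c("beta", "p") %in% names(tr$draws)))
  expect_true(all(tr$draws$p > 0 & tr$draws$p < 1))
})

test_that("BRG posterior of (beta, p) is near-independent when the tree is observed", {
  set.seed(9)
  m <- 50
  # simulate from the BRG model itself: Erdos-Renyi graph, retry until
  # connected
  repeat {
    adj <- matrix(FALSE, m, m)
    up <- upper.tri(adj)
    adj[up] <- runif(sum(up)) < 0.12
    adj <- adj | t(adj)
    g <- netsi:::as_contact_graph(adj)
    ok <- tryCatch({ simulate_si(g, 0.4); TRUE }, error = function(e) FALSE)
    if (ok) break
  }
  ep <- simulate_si(g, 0.4)
  tr <- run_brg_mwg(ep, config = mcmc_config(n_iter = 1500, n_burnin = 500,
                                             seed = 4))
  s <- summarize_trace(tr)
  expect_lt(abs(s$correlation[["beta_p"]]), 0.3)
})

test_that("binomial degree tail matches brute-force summation", {
  expect_equal(binomial_degree_tail(30, 2, 0), 1)
  n <- 334
  p <- 2.158 / n
  brute <- sum(exp(lchoose(n, 18:n) + (18:n) * log(p) +
                     (n - 18:n) * log1p(-p)))
  expect_equal(binomial_degree_tail(n, 2.158, 18), brute,
               tolerance = 1e-12)
  expect_error(binomial_degree_tail(10, 11, 2), "mean_degree")
})

test_that("trace summaries report exact moments and acceptance rates", {
  tr <- structure(list(
    draws = data.frame(chain = 1, iter = 1:3, beta = c(0.2, 0.4, 0.6),
                       mu = c(5, 6, 7), gamma = 0, logpost = 0),
    edge_prob = data.frame(i = 1, j = 2, prob = 1),
    acceptance = list(mu = c(accepted = 25, attempted = 100, rate = 0.25)),
    model = "pa", m = 3), class = "netsi_trace")
  s <- summarize_trace(tr)
  expect_equal(s$table["beta", "mean"], 0.4)
  expect_equal(s$table["beta", "sd"], sd(c(0.2, 0.4, 0.6)))
  expect_equal(s$table["mu", "mean"], 6)
  expect_equal(s$acceptance$mu[["rate"]], 0.25)
  # constant component: zero sd, correlation reported as missing
  expect_equal(s$table["gamma", "sd"], 0)
  expect_true(is.na(s$correlation[["beta_gamma"]]))
})

test_that("m = 2 epidemics are handled as the pure conjugate case", {
  ep <- epidemic(c(0, 1.3), 1L)
  tr <- run_mwg(ep, config = mcmc_config(n_iter = 500, n_burnin = 100,
                                         seed = 5))
  expect_equal(nrow(tr$edge_prob), 1L)
  expect_equal(tr$edge_prob$prob, 1)
  # beta draws match Gamma(a + 1, b + t2)
  expect_gt(ks.test(tr$draws$beta, pgamma, 2, 1.301)$p.value, 1e-4)
})
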