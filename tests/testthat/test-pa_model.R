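test_that("censored Poisson pmf matches its three branches", {
  # mass at 1 collapses to the whole distribution as mu -> 0
  expect_equal(cpois_logpmf(1, 1e-12, 5), 0, tolerance = 1e-10)
  expect_equal(exp(cpois_logpmf(1, 4, 10)), 5 * exp(-4), tolerance = 1e-12)
  # upper-tail branch equals one minus the x = 1 mass at i = 3
  expect_equal(exp(cpois_logpmf(2, 2, 3)), 1 - 3 * exp(-2), tolerance = 1e-12)
  # tail branch cross-checked by naive summation
  naive <- sum(dpois(9:300, 4))
  expect_equal(exp(cpois_logpmf(9, 4, 10)), naive, tolerance = 1e-12)
  expect_identical(cpois_logpmf(0, 2, 5), -Inf)
  expect_identical(cpois_logpmf(5, 2, 5), -Inf)
  expect_error(cpois_logpmf(1.5, 2, 5), "integer")
  expect_error(cpois_logpmf(1, -1, 5), "non-negative")
})

test_that("censored Poisson pmf sums to one and is monotone in mu at x = 1", {
  for (mu in c(0.3, 2, 6, 12)) for (i in c(3, 5, 20, 80))
    expect_equal(sum(exp(cpois_logpmf(1:(i - 1), mu, i))), 1,
                 tolerance = 1e-12)
  p1 <- vapply(seq(0.1, 8, by = 0.5),
               function(mu) exp(cpois_logpmf(1, mu, 30)), numeric(1))
  expect_true(all(diff(p1) < 0))
})

test_that("censored Poisson sampling matches the pmf", {
  set.seed(1)
  expect_true(all(cpois_sample(6, 3, 500) %in% 1:2))
  x <- cpois_sample(6, 50, 1e4)
  exact_mean <- sum((1:49) * exp(cpois_logpmf(1:49, 6, 50)))
  expect_equal(exact_mean, mu_star(6), tolerance = 1e-6) # i large: mean = mu*
  expect_lt(abs(mean(x) - exact_mean), 4 * sd(x) / sqrt(1e4))
  y <- cpois_sample(0.3, 40, 1e4)
  p1 <- exp(-0.3) * 1.3
  expect_lt(abs(mean(y == 1) - p1), 4 * sqrt(p1 * (1 - p1) / 1e4))
})

test_that("mu_star evaluates mu + exp(-mu) with its floor at one", {
  expect_identical(mu_star(0), 1)
  expect_equal(mu_star(6), 6.002479, tolerance = 1e-6)
  expect_error(mu_star(-1), "non-negative")
  mus <- seq(0, 10, by = 0.25)
  expect_true(all(mu_star(mus) >= 1))
})

test_that("attachment weights mix degree and recency components", {
  expect_equal(attachment_weights(c(1, 1), 0), c(1/2, 1/2))
  expect_equal(attachment_weights(c(1, 1), 1), c(1/3, 2/3))
  expect_equal(attachment_weights(c(2, 1, 1), 0), c(1/2, 1/4, 1/4))
  for (gam in c(0, 0.3, 1))
    expect_equal(sum(attachment_weights(c(3, 1, 2, 2), gam)), 1)
  expect_error(attachment_weights(c(0, 0), 0), "all-zero")
})

test_that("successive sampling matches the enumeration oracle", {
  set.seed(2)
  w <- c(0.7, 0.2, 0.1)
  draws <- replicate(2e4, paste(sort(sample_attachment_set(w, 2)),
                                collapse = ""))
  tab <- table(draws) / 2e4
  for (s in list(c(1, 2), c(1, 3), c(2, 3))) {
    p <- enum_set_prob(w, s)
    emp <- tab[[paste(s, collapse = "")]]
    expect_lt(abs(emp - p), 4 * sqrt(p * (1 - p) / 2e4))
    # and the package's subset recursion agrees with the oracle exactly
    expect_equal(exp(attachment_set_logprob(w, s)), p, tolerance = 1e-12)
  }
  expect_equal(sort(sample_attachment_set(c(0.5, 0.5), 2)), 1:2)
  expect_error(sample_attachment_set(c(1, 1), 3), "1..length")
})

test_that("attachment_set_logprob handles larger sets against the oracle", {
  set.seed(3)
  w <- runif(9) + 0.05
  s <- c(2, 4, 5, 8)
  expect_equal(exp(attachment_set_logprob(w, s)), enum_set_prob(w, s),
               tolerance = 1e-12)
  expect_equal(attachment_set_logprob(w, seq_along(w)), 0) # full set: certain
})

test_that("generated networks are connected with supported back-degrees", {
  set.seed(4)
  net2 <- generate_pa_network(2, pa_params(1))
  expect_equal(net2$graph$edge_count, 1L)
  for (rep in 1:10) {
    net <- generate_pa_network(30, pa_params(mu = 3, gamma = 0.5))
    expect_true(order_supported(net$graph, net$order))
    ep <- simulate_si(net$graph, 1) # would error if disconnected
    expect_identical(validate_epidemic(ep), character())
  }
})

test_that("mean edge count matches the exact censored-Poisson means", {
  set.seed(6)
  m <- 70
  exact <- 1 + sum(vapply(3:m, function(i)
    sum((1:(i - 1)) * exp(cpois_logpmf(1:(i - 1), 6, i))), numeric(1)))
  sizes <- replicate(200, generate_pa_network(m, pa_params(6, 0))$graph$edge_count)
  expect_lt(abs(mean(sizes) - exact), 4 * sd(sizes) / sqrt(200))
})

test_that("recency weighting reduces degree inequality", {
  gini <- function(d) {
    d <- sort(d)
    n <- length(d)
    sum((2 * seq_len(n) - n - 1) * d) / (n * sum(d))
  }
  set.seed(7)
  reps <- 100
  g0 <- replicate(reps, {
    net <- generate_pa_network(200, pa_params(4, 0))
    gini(colSums(net$graph$adj))
  })
  g1 <- replicate(reps, {
    net <- generate_pa_network(200, pa_params(4, 1))
    gini(colSums(net$graph$adj))
  })
  expect_lt(mean(g1), mean(g0)) # stochastic ordering of the means
  expect_gt(mean(g0) - mean(g1),
            2 * sqrt(var(g0) / reps + var(g1) / reps))
})

test_that("graph density at m = 3 matches hand evaluation", {
  mu <- 1.7
  pp <- pa_params(mu, 0)
  g <- contact_graph(3, rbind(c(1, 2), c(1, 3)))
  expect_equal(log_graph_given_order(g, 1:3, pp),
               log(exp(-mu) * (1 + mu) / 2), tolerance = 1e-12)
  expect_equal(log_graph_given_order(graph_triangle(), 1:3, pp),
               log(1 - exp(-mu) * (1 + mu)), tolerance = 1e-12)
  # the three supported graphs for sigma = identity sum to one
  g2 <- contact_graph(3, rbind(c(1, 2), c(2, 3)))
  tot <- exp(log_graph_given_order(g, 1:3, pp)) +
    exp(log_graph_given_order(g2, 1:3, pp)) +
    exp(log_graph_given_order(graph_triangle(), 1:3, pp))
  expect_equal(tot, 1, tolerance = 1e-12)
  # unsupported cases
  expect_identical(log_graph_given_order(g2, c(1, 3, 2), pp), -Inf)
})

test_that("graph density normalises over all graphs for m = 3 and 4", {
  for (m in 3:4) for (gam in c(0, 0.5, 1)) for (mu in c(0.5, 6)) {
    tot <- sum(vapply(enum_graphs(m), function(g)
      exp(log_graph_given_order(g, 1:m, pa_params(mu, gam))), numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("simulator graph frequencies match the exact density", {
  set.seed(8)
  m <- 4
  pp <- pa_params(2, 0.3)
  n <- 4000
  key <- replicate(n, {
    e <- graph_edges(generate_pa_network(m, pp, order = 1:m)$graph)
    paste(e[, 1], e[, 2], collapse = ";")
  })
  tab <- table(key) / n
  for (nm in names(sort(tab, decreasing = TRUE))[1:5]) {
    e <- do.call(rbind, lapply(strsplit(strsplit(nm, ";")[[1]], " "),
                               as.integer))
    p <- exp(log_graph_given_order(contact_graph(m, e), 1:m, pp))
    expect_lt(abs(tab[[nm]] - p), 4 * sqrt(p * (1 - p) / n))
  }
})

test_that("augmented (draw-ordered) density marginalises to the exact one", {
  # summing the ordered density over all draw orders of every attachment
  # set recovers log_graph_given_order
  set.seed(9)
  net <- generate_pa_network(5, pa_params(2, 0.4))
  g <- net$graph
  sig <- as.integer(net$order)
  pp <- pa_params(1.3, 0.4)
  sets <- lapply(3:5, function(i)
    which(g$adj[sig[i], sig[seq_len(i - 1)]]))
  tot <- 0
  for (o3 in all_permutations(sets[[1]]))
    for (o4 in all_permutations(sets[[2]]))
      for (o5 in all_permutations(sets[[3]])) {
        orders <- c(list(NULL, NULL), list(o3, o4, o5))
        tot <- tot + exp(netsi:::augmented_graph_logdens(
          g$adj, sig, orders, pp$mu, pp$gamma))
      }
  expect_equal(log(tot), log_graph_given_order(g, sig, pp),
               tolerance = 1e-10)
})
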