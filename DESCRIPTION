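Package: netsi
Title: Latent Preferential-Attachment Network SI Epidemic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and fully Bayesian inference for susceptible-infectious
    (SI) epidemics spreading over a latent social network generated by a
    modified preferential-attachment mechanism with a censored-Poisson
    number of new edges per node. Given the infection times and the
    transmission tree of a completely observed epidemic, a
    Metropolis-within-Gibbs sampler jointly infers the per-edge infection
    rate, the network parameters, the order in which nodes entered the
    network, and the posterior inclusion probability of every potential edge
    of the unobserved contact graph. A Bernoulli-random-graph comparison
    model, partial knowledge of the contact graph, posterior-predictive
    cumulative-incidence simulation, and a simulation-study harness are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
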