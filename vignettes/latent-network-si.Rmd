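---
title: "Latent-network SI epidemics: model, likelihood and sampler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-network SI epidemics: model, likelihood and sampler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsi)
```

## The model

`netsi` fits a susceptible-infectious (SI) epidemic that spreads over a
latent social network.  The data for one epidemic of size $m$ are the
shifted infection times $\tilde I_1 = 0 < \tilde I_2 < \dots < \tilde I_m$
(nodes are labelled in infection order) and the transmission tree $P$
recording who infected whom.  The contact network $G$ — an undirected
simple graph on the same nodes — is usually unobserved and is the main
inferential target, summarised by posterior edge-inclusion probabilities.

**Network component.**  $G$ is modelled by a modified preferential-
attachment (PA) growth process.  Nodes enter the network one at a time in
an unknown order $\sigma$ (a uniform prior over permutations; the entry
order is distinct from the infection order).  The first two entrants form
a connected dyad.  The $i$-th entrant ($i \ge 3$) brings $X_i$ new edges,
where $X_i$ follows a *censored* Poisson distribution with parameter
$\mu$: the Poisson mass at 0 is moved to 1 (every entrant attaches at
least once, keeping the graph connected) and the tail at and beyond $i-1$
is lumped at $i - 1$ (an entrant cannot attach to more nodes than exist).
The $X_i$ endpoints are drawn without replacement, one at a time with
renormalisation, with weight on existing node $j$

$$w_j = (1-\gamma)\,\frac{d_j}{\sum_l d_l} + \gamma\,\frac{j}{\sum_l l},$$

a mixture of the classical degree-proportional PA rule and a recency term;
$\gamma \in [0,1]$ controls how strongly attachment favours high-degree
nodes ($\gamma = 0$ is pure PA; larger $\gamma$ flattens the degree
distribution, which `generate_pa_network()` reproduces as a drop in the
degree Gini coefficient).  For large networks the mean number of new edges
per entrant is $\mu^* = \mu + e^{-\mu}$ (`mu_star()`), the model's natural
measure of average connectivity.

**Epidemic component.**  Given $G$, each edge between an infected and a
susceptible node carries an independent exponential clock with rate
$\beta$; infections occur at the minimum clock and the epidemic runs until
the whole (connected) graph is infected.  This yields three likelihood
factors: the tree probability (each newly infected node is uniformly
infected by one of its earlier-infected neighbours), the times density
$\beta^{m-1}\exp(-\beta E)$ with $E$ the total edge exposure
$\sum_{(i,j) \in G} (\tilde I_j - \tilde I_i)$, and the graph probability
given the entry order.  Because only time *gaps* enter $E$, the time
origin is irrelevant; times carry whatever unit the input uses (days in
typical applications) and $\beta$ is per unit time per edge.  Tied
infection times have probability zero under the continuous-time model and
are rejected as invalid input rather than jittered.

**Priors.**  $\beta$ and $\mu$ carry vague Gamma(1, 0.001) priors,
$\gamma$ a Uniform(0, 1), $\sigma$ uniform over permutations, and (in the
Bernoulli-random-graph comparison model) the edge probability $p$ a
Beta(1, 1).  All are configurable through `prior_spec()`.

## The graph density: exact set probabilities

The probability that successive weighted sampling without replacement
produces a given unordered attachment set has no closed form: it is a sum
over all draw orders.  `attachment_set_logprob()` evaluates it exactly by
a subset recursion (all terms positive, machine-precision accurate,
$O(2^x)$ cost for a set of size $x$, capped at size 16), and
`log_graph_given_order()` assembles the exact graph log-probability from
the censored-Poisson factors and these set probabilities.  Two properties
are verified in the test suite: summing `exp(log_graph_given_order())`
over *all* graphs on 3 and 4 nodes gives 1 to $10^{-10}$ for a grid of
$(\mu, \gamma)$, and simulated graph frequencies from
`generate_pa_network()` match the density within Monte-Carlo error.  A
compact closed-form product for the selection probabilities is sometimes
quoted for this class of models conditional on a canonical draw order; it
does not normalise over sets of a fixed size (we verified a sum of 1.4 on
a three-candidate example), so this package derives everything from the
constructive sampling definition instead.

## The sampler: Metropolis-within-Gibbs with latent draw orders

The exact set probability is too expensive to recompute inside per-edge
Metropolis sweeps ($O(2^x)$ per entry step).  `run_mwg()` therefore
targets an *augmented* posterior that keeps the draw order of every
attachment set as a latent variable.  The per-step ordered
successive-sampling density costs only $O(x)$, and marginalising the
orders recovers the exact posterior over $(\beta, \mu, \gamma, \sigma,
G)$ — the augmentation changes nothing but the computational cost.  The
test suite confirms this end to end: on 3-node epidemics the sampled
edge-inclusion probability agrees with brute-force enumeration plus
numerical integration of the exact density.

One iteration updates, in order:

* **$\beta$** by its conjugate Gibbs draw
  $\mathrm{Gamma}(a_\beta + m - 1,\; b_\beta + E)$.
* **$\mu$** by Gaussian random-walk Metropolis (only the censored-Poisson
  factors and the prior enter the ratio; non-positive proposals are
  rejected).  During burn-in only, the proposal standard deviation is
  adapted in batches of 50 towards acceptance 0.25, multiplying by
  $\exp\{(\hat a - 0.25)/\sqrt{b}\}$ after batch $b$; the post-burn-in
  kernel is fixed so the kept chain is Markov.
* **$\gamma$** likewise on its natural scale with rejection outside
  $[0,1]$ (a logit-scale walk would also be valid; the natural scale keeps
  the uniform prior trivially correct).  By default $\gamma$ is *fixed at
  0*: a single epidemic does not identify it, so the default model is the
  pure PA rule, with estimation retained as an option.
* **$\sigma$** by uniformly random transpositions (default $m$ per
  iteration).  A transposition changes which attachment sets exist between
  the two swapped positions; the move proposes uniformly random draw
  orders for the changed sets (with the matching factorial proposal
  correction) and is auto-rejected whenever the graph cannot be grown
  under the proposed order.  Any irreducible symmetric proposal on
  permutations is valid; transpositions are chosen for simplicity and
  locality.
* **the free potential edges**, each proposed once per iteration in a
  freshly shuffled order (a cheaper partial scan is available through
  `edges_per_iter`).  Removing an edge deletes its endpoint from one draw
  order; adding one inserts the endpoint at a uniformly chosen slot, with
  the slot-count Metropolis correction.  Pairs fixed by the transmission
  tree or by a partial observation (`make_observation()`,
  `graph_observation()`) are never proposed, so their trace frequencies
  are exactly 1 or 0.  All likelihood changes are computed incrementally
  (the times factor changes by $\mp\beta$ times one edge exposure, the
  tree factor through one neighbour count, the graph factor from the
  later endpoint's entry step onward); equality of the incremental caches
  with a full recomputation is unit-tested.
* **draw-order shuffles**, one Metropolis transposition inside each
  attachment set per iteration, which mix the latent orders.

Initialisation uses $\sigma =$ identity and $G =$ the transmission tree
plus any known-present pairs — a state that always has finite posterior
(every node's infector precedes it).  $\beta$ starts at the
method-of-moments value $(m-1)/E$ on the initial graph and $\mu$ at 1 to
shorten burn-in; both are overridable, and any finite-posterior start is
valid.  For $m = 2$ the graph and order are fixed and the posterior
reduces to the conjugate $\beta$ update.  A single seeded generator
drives each chain with a fixed draw order, so runs are bit-reproducible;
multiple chains use consecutive seeds and are pooled after burn-in.

## Identifiability and the network-scaled rate

With the graph latent, $\beta$ and the connectivity are not separately
identifiable: a denser network with a slower rate explains the data as
well as a sparser, faster one, producing a posterior ridge along
$\beta\,\mu^* \approx$ constant.  The product
$\alpha = \beta\,\mu^*$ (`alpha_trace()`) — the *network-scaled epidemic
rate* — is what the data do identify, and it is the quantity to compare
across epidemics.  The package's study harness reproduces this pattern at
reduced scale: posterior means of $\mu$ show no association with the true
$\mu$ when only the tree is known, $\alpha$ is recovered regardless, and
revealing a growing fraction of the true graph (`run_study2()`) shrinks
the error in $\mu$ monotonically.

## The synthetic-data generator

`generate_pa_network()` + `simulate_si()` *are* the model, so simulated
data exercise exactly the assumptions the sampler makes: one index case,
a fully observed epidemic (every node infected, no right-censoring),
exact infection times, a correct transmission tree, and a static network
formed before the epidemic.  Real contact data violate several of these
(unobserved non-participants, measurement error in times, evolving
networks, non-Markovian transmission), so passing the recovery studies
demonstrates the correctness of the inference machinery, not the adequacy
of the model for any particular data set.  Defaults mirror the simulation
studies: $\beta = 0.4$, $\mu \in \{4, 6, 8, 10\}$,
$\gamma \in \{0, 0.2, 0.5, 0.8, 1\}$, $m \in \{30, 50, 70\}$, revealed
proportions $\{0, 0.25, 0.5, 1\}$.

## Problem sizes and numerical choices

The package's study-scale defaults are 20,000 iterations with 10,000
burn-in ("full", matching the published studies) and a 1/10-scale "mini"
preset; the recovery checks in the test suite use 4,000-5,000 iterations
with 1,500-2,000 burn-in at $m = 50$-$70$, sizes chosen so the whole
suite runs in minutes while leaving the qualitative conclusions stable.
Numerical details worth knowing:

* the censored-Poisson tail is computed through the Poisson survival
  function (regularised incomplete gamma), never by naive summation;
* $\mu = 0$ is outside the parameter space (`pa_params()` requires
  $\mu > 0$) but `cpois_logpmf()` accepts the degenerate limit for
  testing;
* exact set probabilities are capped at sets of size 16 (the MCMC never
  needs them; they are a user-facing and testing facility);
* `update_*()` R-level functions mirror each sampler block against the
  exact density for small problems and are the reference implementations
  the compiled sampler is tested against.

## Limitations

Only SI dynamics (no recovery), a single epidemic per network, one global
rate $\beta$, and complete observation of infection times and tree are
supported.  The acceptance rate of entry-order transpositions is high at
$\gamma = 0$ because many orders are near-equivalent; this is harmless
but means $\sigma$-acceptance is not a useful convergence diagnostic.
Model-choice machinery (marginal likelihoods, information criteria) is
deliberately out of scope; the Bernoulli-random-graph model is provided
for the degree-tail and posterior-shape comparisons, not for formal
selection.
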