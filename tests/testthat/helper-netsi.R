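# Shared fixtures, built in code.

path_epidemic3 <- function(times = c(0, 0.8, 2.1)) {
  # tree is the path 1-2-3, leaving (1, 3) as the only free pair
  epidemic(times, c(1, 2))
}

graph_path3 <- function() contact_graph(3, rbind(c(1, 2), c(2, 3)))
graph_triangle <- function() contact_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(k)
    lapply(all_permutations(v[-k]), function(r) c(v[k], r))))
}

# Independent successive-sampling set probability: explicit sum over all
# draw orders (used as the oracle for the package's subset recursion).
enum_set_prob <- function(w, set) {
  w <- w / sum(w)
  tot <- 0
  for (o in all_permutations(set)) {
    pr <- 1
    rem <- 1
    for (j in o) {
      pr <- pr * w[j] / rem
      rem <- rem - w[j]
    }
    tot <- tot + pr
  }
  tot
}

# All simple graphs on m nodes as netsi_graph objects.
enum_graphs <- function(m) {
  pairs <- t(utils::combn(m, 2))
  lapply(0:(2^nrow(pairs) - 1L), function(code) {
    sel <- bitwAnd(code, bitwShiftL(1L, seq_len(nrow(pairs)) - 1L)) > 0L
    contact_graph(m, pairs[sel, , drop = FALSE])
  })
}
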