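# Independent oracles used to validate production code paths.

# direct O(N*K) autocorrelation sum
acf_direct <- function(v, max_lag, mode = "raw") {
  if (mode == "mean-removed") v <- v - mean(v)
  n <- length(v)
  vapply(0:max_lag, function(k) sum(v[1:(n - k)] * v[(1 + k):n]) / (n - k), 0)
}

# union-find connected components (oracle for igraph-based clustering)
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      ri <- find(edges[k, 1]); rj <- find(edges[k, 2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), function(i) find(i), 0L)
}

# brute-force minimum heavy-atom distance between two molecules
brute_min_dist <- function(a, b, L) {
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- a[i, ] - b[j, ]
    d <- d - L * round(d / L)
    best <- min(best, sum(d^2))
  }
  sqrt(best)
}

# simple exponential-decay fit on log scale (oracle for relaxation times);
# restricted to the upper part of the decay where log-noise is benign
fit_exp_tau <- function(t, y) {
  keep <- y > 0.2
  unname(-1 / coef(stats::lm(log(y[keep]) ~ t[keep]))[2])
}

# shared heavy fixture: pooled RDF of a dilute sticky-sphere crowd
# (computed once per test run; used by the colloid and models suites)
.fixtures <- new.env(parent = emptyenv())

sticky_rdf_fixture <- function() {
  if (!is.null(.fixtures$sticky_rdf)) return(.fixtures$sticky_rdf)
  cfg <- crowd_config(n_molecules = 60, radius = 10, D0 = 100, dt = 2e-4,
                      n_steps = 2.5e5, phi = 0.01,
                      pair_potential = "square-well", epsilon = 1.75,
                      seed = 1, thin = 50, n_equil = 8e4)
  rdfs <- lapply(1:5, function(s) {
    cfg$seed <- s
    com_rdf(simulate_brownian_crowd(cfg), bin_width = 0.5, r_max = 40)
  })
  g_pool <- Reduce(`+`, lapply(rdfs, function(r) r$g)) / length(rdfs)
  cfg$seed <- 99
  gt <- simulate_brownian_crowd(
    crowd_config(n_molecules = 2, radius = 10, D0 = 100, dt = 2e-4,
                 n_steps = 10, box_edge = cfg$box_edge,
                 pair_potential = "square-well", epsilon = 1.75,
                 seed = 1))$ground_truth
  .fixtures$sticky_rdf <- list(
    rdf = data.frame(r = rdfs[[1]]$r, g = g_pool),
    per_seed = rdfs, config = cfg, ground_truth = gt)
  .fixtures$sticky_rdf
}
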