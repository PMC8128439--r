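# Shared fixture builders; everything is generated in code.

# Dirichlet-style random split parameters for the N1 engine: (alpha1,
# alpha2, A12) drawn from the flat simplex, branch fractions uniform.
random_split_params <- function() {
  g <- stats::rgamma(3, shape = 1)
  w <- g / sum(g)
  split_params(
    alpha1 = w[1], alpha2 = w[2],
    alpha3 = stats::runif(1), alpha4 = stats::runif(1),
    alpha5 = stats::runif(1), alpha6 = stats::runif(1)
  )
}

# Minimal three-node chain: signal -> kinase -> output.
chain_topology <- function() {
  network_topology(
    nodes = tibble::tibble(
      id = 1:3,
      label = c("signal", "K", "OUT"),
      role = c("source", "kinase", "output")
    ),
    edges = tibble::tibble(
      src = c(1L, 2L), dst = c(2L, 3L),
      fraction_name = c("one", "one"),
      kind = c("pathway", "pathway")
    ),
    splits = list(),
    name = "chain"
  )
}

# Random per-node activity profile in [lo, 1].
random_activity <- function(topology, lo = 0.3) {
  act <- activity_profile(topology)
  kin <- as.character(topology$nodes$id[topology$nodes$role == "kinase"])
  act[kin] <- stats::runif(length(kin), lo, 1)
  act
}
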