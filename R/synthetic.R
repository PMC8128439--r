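#' Sample a random conserved driver-network topology
#'
#' Generates a directed acyclic flow network with one source, one output,
#' `n_pathways` parallel kinase chains, and optional crosstalk edges. The
#' source split and every multi-way branch are drawn from a flat Dirichlet
#' (gamma draws normalized to sum 1), so the outgoing fractions at each
#' node sum to 1 by construction and the sampled network is always
#' conservation-valid. Crosstalk edges run from a kinase to a
#' higher-indexed kinase in another chain (guaranteeing acyclicity), each
#' present independently with probability `crosstalk_density`.
#'
#' Random draws use a stream keyed by `(seed, "topology")`, independent of
#' the readout-noise stream of [simulate_readouts()].
#'
#' @param n_pathways Number of parallel chains (>= 1).
#' @param kinases_per_pathway Chain lengths; a single value or a vector of
#'   length `n_pathways`.
#' @param crosstalk_density Probability of each candidate crosstalk edge,
#'   in \[0, 1\]. 0 yields independent chains (an N2-like network).
#' @param concentration Dirichlet concentration for split sampling
#'   (default 1: uniform over the simplex).
#' @param seed Mandatory integer seed.
#' @return A `network_topology` named `"synthetic"`.
#' @examples
#' random_topology(3, seed = 1)
#' @export
random_topology <- function(n_pathways, kinases_per_pathway = 2,
                            crosstalk_density = 0.3, concentration = 1,
                            seed) {
  if (missing(seed)) stop("seed is mandatory for stochastic output", call. = FALSE)
  stopifnot(n_pathways >= 1, crosstalk_density >= 0, crosstalk_density <= 1,
            concentration > 0)
  lens <- rep_len(as.integer(kinases_per_pathway), n_pathways)
  stopifnot(all(lens >= 1))

  withr::with_seed(derive_seed(seed, "topology"), {
    n_kin <- sum(lens)
    ids <- seq_len(n_kin + 2L)
    source_id <- 1L
    output_id <- n_kin + 2L
    kin_ids <- split(seq_len(n_kin) + 1L,
                     rep(seq_len(n_pathways), lens))

    nodes <- tibble::tibble(
      id = ids,
      label = c("signal",
                unlist(lapply(seq_len(n_pathways), function(p) {
                  paste0("K", p, ".", seq_len(lens[p]))
                })),
                "OUT"),
      role = c("source", rep("kinase", n_kin), "output")
    )

    src <- unname(unlist(lapply(kin_ids, function(chain) c(source_id, chain))))
    dst <- unname(unlist(lapply(kin_ids, function(chain) c(chain, output_id))))
    kind <- rep("pathway", length(src))

    if (crosstalk_density > 0 && n_pathways > 1L) {
      kins <- seq_len(n_kin) + 1L
      pathway_of <- rep(seq_len(n_pathways), lens)
      ok <- outer(kins, kins, `<`) & outer(pathway_of, pathway_of, `!=`)
      idx <- which(ok, arr.ind = TRUE)
      if (nrow(idx)) {
        keep <- stats::runif(nrow(idx)) < crosstalk_density
        src <- c(src, kins[idx[keep, 1L]])
        dst <- c(dst, kins[idx[keep, 2L]])
        kind <- c(kind, rep("crosstalk", sum(keep)))
      }
    }

    fraction_name <- paste0("w", src, "_", dst)
    splits <- list()
    for (s in unique(src)) {
      at <- which(src == s)
      if (length(at) == 1L) {
        fraction_name[at] <- "one"
      } else {
        g <- stats::rgamma(length(at), shape = concentration)
        w <- g / sum(g)
        for (k in seq_along(at)) splits[[fraction_name[at[k]]]] <- w[k]
      }
    }
    network_topology(
      nodes,
      tibble::tibble(src = src, dst = dst,
                     fraction_name = fraction_name, kind = kind),
      splits, name = "synthetic"
    )
  })
}

#' Brute-force flow solution via the node-balance linear system
#'
#' Independent cross-check for [propagate()]: instead of a pass in
#' topological order, assembles the full linear balance system
#' `Y_j = sum_i f_ij * a_i * Y_i` (source fixed at 1) and solves it
#' directly with a dense linear solver. Intended as the test oracle; both
#' routes must agree to tight tolerance on any valid topology.
#'
#' @inheritParams propagate
#' @return A `"flow_state"` tibble with the same shape as [propagate()].
#' @examples
#' flow_oracle(build_n1())
#' @export
flow_oracle <- function(topology, activity = NULL) {
  validate_topology(topology)
  nodes <- topology$nodes
  if (is.null(activity)) activity <- activity_profile(topology)
  act <- rep(1, nrow(nodes))
  names(act) <- as.character(nodes$id)
  act[names(activity)] <- pmin(pmax(activity, 0), 1)

  mass <- topology$edges[topology$edges$kind != "repression", , drop = FALSE]
  frac <- resolve_fractions(mass$fraction_name, topology$splits)

  n <- nrow(nodes)
  pos <- stats::setNames(seq_len(n), as.character(nodes$id))
  A <- diag(n)
  b <- rep(0, n)
  src_row <- pos[as.character(nodes$id[nodes$role == "source"])]
  b[src_row] <- 1
  for (k in seq_len(nrow(mass))) {
    i <- pos[as.character(mass$src[k])]
    j <- pos[as.character(mass$dst[k])]
    if (j == src_row) next
    A[j, i] <- A[j, i] - frac[k] * act[as.character(mass$src[k])]
  }
  inflow <- tryCatch(solve(A, b),
                     error = function(e) stop("singular balance system: ",
                                              conditionMessage(e), call. = FALSE))
  outflow <- act[as.character(nodes$id)] * inflow
  loss <- (1 - act[as.character(nodes$id)]) * inflow

  fs <- tibble::tibble(
    node_id = nodes$id,
    label = nodes$label,
    inflow = unname(inflow),
    outflow = unname(outflow),
    loss = unname(loss)
  )
  class(fs) <- c("flow_state", class(fs))
  attr(fs, "output_flow") <- unname(inflow[pos[as.character(nodes$id[nodes$role == "output"])]])
  attr(fs, "topology") <- topology$name
  fs
}

#' Simulate noisy replicate BACH1 dose-response readouts
#'
#' Emulates the statistical structure of qPCR relative-expression
#' measurements: the model prediction `phi(x)` at each dose is multiplied
#' by independent lognormal noise with median 1 and log-scale standard
#' deviation `noise_sd` for each replicate (relative expression is
#' ratio-scale, so noise is multiplicative). An additive Gaussian
#' alternative is available behind `noise = "gaussian"`. Draws use a
#' stream keyed by `(seed, "readouts")`.
#'
#' @param topology A `network_topology`.
#' @param scen A [scenario()] or preset name.
#' @param doses Dose grid in \[0, 1\].
#' @param n_replicates Replicates per dose (default 3).
#' @param noise_sd Log-scale (or additive) noise standard deviation, >= 0.
#' @param seed Mandatory integer seed.
#' @param noise `"lognormal"` (default) or `"gaussian"`.
#' @param constants Constant set from [mapk_constants()].
#' @return A tibble with columns `dose`, `replicate`, `expression`,
#'   `scenario`, `topology`.
#' @examples
#' simulate_readouts(build_n1(), "meki", seq(0, 1, 0.1), seed = 7)
#' @export
simulate_readouts <- function(topology, scen, doses = seq(0, 1, by = 0.1),
                              n_replicates = 3, noise_sd = 0.05, seed,
                              noise = c("lognormal", "gaussian"),
                              constants = mapk_constants()) {
  if (missing(seed)) stop("seed is mandatory for stochastic output", call. = FALSE)
  noise <- match.arg(noise)
  stopifnot(n_replicates >= 1, noise_sd >= 0)
  curve <- dose_response(topology, scen, doses, constants = constants)

  withr::with_seed(derive_seed(seed, "readouts"), {
    tbl <- tidyr::expand_grid(dose = curve$dose,
                              replicate = seq_len(n_replicates)) |>
      dplyr::left_join(curve[, c("dose", "phi_bach1")], by = "dose")
    eps <- stats::rnorm(nrow(tbl), mean = 0, sd = noise_sd)
    tbl$expression <- if (noise == "lognormal") {
      tbl$phi_bach1 * exp(eps)
    } else {
      tbl$phi_bach1 + eps
    }
    tibble::tibble(
      dose = tbl$dose,
      replicate = as.integer(tbl$replicate),
      expression = tbl$expression,
      scenario = curve$scenario[1],
      topology = curve$topology[1]
    )
  })
}
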