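#' Construct a conserved signal-flow network topology
#'
#' A topology is a directed acyclic graph of kinase nodes through which a
#' normalized stress signal (total input = 1) flows. Each mass-carrying
#' edge carries a named fraction of its source node's outflow; at every
#' node the outgoing fractions sum to 1, so the network conserves signal.
#' Repression edges are modifiers only and carry no mass.
#'
#' @param nodes A data frame with columns `id` (unique positive integers),
#'   `label` (e.g. "RAF", "p38"), and `role` (one of `"source"`,
#'   `"kinase"`, `"output"`; exactly one source and one output).
#' @param edges A data frame with columns `src`, `dst` (node ids),
#'   `fraction_name` (a key into `splits`, or `"one"` for a full-flow
#'   edge), and `kind` (`"pathway"`, `"crosstalk"`, or `"repression"`).
#' @param splits A named list or vector mapping fraction names to values in
#'   \[0, 1\], e.g. the result of [split_params()].
#' @param name Topology name used to tag downstream results.
#' @return An object of class `"network_topology"`.
#' @seealso [build_n1()], [build_n2()], [random_topology()], [propagate()]
#' @export
network_topology <- function(nodes, edges, splits, name = "custom") {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("id", "label", "role") %in% names(nodes)),
            all(c("src", "dst", "fraction_name", "kind") %in% names(edges)))
  topo <- structure(
    list(name = name, nodes = nodes, edges = edges, splits = splits),
    class = "network_topology"
  )
  # validation and the propagation cache (resolved fractions, topological
  # order) share one pass, so construction is cheap enough for large
  # property sweeps
  topo$.cache <- build_validated_cache(nodes, edges, splits)
  topo
}

# internal: run all structural checks and return the propagation cache
build_validated_cache <- function(nodes, edges, splits, tol = 1e-9) {
  if (anyDuplicated(nodes$id)) stop("node ids must be unique", call. = FALSE)
  if (sum(nodes$role == "source") != 1L) {
    stop("topology must have exactly one source node", call. = FALSE)
  }
  if (sum(nodes$role == "output") != 1L) {
    stop("topology must have exactly one output node", call. = FALSE)
  }
  if (!all(edges$kind %in% c("pathway", "crosstalk", "repression"))) {
    stop("edge kind must be pathway, crosstalk or repression", call. = FALSE)
  }
  if (!all(c(edges$src, edges$dst) %in% nodes$id)) {
    stop("edge endpoints must reference declared node ids", call. = FALSE)
  }
  mass <- edges[edges$kind != "repression", , drop = FALSE]
  frac <- resolve_fractions(mass$fraction_name, splits)
  src_chr <- as.character(mass$src)
  dst_chr <- as.character(mass$dst)
  g <- igraph::graph_from_data_frame(
    data.frame(from = src_chr, to = dst_chr),
    vertices = data.frame(name = as.character(nodes$id))
  )
  if (!igraph::is_dag(g)) {
    stop("cycle detected in the mass-carrying subgraph", call. = FALSE)
  }
  out_id <- nodes$id[nodes$role == "output"]
  if (any(mass$src == out_id)) {
    stop("output node must not emit mass flow", call. = FALSE)
  }
  sums <- tapply(frac, src_chr, sum)
  off <- abs(sums - 1) > tol
  if (any(off)) {
    stop("outgoing fractions at node(s) ",
         paste(names(sums)[off], collapse = ", "),
         " do not sum to 1", call. = FALSE)
  }
  silent <- setdiff(nodes$id[nodes$role != "output"], unique(mass$src))
  if (length(silent)) {
    stop("non-output node(s) ", paste(silent, collapse = ", "),
         " have no outgoing mass edge (flow would be lost)", call. = FALSE)
  }
  list(
    src = src_chr,
    dst = dst_chr,
    frac = frac,
    order = igraph::as_ids(igraph::topo_sort(g, mode = "out")),
    out_edges = split(seq_along(src_chr), src_chr)
  )
}

#' Validate a network topology
#'
#' Checks the structural invariants of a conserved flow network: unique
#' node ids, exactly one source and one output, every edge fraction
#' resolving to a value in \[0, 1\], acyclicity of the mass-carrying
#' (pathway/crosstalk) subgraph, and outgoing fractions summing to 1 at
#' every node that emits mass (the output node emits none).
#'
#' @param topology A `network_topology`.
#' @param tol Tolerance on per-node fraction sums.
#' @return The topology, invisibly; errors describe the first violation.
#' @export
validate_topology <- function(topology, tol = 1e-9) {
  build_validated_cache(topology$nodes, topology$edges, topology$splits,
                        tol = tol)
  invisible(topology)
}

# internal: map fraction names to numeric values; "one" is the unit fraction
resolve_fractions <- function(fraction_name, splits) {
  vals <- vapply(fraction_name, function(nm) {
    if (identical(nm, "one")) return(1)
    v <- splits[[nm]]
    if (is.null(v) || is.na(v)) {
      stop("unresolved fraction name '", nm, "'", call. = FALSE)
    }
    as.numeric(v)
  }, numeric(1), USE.NAMES = FALSE)
  if (any(vals < -1e-12 | vals > 1 + 1e-12)) {
    stop("fraction values must lie in [0, 1]", call. = FALSE)
  }
  pmin(pmax(vals, 0), 1)
}

#' Build the crosstalk-containing benchmark topology N1
#'
#' The nine-node stress MAPK driver network of anisomycin-stimulated BM1
#' cells: a stress signal splits across the RAF/MEK/ERK, MLK/JNK and
#' TAOK/p38 pathways, with crosstalk edges MLK->p38, TAOK->JNK, p38->ERK
#' and ERK->JNK, and mass-free repressions TAOK-|ERK and JNK-|ERK. All
#' pathway outputs converge on the BACH1 transcription node.
#'
#' Node ids follow the canonical numbering: 1 signal split, 2 RAF, 3 MEK,
#' 4 ERK, 5 MLK, 6 JNK, 7 TAOK, 8 p38, 9 BACH1 output.
#'
#' @param splits A [split_params()] object.
#' @return A `network_topology` named `"N1"`.
#' @examples
#' n1 <- build_n1()
#' propagate(n1)
#' @export
build_n1 <- function(splits = split_params()) {
  if (!inherits(splits, "split_params")) {
    splits <- do.call(split_params, as.list(splits))
  }
  nodes <- tibble::tibble(
    id = 1:9,
    label = c("signal", "RAF", "MEK", "ERK", "MLK", "JNK", "TAOK", "p38", "BACH1"),
    role = c("source", rep("kinase", 7), "output")
  )
  edges <- tibble::tribble(
    ~src, ~dst, ~fraction_name, ~kind,
    1L, 2L, "alpha1", "pathway",
    1L, 5L, "alpha2", "pathway",
    1L, 7L, "A12",    "pathway",
    2L, 3L, "one",    "pathway",
    3L, 4L, "one",    "pathway",
    5L, 6L, "alpha3", "pathway",
    5L, 8L, "A3",     "crosstalk",
    7L, 8L, "A4",     "pathway",
    7L, 6L, "alpha4", "crosstalk",
    8L, 9L, "alpha5", "pathway",
    8L, 4L, "A5",     "crosstalk",
    4L, 9L, "alpha6", "pathway",
    4L, 6L, "A6",     "crosstalk",
    6L, 9L, "one",    "pathway",
    7L, 4L, "gamma1", "repression",
    6L, 4L, "gamma2", "repression"
  )
  network_topology(nodes, edges, splits, name = "N1")
}

#' Build the crosstalk-free benchmark topology N2
#'
#' Three independent chains signal->RAF->MEK->ERK->BACH1,
#' signal->MLK->JNK->BACH1 and signal->TAOK->p38->BACH1. Implemented with
#' the same engine as [build_n1()] by fixing the branch fractions
#' `alpha3 = 1` (so `A3 = 0`), `alpha4 = 0` (so `A4 = 1`), `alpha5 = 1`
#' and `alpha6 = 1` (so `A5 = A6 = 0`): every crosstalk edge then carries
#' zero flow.
#'
#' @param alpha1,alpha2 Source split fractions of the three chains
#'   (`A12 = 1 - alpha1 - alpha2` goes to the TAOK/p38 chain).
#' @return A `network_topology` named `"N2"`.
#' @examples
#' propagate(build_n2())
#' @export
build_n2 <- function(alpha1 = 0.2, alpha2 = 0.2) {
  topo <- build_n1(split_params(alpha1 = alpha1, alpha2 = alpha2,
                                alpha3 = 1, alpha4 = 0,
                                alpha5 = 1, alpha6 = 1))
  topo$name <- "N2"
  topo
}

#' Per-node activity profile
#'
#' A multiplicative pass-through per node: 1 means untreated, and a value
#' `1 - xi` models a treatment reducing a kinase's capacity to absorb
#' inflow by the fraction `xi`. Values are clamped into \[0, 1\].
#'
#' @param topology A `network_topology`.
#' @param ... Named overrides by node label (e.g. `p38 = 0.7`) or by node
#'   id given as `"3"`.
#' @return A named numeric vector indexed by node id, all entries in
#'   \[0, 1\].
#' @examples
#' activity_profile(build_n1(), MEK = 0.7)
#' @export
activity_profile <- function(topology, ...) {
  nodes <- topology$nodes
  act <- rep(1, nrow(nodes))
  names(act) <- as.character(nodes$id)
  overrides <- list(...)
  for (nm in names(overrides)) {
    id <- if (nm %in% nodes$label) {
      as.character(nodes$id[nodes$label == nm])
    } else if (nm %in% names(act)) {
      nm
    } else {
      stop("unknown node '", nm, "' in activity profile", call. = FALSE)
    }
    act[id] <- overrides[[nm]]
  }
  pmin(pmax(act, 0), 1)
}

#' Propagate the stress signal through a topology
#'
#' Computes the steady-state inflow and outflow at every node by a single
#' pass in topological order: the source emits 1, each mass-carrying edge
#' delivers its fraction of the upstream outflow, and each node's outflow
#' is its inflow scaled by the node's activity. The deficit
#' `(1 - activity) * inflow` is recorded as a node-local loss (the signal
#' a treated kinase fails to absorb). Untreated (all activities 1), the
#' inflow at the output node is exactly 1 by conservation.
#'
#' @param topology A `network_topology`.
#' @param activity Optional [activity_profile()]-style named vector; `NULL`
#'   means untreated.
#' @return A tibble of class `"flow_state"` with columns `node_id`,
#'   `label`, `inflow`, `outflow`, `loss`, and attributes `output_flow`
#'   (inflow at the output node) and `topology` (its name).
#' @examples
#' propagate(build_n1())
#' propagate(build_n1(), activity_profile(build_n1(), MEK = 0.5))
#' @export
propagate <- function(topology, activity = NULL) {
  nodes <- topology$nodes
  cache <- topology$.cache
  if (is.null(cache)) {
    validate_topology(topology)
    mass <- topology$edges[topology$edges$kind != "repression", , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(mass$src), to = as.character(mass$dst)),
      vertices = data.frame(name = as.character(nodes$id))
    )
    cache <- list(
      src = as.character(mass$src),
      dst = as.character(mass$dst),
      frac = resolve_fractions(mass$fraction_name, topology$splits),
      order = igraph::as_ids(igraph::topo_sort(g, mode = "out")),
      out_edges = split(seq_along(mass$src), as.character(mass$src))
    )
  }
  if (is.null(activity)) activity <- activity_profile(topology)
  act <- rep(1, nrow(nodes))
  names(act) <- as.character(nodes$id)
  act[names(activity)] <- pmin(pmax(activity, 0), 1)

  inflow <- stats::setNames(rep(0, nrow(nodes)), as.character(nodes$id))
  src_id <- as.character(nodes$id[nodes$role == "source"])
  inflow[src_id] <- 1
  outflow <- inflow
  for (id in cache$order) {
    outflow[id] <- act[id] * inflow[id]
    for (k in cache$out_edges[[id]]) {
      dst <- cache$dst[k]
      inflow[dst] <- inflow[dst] + cache$frac[k] * outflow[id]
    }
  }
  loss <- (1 - act) * inflow
  out_id <- as.character(nodes$id[nodes$role == "output"])

  fs <- tibble::tibble(
    node_id = nodes$id,
    label = nodes$label,
    inflow = unname(inflow[as.character(nodes$id)]),
    outflow = unname(outflow[as.character(nodes$id)]),
    loss = unname(loss[as.character(nodes$id)])
  )
  class(fs) <- c("flow_state", class(fs))
  attr(fs, "output_flow") <- unname(inflow[out_id])
  attr(fs, "topology") <- topology$name
  fs
}

#' Output flow of a propagated state
#'
#' @param flow A `"flow_state"` as returned by [propagate()].
#' @return The inflow at the output node (relative BACH1 output when
#'   untreated input is 1).
#' @export
output_flow <- function(flow) {
  of <- attr(flow, "output_flow", exact = TRUE)
  if (is.null(of)) stop("not a flow_state: missing output_flow", call. = FALSE)
  of
}

#' Conservation residual of a flow state
#'
#' The network is conservative: the signal reaching the output plus all
#' node-local losses must equal the unit input. Returns the absolute
#' bookkeeping violation `|output_flow + sum(losses) - 1|`, which is 0 for
#' any untreated network and below numerical tolerance for any treated
#' scenario computed by [propagate()].
#'
#' @param flow A `"flow_state"` tibble.
#' @return A single nonnegative number.
#' @examples
#' conservation_residual(propagate(build_n1()))
#' @export
conservation_residual <- function(flow) {
  abs(output_flow(flow) + sum(flow$loss) - 1)
}

# internal: does any crosstalk edge carry nonzero flow?
crosstalk_present <- function(topology) {
  ct <- topology$edges[topology$edges$kind == "crosstalk", , drop = FALSE]
  if (!nrow(ct)) return(FALSE)
  any(resolve_fractions(ct$fraction_name, topology$splits) > 0)
}

# internal: untreated inflow at the node with the given label
untreated_inflow <- function(topology, label) {
  fs <- propagate(topology)
  idx <- fs$label == label
  if (!any(idx)) stop("topology has no node labeled '", label, "'", call. = FALSE)
  fs$inflow[idx]
}

#' @export
print.network_topology <- function(x, ...) {
  mass <- x$edges[x$edges$kind != "repression", , drop = FALSE]
  cat(sprintf("<network_topology '%s'>: %d nodes, %d mass edges (%d crosstalk), %d repression edges\n",
              x$name, nrow(x$nodes), nrow(mass),
              sum(mass$kind == "crosstalk"),
              sum(x$edges$kind == "repression")))
  fracs <- unlist(x$splits[!vapply(x$splits, is.na, logical(1))])
  cat("  splits: ", paste(names(fracs), format(unname(fracs), digits = 4),
                          sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
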