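#' Read and write topology configuration files
#'
#' Topologies are exchanged as JSON documents with three members:
#' `name`, `nodes` (objects with `id`, `label`, `role`), `edges` (objects
#' with `src`, `dst`, `fraction_name`, `kind`) and `splits` (a name-value
#' map; repression strengths may be `null`). Canonical `n1.json` and
#' `n2.json` configs ship with the package under `extdata/`.
#'
#' @param path File path.
#' @return `read_topology()` returns a validated `network_topology`;
#'   `write_topology()` returns `path` invisibly.
#' @examples
#' n1 <- read_topology(system.file("extdata", "n1.json", package = "mapkflow"))
#' @export
read_topology <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  need <- c("name", "nodes", "edges", "splits")
  miss <- setdiff(need, names(doc))
  if (length(miss)) {
    stop("topology config lacks member(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  splits <- lapply(doc$splits, function(v) if (is.null(v)) NA_real_ else as.numeric(v))
  network_topology(doc$nodes, doc$edges, splits, name = doc$name)
}

#' @rdname read_topology
#' @param topology A `network_topology`.
#' @export
write_topology <- function(topology, path) {
  validate_topology(topology)
  splits <- lapply(topology$splits, function(v) {
    if (is.na(v)) NULL else as.numeric(v)
  })
  doc <- list(
    name = topology$name,
    nodes = topology$nodes,
    edges = topology$edges,
    splits = splits
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", pretty = TRUE)
  invisible(path)
}

#' Resolve a topology argument: preset name, file path, or object
#'
#' `"n1"` and `"n2"` resolve to [build_n1()]/[build_n2()] without files;
#' any other character value is treated as a config file path.
#'
#' @param topology A `network_topology`, `"n1"`, `"n2"`, or a path.
#' @return A `network_topology`.
#' @export
resolve_topology <- function(topology) {
  if (inherits(topology, "network_topology")) return(topology)
  if (is.character(topology) && length(topology) == 1L) {
    key <- tolower(topology)
    if (key == "n1") return(build_n1())
    if (key == "n2") return(build_n2())
    if (file.exists(topology)) return(read_topology(topology))
    stop("unknown topology '", topology,
         "': not a preset (n1/n2) and no such file", call. = FALSE)
  }
  stop("topology must be a network_topology, a preset name, or a path",
       call. = FALSE)
}

#' Read a readout table from CSV
#'
#' Expects columns `dose`, `replicate`, `expression` (extra columns pass
#' through). Validation errors name the offending row.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_readouts <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  validate_readouts(tbl)
}

#' Export a flow state, curve or surplus report to CSV
#'
#' Plain `readr::write_csv()` of the tidy table; provided so scripted
#' pipelines have one documented export dialect.
#'
#' @param x A tibble (e.g. `flow_state`, `dose_response_curve`,
#'   `surplus_report`, or a readout table).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_flow_csv <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}
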