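#' Construct a river network
#'
#' A directed acyclic network whose edges point downstream, with edge
#' lengths in kilometres, node coordinates/elevations, and a mapping from
#' sampling locations to nodes. Locations belonging to one river system must
#' be connected (ignoring direction); separate basins may form separate
#' components.
#'
#' @param nodes Data frame with `node_id`, `latitude`, `longitude`,
#'   `elevation_m`.
#' @param edges Data frame with `from`, `to` (downstream direction) and
#'   `length_km` (> 0).
#' @param locations Data frame with `location_id`, `node_id`.
#' @return A list of class `river_network`.
#' @export
river_network <- function(nodes, edges, locations) {
  stopifnot(all(c("node_id") %in% names(nodes)),
            all(c("from", "to", "length_km") %in% names(edges)),
            all(c("location_id", "node_id") %in% names(locations)))
  if (any(edges$length_km <= 0))
    stop("edge lengths must be > 0", call. = FALSE)
  unknown <- setdiff(c(edges$from, edges$to, locations$node_id),
                     nodes$node_id)
  if (length(unknown) > 0)
    stop("edges or locations reference unknown nodes: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  g_dir <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = nodes$node_id))
  if (!igraph::is_dag(g_dir))
    stop("downstream edges must not form directed cycles", call. = FALSE)
  net <- list(nodes = nodes, edges = edges, locations = locations)
  class(net) <- "river_network"
  net
}

# undirected igraph with length weights, vertices named by node id
network_graph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = net$edges$from, to = net$edges$to,
               weight = net$edges$length_km),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$node_id))
}

#' Flow-corrected along-network distances between locations
#'
#' Straight-line or plain along-river distances ignore that moving upstream
#' against the current costs a migrating fish more than drifting downstream.
#' The unique network path from location i to j is decomposed into its
#' downstream length `L_down` and upstream length `L_up` (relative to the
#' direction of travel); the directed cost is `L_down + lambda_up * L_up`
#' and the reported distance is the mean of the two directed costs.
#' `lambda_up = 1` recovers the plain along-network distance.
#'
#' @param network A [river_network()].
#' @param locations Character vector of location ids (default: all mapped).
#' @param lambda_up Upstream travel cost multiplier, >= 1. Default 2.
#' @return A symmetric distance matrix (km-equivalents) over locations.
#' @export
corrected_geo_distance <- function(network, locations = NULL, lambda_up = 2) {
  stopifnot(inherits(network, "river_network"))
  if (lambda_up < 1) stop("lambda_up must be >= 1", call. = FALSE)
  map <- network$locations
  locations <- locations %||% map$location_id
  missing_loc <- setdiff(locations, map$location_id)
  if (length(missing_loc) > 0)
    stop("locations not mapped to the network: ",
         paste(missing_loc, collapse = ", "), call. = FALSE)
  g <- network_graph(network)
  # downstream orientation lookup: "from->to" means from is upstream of to
  down_key <- paste(network$edges$from, network$edges$to, sep = "\r")
  len_key <- setNames(network$edges$length_km, down_key)
  n <- length(locations)
  d <- matrix(0, n, n, dimnames = list(locations, locations))
  node_of <- setNames(map$node_id, map$location_id)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = node_of[locations[i]],
                             to = node_of[locations[j]],
                             output = "vpath"))
    vp <- names(sp$vpath[[1]])
    if (length(vp) == 0)
      stop("locations ", locations[i], " and ", locations[j],
           " are not connected in the network", call. = FALSE)
    l_down <- 0; l_up <- 0  # travelling i -> j
    for (k in seq_len(length(vp) - 1L)) {
      a <- vp[k]; b <- vp[k + 1L]
      if (paste(a, b, sep = "\r") %in% down_key) {
        l_down <- l_down + len_key[[paste(a, b, sep = "\r")]]
      } else {
        l_up <- l_up + len_key[[paste(b, a, sep = "\r")]]
      }
    }
    cost_ij <- l_down + lambda_up * l_up
    cost_ji <- l_up + lambda_up * l_down
    d[i, j] <- d[j, i] <- (cost_ij + cost_ji) / 2
  }
  d
}
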