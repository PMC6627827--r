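# Structural controllability of the directed dependency network: minimal
# driver sets via maximum matching on the bipartite split representation.

net_edges <- function(x) {
  edges <- if (inherits(x, "dependency_network")) x$edges else tibble::as_tibble(x)
  if (!all(c("modulator", "dependent") %in% names(edges))) {
    abort("edges need columns modulator, dependent")
  }
  edges
}

net_nodes <- function(x, edges) {
  if (inherits(x, "dependency_network") && length(x$nodes) > 0) {
    x$nodes
  } else {
    sort(unique(c(edges$modulator, edges$dependent)))
  }
}

#' Bipartite split representation of a directed network
#'
#' Every node `v` becomes an out-copy `v+` and an in-copy `v-`; every
#' directed edge `u -> v` becomes the bipartite edge `(u+, v-)`. A maximum
#' matching of this bipartite graph determines the minimal driver set of the
#' directed network.
#'
#' @param x A `dependency_network` or a data frame of directed edges
#'   (`modulator`, `dependent`).
#' @return A tibble with columns `out_copy`, `in_copy`.
#' @examples
#' bipartite_split(data.frame(modulator = c("a", "b"), dependent = c("b", "c")))
#' @export
bipartite_split <- function(x) {
  edges <- net_edges(x)
  if (nrow(edges) == 0) {
    return(tibble::tibble(out_copy = character(0), in_copy = character(0)))
  }
  tibble::tibble(
    out_copy = paste0(edges$modulator, "+"),
    in_copy = paste0(edges$dependent, "-")
  )
}

#' Maximum matching and driver nodes of a directed network
#'
#' Computes a maximum matching of the bipartite split with an
#' augmenting-path algorithm whose node visitation order is `node_order`;
#' the matching *size* is the same for every order (maximality), but the
#' matched edge set — and hence the driver set — can differ. Driver nodes
#' are the nodes whose in-copy is unmatched: they must receive an external
#' control input for the network to be structurally controllable. When the
#' matching is perfect the driver set is defined as the first node of
#' `node_order` (at least one input is always required); in an edgeless
#' network every node is its own driver.
#'
#' @param x A `dependency_network` or a data frame of directed edges.
#' @param node_order Character vector, a permutation of the node set;
#'   defaults to sorted order.
#' @param nodes Optional full node set (lets isolated nodes, which are always
#'   drivers, be represented); defaults to the nodes incident to edges (or
#'   the network's node set).
#' @return A list of class `"matching_result"`: `matched_edges` (tibble
#'   `modulator`, `dependent`), `driver_nodes` (character), `matching_size`,
#'   `n_nodes`.
#' @examples
#' path <- data.frame(modulator = c("n1", "n2"), dependent = c("n2", "n3"))
#' max_matching_drivers(path)   # drivers: n1
#' @export
max_matching_drivers <- function(x, node_order = NULL, nodes = NULL) {
  edges <- net_edges(x)
  if (is.null(nodes)) nodes <- net_nodes(x, edges)
  nodes <- as.character(nodes)
  n <- length(nodes)
  if (n == 0) abort("network has no nodes")
  if (is.null(node_order)) node_order <- sort(nodes)
  if (!setequal(node_order, nodes) || length(node_order) != n) {
    abort("node_order must be a permutation of the node set")
  }
  from <- match(edges$modulator, nodes) - 1L
  to <- match(edges$dependent, nodes) - 1L
  if (anyNA(from) || anyNA(to)) abort("edge endpoints missing from `nodes`")
  ord <- match(node_order, nodes) - 1L
  res <- cpp_kuhn_match(n, from, to, ord)
  match_in <- res$match_in
  drivers <- nodes[match_in == -1L]
  if (length(drivers) == 0) drivers <- node_order[1]   # perfect matching
  matched <- which(match_in >= 0L)
  structure(
    list(
      matched_edges = tibble::tibble(
        modulator = nodes[match_in[matched] + 1L],
        dependent = nodes[matched]
      ),
      driver_nodes = drivers,
      matching_size = res$matching_size,
      n_nodes = n
    ),
    class = "matching_result"
  )
}

#' @export
print.matching_result <- function(x, ...) {
  cat("Maximum matching of size ", x$matching_size, " on ", x$n_nodes,
      " nodes; ", length(x$driver_nodes), " driver node(s)\n", sep = "")
  invisible(x)
}

#' Sample minimal driver sets under randomized node orderings
#'
#' Maximum matchings of complex networks are rarely unique; repeating the
#' matching under `runs` random node permutations (the dependency relations
#' themselves are untouched) samples alternative minimal driver sets. The
#' per-gene count of appearances across runs measures how indispensable each
#' gene is; the matching size is asserted identical in every run.
#'
#' @inheritParams max_matching_drivers
#' @param runs Number of randomized runs (study default 500).
#' @param seed Integer seed; run `i` uses its own derived stream.
#' @return A tibble of class `"driver_freq"` with columns `gene`, `count`,
#'   and attributes `runs`, `matching_size`, `n_nodes`.
#' @export
sample_driver_sets <- function(x, runs = 500L, seed = 1L, nodes = NULL) {
  if (runs < 1) abort("runs must be >= 1")
  edges <- net_edges(x)
  if (is.null(nodes)) nodes <- net_nodes(x, edges)
  counts <- stats::setNames(integer(length(nodes)), nodes)
  msize <- NA_integer_
  for (i in seq_len(runs)) {
    ord <- with_seed(derive_seed(seed, i), sample(nodes))
    res <- max_matching_drivers(edges, node_order = ord, nodes = nodes)
    if (is.na(msize)) {
      msize <- res$matching_size
    } else if (res$matching_size != msize) {
      abort("matching size varied across runs; augmenting search is broken")
    }
    counts[res$driver_nodes] <- counts[res$driver_nodes] + 1L
  }
  out <- tibble::tibble(gene = nodes, count = unname(counts)) %>%
    dplyr::arrange(dplyr::desc(.data$count), .data$gene)
  structure(out, runs = as.integer(runs), matching_size = msize,
            n_nodes = length(nodes),
            class = c("driver_freq", class(out)))
}

#' Genes present in every sampled minimal driver set
#'
#' The feature candidates of the pipeline: genes whose driver frequency
#' equals the total number of randomized matching runs, i.e. genes that no
#' alternative maximum matching can avoid controlling.
#'
#' @param freq A `driver_freq` table from [sample_driver_sets()].
#' @return Sorted character vector of gene identifiers (possibly empty).
#' @export
select_candidates <- function(freq) {
  runs <- attr(freq, "runs")
  if (is.null(runs)) abort("freq must come from sample_driver_sets()")
  sort(freq$gene[freq$count == runs])
}
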