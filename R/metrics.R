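#' Density of connections (D)
#'
#' Ratio of realized articulations to the maximum possible number of
#' articulations among `N` elements: `D = 2K / (N (N - 1))`.
#'
#' @param net an `anatomical_network` with at least 2 nodes.
#' @return density in `[0, 1]`.
#' @export
connection_density <- function(net) {
  n <- node_count(net)
  if (n < 2) stop("density undefined for networks with fewer than 2 nodes", call. = FALSE)
  2 * connection_count(net) / (n * (n - 1))
}

#' Mean clustering coefficient (C)
#'
#' Average over nodes of the local clustering coefficient: the fraction of a
#' node's neighbour pairs that are themselves articulated. Nodes of degree
#' < 2 have no neighbour pair; by default they are excluded from the average
#' (`low_degree = "exclude"`), or they can be counted as 0
#' (`low_degree = "zero"`).
#'
#' @param net an `anatomical_network`.
#' @param low_degree how to treat degree-0/1 nodes.
#' @return mean clustering coefficient in `[0, 1]`.
#' @export
mean_clustering <- function(net, low_degree = c("exclude", "zero")) {
  low_degree <- match.arg(low_degree)
  if (!any(node_degrees(net) >= 2)) {
    stop("clustering undefined: no node has degree >= 2", call. = FALSE)
  }
  local <- igraph::transitivity(as_igraph(net), type = "local", isolates = "NaN")
  if (low_degree == "zero") local[is.nan(local)] <- 0
  mean(local, na.rm = TRUE)
}

#' Mean shortest path length (L)
#'
#' Unweighted shortest-path distance averaged over all unordered node pairs
#' at finite distance. Pairs in different connected components (e.g. pairs
#' involving an isolated element) are excluded rather than treated as
#' infinite, so networks containing isolates still have a finite L.
#'
#' @param net an `anatomical_network` with at least one connection.
#' @return mean geodesic length, >= 1.
#' @export
mean_path_length <- function(net) {
  if (connection_count(net) == 0) {
    stop("path length undefined: network has no connections", call. = FALSE)
  }
  d <- igraph::distances(as_igraph(net))
  vals <- d[upper.tri(d)]
  mean(vals[is.finite(vals)])
}

#' Heterogeneity of connections (H)
#'
#' Coefficient of variation of the degree sequence, `sd(k) / mean(k)`. Low H
#' means all elements articulate with a similar number of neighbours; high H
#' flags hubs and isolates (anisomerism). Degree-0 nodes are included. The
#' sample (n-1) standard deviation is the default, the population (n)
#' variant is available for comparison with other toolchains.
#'
#' @param net an `anatomical_network` with at least one connection.
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return non-negative coefficient of variation.
#' @export
degree_heterogeneity <- function(net, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  k <- node_degrees(net)
  if (mean(k) == 0) stop("heterogeneity undefined: all degrees are zero", call. = FALSE)
  s <- stats::sd(k)
  if (sd_type == "population") s <- s * sqrt((length(k) - 1) / length(k))
  s / mean(k)
}

#' Leading-eigenvector community detection
#'
#' Newman's spectral community detection by recursive bisection: each group is
#' split by the sign pattern of the leading eigenvector of its generalized
#' modularity matrix, and a split is kept only while it increases modularity
#' Q. Unlike annealing-based detectors this handles isolated elements, each of
#' which forms its own singleton community. Deterministic: eigenvector entries
#' that are exactly zero are assigned to the positive side.
#'
#' @param net an `anatomical_network`.
#' @return list with `membership` (named integer vector, consecutive ids in
#'   order of first appearance) and `sizes` (community sizes).
#' @references Newman, M. E. J. (2006) Modularity and community structure in
#'   networks. PNAS 103:8577-8582.
#' @export
leading_eigen_communities <- function(net) {
  a <- net$adjacency
  n <- nrow(a)
  k <- rowSums(a)
  two_k <- sum(k)
  membership <- integer(n)
  names(membership) <- net$nodes

  if (two_k == 0) {
    membership[] <- seq_len(n)
    return(list(membership = membership, sizes = rep(1L, n)))
  }

  isolates <- which(k == 0)
  active <- setdiff(seq_len(n), isolates)
  b_full <- a - outer(k, k) / two_k

  # Recursive bisection on index sets of the non-isolated subgraph.
  groups <- list()
  split_group <- function(idx) {
    if (length(idx) == 1) { groups[[length(groups) + 1]] <<- idx; return(invisible()) }
    bg <- b_full[idx, idx, drop = FALSE]
    # generalized modularity matrix: subtract row sums on the diagonal
    diag(bg) <- diag(bg) - rowSums(bg)
    eig <- eigen(bg, symmetric = TRUE)
    lead <- eig$values[1]
    if (lead <= 1e-12) { groups[[length(groups) + 1]] <<- idx; return(invisible()) }
    s <- ifelse(eig$vectors[, 1] >= 0, 1, -1)
    dq <- as.numeric(t(s) %*% bg %*% s) / (2 * two_k)
    if (dq <= 1e-12 || all(s == s[1])) {
      groups[[length(groups) + 1]] <<- idx
      return(invisible())
    }
    split_group(idx[s > 0])
    split_group(idx[s < 0])
  }
  split_group(active)

  next_id <- 1L
  for (g in groups) {
    membership[g] <- next_id
    next_id <- next_id + 1L
  }
  for (i in isolates) {
    membership[i] <- next_id
    next_id <- next_id + 1L
  }
  # renumber in order of first appearance for stability
  membership <- match(membership, unique(membership))
  names(membership) <- net$nodes
  list(membership = membership,
       sizes = as.integer(table(membership)[as.character(seq_len(max(membership)))]))
}

#' Parcellation (P)
#'
#' A modularity summary measuring how extensively and how evenly the network
#' divides into communities: `P = 1 - sum_i (N_i / N)^2` over the community
#' sizes `N_i` found by [leading_eigen_communities()]. P is 0 when the whole
#' network is a single community and approaches `1 - 1/N` for all-singleton
#' partitions.
#'
#' @param net an `anatomical_network`.
#' @param communities optional precomputed result of
#'   [leading_eigen_communities()].
#' @return parcellation in `[0, 1 - 1/N]`.
#' @export
parcellation <- function(net, communities = NULL) {
  if (is.null(communities)) communities <- leading_eigen_communities(net)
  n <- node_count(net)
  1 - sum((communities$sizes / n)^2)
}

#' Compute all whole-network parameters
#'
#' One row of the per-taxon parameter table: node count N (including
#' isolates), connection count K (undirected articulations counted once),
#' density D, mean clustering coefficient C, mean shortest path length L,
#' heterogeneity of connections H, and parcellation P.
#'
#' @param net an `anatomical_network`.
#' @param taxon row label; defaults to the network's specimen id.
#' @param low_degree passed to [mean_clustering()].
#' @param sd_type passed to [degree_heterogeneity()].
#' @return one-row data.frame with columns `Taxon, N, K, D, C, L, H, P`.
#' @examples
#' net <- generate_skull_network(seed = 1)$network
#' network_parameters(net)
#' @export
network_parameters <- function(net, taxon = net$specimen_id,
                               low_degree = "exclude", sd_type = "sample") {
  data.frame(
    Taxon = taxon,
    N = node_count(net),
    K = connection_count(net),
    D = connection_density(net),
    C = mean_clustering(net, low_degree = low_degree),
    L = mean_path_length(net),
    H = degree_heterogeneity(net, sd_type = sd_type),
    P = parcellation(net),
    stringsAsFactors = FALSE
  )
}
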