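#' Construct an anatomical network
#'
#' An anatomical network models a jointed skeletal system (typically a skull)
#' as an unweighted, undirected graph: nodes are named skeletal elements
#' (bones) and an edge records an articulation between two elements. The
#' adjacency matrix must be binary, symmetric, and zero on the diagonal.
#' Degree-0 nodes are permitted: real skulls contain elements with no scored
#' articulation (e.g. a free-floating jugal), and such elements still count
#' towards the network size.
#'
#' @param adjacency square numeric matrix with entries in \{0, 1\}; row and
#'   column names must be identical, unique bone labels.
#' @param specimen_id character label for the specimen/taxon the network
#'   describes.
#' @return An object of class `anatomical_network`: a list with elements
#'   `specimen_id`, `nodes` (character vector of bone labels in matrix order)
#'   and `adjacency` (the validated integer matrix).
#' @examples
#' m <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' m["A", "B"] <- m["B", "A"] <- 1
#' m["B", "C"] <- m["C", "B"] <- 1
#' net <- anatomical_network(m, "path_ABC")
#' connection_count(net) # 2
#' @export
anatomical_network <- function(adjacency, specimen_id = "network") {
  if (!is.matrix(adjacency)) {
    stop("`adjacency` must be a matrix", call. = FALSE)
  }
  if (nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency matrix must be square", call. = FALSE)
  }
  labels <- rownames(adjacency)
  if (is.null(labels) || is.null(colnames(adjacency))) {
    stop("adjacency matrix must carry row and column names (bone labels)",
         call. = FALSE)
  }
  if (!identical(labels, colnames(adjacency))) {
    stop("row and column labels must be identical and in identical order",
         call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("node labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  mode(adjacency) <- "numeric"
  if (anyNA(adjacency) || !all(adjacency %in% c(0, 1))) {
    bad <- which(!(adjacency %in% c(0, 1)) | is.na(adjacency))[1]
    stop(sprintf("adjacency entries must be 0 or 1 (offending entry at [%d, %d])",
                 (bad - 1) %% nrow(adjacency) + 1, (bad - 1) %/% nrow(adjacency) + 1),
         call. = FALSE)
  }
  asym <- which(adjacency != t(adjacency), arr.ind = TRUE)
  if (nrow(asym) > 0) {
    i <- asym[1, 1]; j <- asym[1, 2]
    stop(sprintf("adjacency matrix is asymmetric at (%s, %s)", labels[i], labels[j]),
         call. = FALSE)
  }
  if (any(diag(adjacency) != 0)) {
    stop("adjacency diagonal must be zero (no self-articulations): ",
         paste(labels[diag(adjacency) != 0], collapse = ", "), call. = FALSE)
  }
  storage.mode(adjacency) <- "integer"
  structure(
    list(specimen_id = as.character(specimen_id)[1],
         nodes = labels,
         adjacency = adjacency),
    class = "anatomical_network"
  )
}

#' @export
print.anatomical_network <- function(x, ...) {
  cat(sprintf("Anatomical network '%s': %d nodes, %d connections\n",
              x$specimen_id, node_count(x), connection_count(x)))
  iso <- sum(node_degrees(x) == 0)
  if (iso > 0) cat(sprintf("  (%d isolated element%s)\n", iso, if (iso > 1) "s" else ""))
  invisible(x)
}

#' Number of nodes (N)
#' @param net an `anatomical_network`
#' @return integer node count, including isolated elements.
#' @export
node_count <- function(net) length(net$nodes)

#' Number of connections (K)
#' @param net an `anatomical_network`
#' @return integer count of undirected articulations, each counted once.
#' @export
connection_count <- function(net) as.integer(sum(net$adjacency) / 2)

#' Node degree sequence
#' @param net an `anatomical_network`
#' @return named integer vector of per-node articulation counts.
#' @export
node_degrees <- function(net) {
  d <- rowSums(net$adjacency)
  storage.mode(d) <- "integer"
  d
}

#' Convert an anatomical network to an igraph graph
#'
#' @param net an `anatomical_network`
#' @return an undirected [igraph::graph] with vertex names equal to bone labels.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "anatomical_network"))
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
}

#' Describe the left/right layout of a network's elements
#'
#' Skull elements are either paired (a left and a right copy, e.g.
#' `maxilla_L` / `maxilla_R`) or unpaired midline elements (e.g. the
#' parietal in many snakes). A laterality map records this layout so that
#' bilateral symmetry of the articulation matrix can be checked: every node
#' must appear exactly once across the pairs and the midline list.
#'
#' @param pairs two-column character matrix or data.frame; column 1 left
#'   labels, column 2 the corresponding right labels.
#' @param midline character vector of unpaired element labels.
#' @return object of class `laterality_map` with elements `pairs` (2-column
#'   character matrix) and `midline`.
#' @seealso [infer_laterality()] to build one from `_L`/`_R` suffixes,
#'   [check_bilateral_symmetry()].
#' @export
laterality_map <- function(pairs, midline = character()) {
  pairs <- as.matrix(pairs)
  if (length(pairs) == 0) pairs <- matrix(character(), ncol = 2)
  if (ncol(pairs) != 2) stop("`pairs` must have two columns (left, right)", call. = FALSE)
  storage.mode(pairs) <- "character"
  colnames(pairs) <- c("left", "right")
  all_nodes <- c(pairs[, 1], pairs[, 2], midline)
  if (anyDuplicated(all_nodes)) {
    stop("each node may appear only once across pairs and midline; duplicated: ",
         paste(unique(all_nodes[duplicated(all_nodes)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(pairs = pairs, midline = as.character(midline)),
            class = "laterality_map")
}

#' Infer a laterality map from node-label suffixes
#'
#' Builds a [laterality_map()] by pairing labels that differ only in a
#' left/right suffix; all other labels are treated as midline elements.
#'
#' @param net an `anatomical_network`
#' @param left,right suffixes marking left and right copies (defaults `"_L"`,
#'   `"_R"`).
#' @return a `laterality_map` covering every node of `net`.
#' @export
infer_laterality <- function(net, left = "_L", right = "_R") {
  nodes <- net$nodes
  is_left <- endsWith(nodes, left)
  is_right <- endsWith(nodes, right)
  base_l <- substr(nodes[is_left], 1, nchar(nodes[is_left]) - nchar(left))
  base_r <- substr(nodes[is_right], 1, nchar(nodes[is_right]) - nchar(right))
  shared <- intersect(base_l, base_r)
  pairs <- cbind(paste0(shared, left), paste0(shared, right))
  midline <- setdiff(nodes, c(pairs))
  laterality_map(pairs, midline)
}

#' Check bilateral symmetry of an articulation network
#'
#' A well-scored skull network should be invariant under the mirror
#' relabelling that swaps each left element with its right counterpart and
#' fixes midline elements; i.e. the mirror map must be a graph automorphism.
#' This check reports every edge whose mirrored edge is absent.
#'
#' @param net an `anatomical_network`
#' @param lat a `laterality_map` covering all nodes of `net` (default:
#'   inferred from `_L`/`_R` suffixes).
#' @return data.frame with zero or more rows and columns `from`, `to`
#'   (an existing edge) and `mirror_from`, `mirror_to` (its missing mirror
#'   image). Zero rows means the network is bilaterally symmetric.
#' @export
check_bilateral_symmetry <- function(net, lat = infer_laterality(net)) {
  stopifnot(inherits(net, "anatomical_network"), inherits(lat, "laterality_map"))
  covered <- c(lat$pairs[, 1], lat$pairs[, 2], lat$midline)
  missing_in_net <- setdiff(covered, net$nodes)
  if (length(missing_in_net) > 0) {
    stop("laterality map names nodes absent from the network: ",
         paste(missing_in_net, collapse = ", "), call. = FALSE)
  }
  uncovered <- setdiff(net$nodes, covered)
  if (length(uncovered) > 0) {
    stop("laterality map does not cover nodes: ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  mirror <- stats::setNames(net$nodes, net$nodes)
  mirror[lat$pairs[, 1]] <- lat$pairs[, 2]
  mirror[lat$pairs[, 2]] <- lat$pairs[, 1]

  a <- net$adjacency
  edges <- which(a == 1 & upper.tri(a), arr.ind = TRUE)
  out <- data.frame(from = character(), to = character(),
                    mirror_from = character(), mirror_to = character(),
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(edges))) {
    i <- net$nodes[edges[r, 1]]; j <- net$nodes[edges[r, 2]]
    mi <- mirror[[i]]; mj <- mirror[[j]]
    if (a[mi, mj] != 1) {
      out[nrow(out) + 1L, ] <- c(i, j, mi, mj)
    }
  }
  out
}
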