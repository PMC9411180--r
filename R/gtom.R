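#' Generalized topological overlap matrix (GTOM)
#'
#' Converts a binary articulation matrix into a node-by-node similarity
#' matrix measuring the extent to which two elements share neighbourhoods.
#' For neighbourhood order `steps = 1`,
#' \deqn{t_{ij} = \frac{|N(i) \cap N(j)| + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},}
#' where `N(i)` is the set of neighbours of `i` (excluding `i` and `j`) and
#' `k_i` the degree. For `steps = m > 1` the same formula is applied to
#' m-step neighbourhoods (all nodes reachable in at most m steps), following
#' Yip & Horvath's generalization. The diagonal is 1; pairs with a zero
#' denominator (two isolated elements) get overlap 0, so isolates are
#' maximally dissimilar to everything and join a dendrogram last.
#'
#' @param net an `anatomical_network`.
#' @param steps neighbourhood order m >= 1 (default 1, the base GTOM).
#' @return symmetric numeric matrix in `[0, 1]` with bone labels as
#'   dimnames and attribute `steps`.
#' @references Yip, A. M. & Horvath, S. (2007) Gene network interconnectedness
#'   and the generalized topological overlap measure. BMC Bioinformatics 8:22.
#' @export
gtom <- function(net, steps = 1) {
  stopifnot(inherits(net, "anatomical_network"))
  steps <- as.integer(steps)
  if (steps < 1) stop("`steps` must be >= 1", call. = FALSE)
  a <- net$adjacency
  n <- nrow(a)
  storage.mode(a) <- "double"

  # m-step neighbourhood indicator: reachable within `steps` steps, self excluded
  if (steps == 1) {
    m <- a
  } else {
    reach <- a + diag(n)
    acc <- reach
    for (s in seq_len(steps - 1)) acc <- acc %*% reach
    m <- (acc > 0) * 1
    diag(m) <- 0
  }

  shared <- m %*% m              # |N_m(i) ∩ N_m(j)|, i and j excluded (zero diag)
  r <- rowSums(m)                # |N_m(i)|
  denom <- pmin(outer(r, rep(1, n)), outer(rep(1, n), r)) + 1 - a
  t_mat <- (shared + a) / denom
  t_mat[denom <= 0] <- 0
  diag(t_mat) <- 1
  dimnames(t_mat) <- list(net$nodes, net$nodes)
  attr(t_mat, "steps") <- steps
  t_mat
}

#' Dissimilarity from a GTOM matrix
#'
#' @param overlap matrix from [gtom()].
#' @return symmetric distance matrix `d = 1 - t` with zero diagonal.
#' @export
gtom_dissimilarity <- function(overlap) {
  d <- 1 - overlap
  diag(d) <- 0
  attr(d, "steps") <- NULL
  d
}

#' UPGMA (average-linkage) hierarchical clustering
#'
#' Agglomerative clustering in which the distance between two clusters is the
#' arithmetic mean of all between-cluster pairwise distances, and each merge
#' height equals that mean at the time of merging. Ties between candidate
#' merges are broken deterministically: the pair whose lexicographically
#' smallest member label is smallest wins (then the second label), so the
#' dendrogram is reproducible regardless of input order.
#'
#' @param d symmetric zero-diagonal distance matrix with labels, or a
#'   [stats::dist] object.
#' @return a [stats::hclust] object (method `"average"`), usable with
#'   [stats::cutree()], [stats::cophenetic()] and [ape::as.phylo()].
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d)) || any(diag(d) != 0)) {
    stop("`d` must be a symmetric distance matrix with zero diagonal", call. = FALSE)
  }
  if (anyNA(d)) stop("distance matrix contains NA/NaN", call. = FALSE)
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n < 2) stop("need at least 2 items to cluster", call. = FALSE)

  # active cluster bookkeeping
  size <- rep(1, n)
  id <- -seq_len(n)              # hclust convention: negative = singleton
  rep_label <- labels            # lexicographically smallest member label
  active <- rep(TRUE, n)
  dd <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- NULL
    best_val <- Inf
    for (ii in seq_along(idx)[-length(idx)]) {
      i <- idx[ii]
      js <- idx[(ii + 1):length(idx)]
      vals <- dd[i, js]
      jmin <- js[vals <= best_val + 1e-15]
      for (j in jmin) {
        v <- dd[i, j]
        if (v < best_val - 1e-15) {
          best_val <- v; best <- c(i, j)
        } else if (v <= best_val + 1e-15) {
          # tie: lexicographic on sorted representative labels
          cand <- sort(c(rep_label[i], rep_label[j]))
          cur <- sort(c(rep_label[best[1]], rep_label[best[2]]))
          if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
            best_val <- min(best_val, v); best <- c(i, j)
          }
        }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- dd[i, j]
    # merged cluster stored in slot i
    others <- setdiff(idx, c(i, j))
    if (length(others) > 0) {
      dd[i, others] <- (size[i] * dd[i, others] + size[j] * dd[j, others]) /
        (size[i] + size[j])
      dd[others, i] <- dd[i, others]
    }
    size[i] <- size[i] + size[j]
    id[i] <- step
    rep_label[i] <- min(rep_label[i], rep_label[j])
    active[j] <- FALSE
  }

  # leaf order for plotting: in-order traversal of the merge tree
  order_of <- function(node) {
    if (node < 0) return(-node)
    c(order_of(merge[node, 1]), order_of(merge[node, 2]))
  }
  hc <- list(merge = merge, height = height, order = order_of(n - 1),
             labels = labels, method = "average",
             call = match.call(), dist.method = "gtom")
  class(hc) <- "hclust"
  hc
}

#' Export a dendrogram as Newick
#'
#' Converts an [upgma()] dendrogram to a Newick string (branch lengths
#' derived from merge heights) for external tree viewers.
#'
#' @param hc an `hclust` object.
#' @param path optional file; when given the string is also written there.
#' @return Newick string, invisibly when `path` is given.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
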