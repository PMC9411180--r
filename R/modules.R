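#' Newman-Girvan modularity Q
#'
#' For a partition of the network's nodes into modules,
#' `Q = sum_s (e_ss - a_s^2)`, where `e_ss` is the fraction of connections
#' falling inside module `s` and `a_s` the fraction of connection endpoints
#' attached to nodes of `s`. Q is 0 when within-module connectivity is no
#' better than expected for a randomly wired network with the same degrees,
#' and approaches 1 for strongly modular networks.
#'
#' @param net an `anatomical_network` with at least one connection.
#' @param membership vector assigning every node to a module (any label
#'   type); order must follow `net$nodes` unless named.
#' @return modularity Q in `[-1, 1]`.
#' @export
newman_girvan_q <- function(net, membership) {
  k_tot <- connection_count(net)
  if (k_tot == 0) stop("Q undefined: network has no connections", call. = FALSE)
  if (!is.null(names(membership))) membership <- membership[net$nodes]
  if (length(membership) != node_count(net) || anyNA(membership)) {
    stop("membership must cover every node exactly once", call. = FALSE)
  }
  a <- net$adjacency
  q <- 0
  for (s in unique(membership)) {
    inside <- membership == s
    e_ss <- sum(a[inside, inside, drop = FALSE]) / (2 * k_tot)
    a_s <- sum(a[inside, , drop = FALSE]) / (2 * k_tot)
    q <- q + e_ss - a_s^2
  }
  q
}

#' Q-modules: the modularity-optimal dendrogram cut
#'
#' Evaluates Newman-Girvan Q on the partition induced by cutting the
#' dendrogram into `k = 1 .. N` clusters and returns the cut with maximal Q
#' (ties broken toward fewer clusters). Q is computed on the original binary
#' articulation matrix, not on GTOM weights.
#'
#' @param net an `anatomical_network`.
#' @param hc UPGMA dendrogram of `net` (leaves must equal the network nodes).
#' @return list of class `q_modules`: `membership` (named integer vector of
#'   module ids for the best cut), `q_value`, `n_modules` and `q_profile`
#'   (data.frame of `k` and `Q` for every evaluated cut).
#' @export
q_modules <- function(net, hc) {
  if (!setequal(hc$labels, net$nodes)) {
    stop("dendrogram leaves must match network nodes", call. = FALSE)
  }
  n <- node_count(net)
  ks <- seq_len(n)
  cuts <- stats::cutree(hc, k = ks)    # n x n matrix, columns are cuts
  qs <- vapply(ks, function(k) newman_girvan_q(net, cuts[, k]), numeric(1))
  best_k <- ks[which.max(qs)]          # which.max takes the first (fewest clusters)
  membership <- cuts[, best_k][net$nodes]
  structure(list(membership = membership,
                 q_value = qs[best_k],
                 n_modules = length(unique(membership)),
                 q_profile = data.frame(k = ks, Q = qs)),
            class = "q_modules")
}

#' @export
print.q_modules <- function(x, ...) {
  cat(sprintf("Q-module partition: %d modules, Q_max = %.4f\n",
              x$n_modules, x$q_value))
  invisible(x)
}

#' One-sided two-sample Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Tests whether values in `internal` tend to exceed values in `external`
#' (alternative: internal > external). The p-value is exact (enumeration of
#' rank assignments) when the combined sample size is at most 20 and there
#' are no ties; otherwise the normal approximation with continuity and tie
#' correction is used.
#'
#' @param internal,external non-empty numeric vectors.
#' @return list with `u_statistic` (Mann-Whitney U for the first sample),
#'   `p_value`, and `exact` (logical).
#' @export
mann_whitney_one_sided <- function(internal, external) {
  if (length(internal) == 0 || length(external) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n_comb <- length(internal) + length(external)
  has_ties <- anyDuplicated(c(internal, external)) > 0
  use_exact <- n_comb <= 20 && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(internal, external, alternative = "greater",
                       exact = use_exact, correct = TRUE)
  )
  list(u_statistic = unname(wt$statistic), p_value = wt$p.value, exact = use_exact)
}

# significance tiers used when annotating S-modules on dendrogram figures
.s_tier <- function(p) {
  if (is.na(p)) return("ns")
  if (p < 0.001) "p<0.001"
  else if (p < 0.01) "0.001<=p<0.01"
  else if (p < 0.05) "0.01<=p<0.05"
  else "ns"
}

#' S-modules: statistically supported dendrogram clusters
#'
#' For every internal node of the dendrogram (every nested cluster of size
#' >= 2), counts for each member its connections to other members (internal)
#' and to non-members (external), and tests internal > external with a
#' one-sided Mann-Whitney test. Clusters are assigned significance tiers
#' `p<0.001`, `0.001<=p<0.01`, `0.01<=p<0.05` or `ns`. The root cluster
#' (all nodes) has no outside and is reported with `degenerate = TRUE`.
#'
#' @param net an `anatomical_network`.
#' @param hc UPGMA dendrogram of `net`.
#' @return data.frame with one row per cluster: `cluster_id` (merge index),
#'   `size`, `members` (comma-joined labels), `u_statistic`, `p_value`,
#'   `tier`, `degenerate`.
#' @export
s_modules <- function(net, hc) {
  if (!setequal(hc$labels, net$nodes)) {
    stop("dendrogram leaves must match network nodes", call. = FALSE)
  }
  a <- net$adjacency
  n <- node_count(net)
  # members of the cluster created at each merge
  members_of <- vector("list", n - 1)
  leaves_of <- function(node) {
    if (node < 0) return(hc$labels[-node])
    members_of[[node]]
  }
  res <- vector("list", n - 1)
  for (m in seq_len(n - 1)) {
    mem <- c(leaves_of(hc$merge[m, 1]), leaves_of(hc$merge[m, 2]))
    members_of[[m]] <- mem
    inside <- net$nodes %in% mem
    internal <- rowSums(a[inside, inside, drop = FALSE])
    external <- rowSums(a[inside, !inside, drop = FALSE])
    degenerate <- all(!(!inside))
    mw <- mann_whitney_one_sided(internal, external)
    res[[m]] <- data.frame(
      cluster_id = m,
      size = length(mem),
      members = paste(sort(mem), collapse = ","),
      u_statistic = mw$u_statistic,
      p_value = mw$p_value,
      tier = .s_tier(mw$p_value),
      degenerate = degenerate,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, res)
}

#' Full module analysis of one network
#'
#' Convenience wrapper chaining [gtom()], [gtom_dissimilarity()], [upgma()],
#' [q_modules()] and [s_modules()].
#'
#' @param net an `anatomical_network`.
#' @param gtom_steps GTOM neighbourhood order (default 1).
#' @return list with `dendrogram` (hclust), `q` (`q_modules` result) and
#'   `s` (data.frame of S-module tests).
#' @export
skull_modules <- function(net, gtom_steps = 1) {
  hc <- upgma(gtom_dissimilarity(gtom(net, steps = gtom_steps)))
  list(dendrogram = hc, q = q_modules(net, hc), s = s_modules(net, hc))
}

#' JSON module report
#'
#' Serializes the result of [skull_modules()] as the per-specimen module
#' report: Q_max, Q-module memberships and S-module tests.
#'
#' @param net an `anatomical_network`.
#' @param modules result of [skull_modules()] (computed if omitted).
#' @param path optional output file.
#' @param gtom_steps used when `modules` is omitted.
#' @return JSON string (invisibly when `path` is given).
#' @export
module_report <- function(net, modules = NULL, path = NULL, gtom_steps = 1) {
  if (is.null(modules)) modules <- skull_modules(net, gtom_steps = gtom_steps)
  q <- modules$q
  mods <- lapply(sort(unique(q$membership)), function(id) {
    list(id = id, members = sort(names(q$membership)[q$membership == id]))
  })
  s_list <- lapply(seq_len(nrow(modules$s)), function(i) {
    row <- modules$s[i, ]
    list(members = strsplit(row$members, ",", fixed = TRUE)[[1]],
         U = row$u_statistic, p = row$p_value, tier = row$tier,
         degenerate = row$degenerate)
  })
  payload <- list(specimen = net$specimen_id,
                  q_max = q$q_value,
                  modules = mods,
                  s_modules = s_list)
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
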