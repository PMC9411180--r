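#' Generate a bilaterally symmetric skull-like network with planted modules
#'
#' Simulates an articulation network with the gross statistical structure of
#' a vertebrate skull network: paired left/right elements plus unpaired
#' midline elements, a planted partition into modules with dense
#' within-module and sparse between-module wiring, and (optionally) isolated
#' elements with no articulation at all. Edges are sampled by Bernoulli
#' draws on one hemisphere (left elements and midline elements) and then
#' mirrored, so left-right symmetry of the adjacency matrix is exact by
#' construction, mimicking the symmetry requirement imposed on real scored
#' specimens.
#'
#' Defaults give a 40-element network (16 pairs + 8 midline) in 4 modules,
#' within the 30-57 element range typical of squamate skulls.
#'
#' @param n_pairs number of left/right element pairs.
#' @param n_midline number of unpaired midline elements.
#' @param n_modules number of planted modules; elements are assigned to
#'   modules round-robin (pair members always share a module).
#' @param p_in within-module connection probability.
#' @param p_out between-module connection probability; must satisfy
#'   `0 <= p_out < p_in <= 1`.
#' @param n_isolates number of additional degree-0 elements.
#' @param seed RNG seed.
#' @param specimen_id network label.
#' @return list with `network` (`anatomical_network`), `laterality`
#'   (`laterality_map`) and `membership` (named integer vector of planted
#'   module ids; isolates get their own singleton ids).
#' @export
generate_skull_network <- function(n_pairs = 16, n_midline = 8, n_modules = 4,
                                   p_in = 0.8, p_out = 0.05, n_isolates = 0,
                                   seed = NULL, specimen_id = "synthetic_skull") {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("need 0 <= p_out < p_in <= 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  pair_base <- sprintf("bone%02d", seq_len(n_pairs))
  left <- paste0(pair_base, "_L")
  right <- paste0(pair_base, "_R")
  midline <- if (n_midline > 0) sprintf("mid%02d", seq_len(n_midline)) else character()
  isolates <- if (n_isolates > 0) sprintf("iso%02d", seq_len(n_isolates)) else character()

  # planted module ids: round-robin over pairs then midline elements
  unit_modules <- rep(seq_len(n_modules), length.out = n_pairs + n_midline)
  pair_mod <- unit_modules[seq_len(n_pairs)]
  mid_mod <- unit_modules[n_pairs + seq_len(n_midline)]

  nodes <- c(left, right, midline, isolates)
  a <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))

  # one hemisphere: left elements + midline
  hemi <- c(left, midline)
  hemi_mod <- c(pair_mod, mid_mod)
  mirror <- stats::setNames(nodes, nodes)
  mirror[left] <- right
  mirror[right] <- left
  for (i in seq_along(hemi)) {
    for (j in seq_len(i - 1)) {
      p <- if (hemi_mod[i] == hemi_mod[j]) p_in else p_out
      if (stats::runif(1) < p) {
        u <- hemi[i]; v <- hemi[j]
        a[u, v] <- a[v, u] <- 1L
        mu <- mirror[[u]]; mv <- mirror[[v]]
        a[mu, mv] <- a[mv, mu] <- 1L
      }
    }
  }

  membership <- c(stats::setNames(pair_mod, left),
                  stats::setNames(pair_mod, right),
                  stats::setNames(mid_mod, midline))
  if (n_isolates > 0) {
    membership <- c(membership,
                    stats::setNames(n_modules + seq_len(n_isolates), isolates))
  }
  membership <- membership[nodes]

  list(network = anatomical_network(a, specimen_id),
       laterality = laterality_map(cbind(left, right), c(midline, isolates)),
       membership = membership)
}

#' Simulate a pure-birth (Yule) tree
#'
#' Forward simulation with exponential waiting times: while `k` lineages are
#' alive the time to the next split is Exp(`k * lambda`) and a uniformly
#' chosen lineage splits. The simulation stops at the (truncated) epoch in
#' which the `n_tips + 1`-th split would occur, so the tree is ultrametric
#' and the expected root height is `sum_{k=2..n} 1 / (lambda k)`.
#'
#' @param n_tips number of tips (>= 2).
#' @param lambda speciation rate (default 1).
#' @param seed RNG seed.
#' @return an ultrametric [ape::phylo] tree with tips `t1 .. tn`.
#' @export
generate_pure_birth_tree <- function(n_tips, lambda = 1, seed = NULL) {
  if (n_tips < 2) stop("need at least 2 tips", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  # node bookkeeping: tips 1..n, internal nodes n+1 .. 2n-1 (root = n+1)
  n <- n_tips
  parent <- integer(0)
  child <- integer(0)
  birth_time <- numeric(2 * n - 1)      # time each node was created
  next_internal <- n + 1L
  next_tip <- 1L

  # lineage list holds (eventual) node ids of currently alive lineages;
  # alive lineages are provisional tips, realized as splits happen
  t_now <- 0
  alive_created <- c(0)                 # creation time of each alive lineage
  alive_id <- c(NA_integer_)            # node id once known; root handled first
  # first split creates the root from the single original lineage
  t_now <- t_now + stats::rexp(1, 1 * lambda)
  root <- next_internal; next_internal <- next_internal + 1L
  birth_time[root] <- t_now
  alive_created <- c(t_now, t_now)
  alive_parent <- c(root, root)
  k <- 2L
  edges <- list()
  while (k < n) {
    t_now <- t_now + stats::rexp(1, k * lambda)
    pick <- sample.int(k, 1)
    node <- next_internal; next_internal <- next_internal + 1L
    birth_time[node] <- t_now
    edges[[length(edges) + 1]] <- c(alive_parent[pick], node)
    alive_parent <- c(alive_parent[-pick], node, node)
    alive_created <- c(alive_created[-pick], t_now, t_now)
    k <- k + 1L
  }
  # present = time at which the (n+1)-th split would have happened
  t_present <- t_now + stats::rexp(1, n * lambda)
  tip_ids <- seq_len(n)
  for (i in seq_len(n)) {
    edges[[length(edges) + 1]] <- c(alive_parent[i], tip_ids[i])
    birth_time[tip_ids[i]] <- t_present
  }
  edge <- do.call(rbind, edges)
  edge_length <- birth_time[edge[, 2]] - birth_time[edge[, 1]]
  phy <- list(edge = edge, edge.length = edge_length,
              Nnode = n - 1L, tip.label = paste0("t", seq_len(n)))
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

#' Simulate Brownian-motion trait tables on a tree
#'
#' Draws multivariate-normal tip values with covariance `sigma2[j] * C` per
#' trait (`C` the tree's shared branch-length matrix) plus optional additive
#' group offsets, emulating trait tables whose phylogenetic structure a
#' phylogenetic PCA should absorb and whose group structure a PERMANOVA
#' should detect.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param n_traits number of traits (columns).
#' @param sigma2 Brownian rate per trait (recycled; default 1).
#' @param tip_groups optional character vector (named by tip or in tip
#'   order) assigning each tip to a category.
#' @param group_effects optional matrix or data.frame of per-category trait
#'   offsets (rows = categories, columns = traits).
#' @param seed RNG seed.
#' @param trait_names column names (default `trait1..`).
#' @return data.frame with `Taxon` (tip labels), trait columns, and a
#'   `group` column when `tip_groups` is given.
#' @export
simulate_bm_traits <- function(tree, n_traits = 7, sigma2 = 1,
                               tip_groups = NULL, group_effects = NULL,
                               seed = NULL,
                               trait_names = paste0("trait", seq_len(n_traits))) {
  if (!is.null(seed)) set.seed(seed)
  cmat <- ape::vcv.phylo(tree)
  n <- nrow(cmat)
  sigma2 <- rep_len(sigma2, n_traits)
  cl <- chol(cmat)                      # upper triangular, t(cl) %*% cl = C
  z <- matrix(stats::rnorm(n * n_traits), n, n_traits)
  x <- t(cl) %*% z %*% diag(sqrt(sigma2), n_traits)
  rownames(x) <- rownames(cmat)
  colnames(x) <- trait_names
  out <- data.frame(Taxon = rownames(x), x, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (!is.null(tip_groups)) {
    if (!is.null(names(tip_groups))) tip_groups <- tip_groups[out$Taxon]
    stopifnot(length(tip_groups) == n)
    out$group <- as.character(tip_groups)
    if (!is.null(group_effects)) {
      ge <- as.matrix(group_effects)
      if (is.null(rownames(ge))) stop("group_effects needs category rownames", call. = FALSE)
      out[trait_names] <- out[trait_names] + ge[out$group, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

#' Write a deterministic fixture suite
#'
#' Writes small, seeded example inputs in the formats the pipeline consumes:
#' a 3-node path, two joined 4-cliques, three planted-module skull networks
#' spanning easy/medium/hard recovery regimes (p_in/p_out contrasts
#' 0.8/0.05, 0.45/0.12, 0.2/0.18) with their laterality maps and planted
#' labels, a pure-birth tree, and a matched Brownian trait table with
#' habitat and size-class groupings. Running twice with the same seed gives
#' byte-identical files.
#'
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed driving every stochastic fixture.
#' @return character vector of written file paths, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  put <- function(p) { written <<- c(written, p); p }

  # path A-B-C
  m <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m["A", "B"] <- m["B", "A"] <- 1; m["B", "C"] <- m["C", "B"] <- 1
  write_adjacency(anatomical_network(m, "path_ABC"),
                  put(file.path(out_dir, "path_ABC.csv")))

  # two 4-cliques joined by one bridge
  lab <- c(paste0("a", 1:4), paste0("b", 1:4))
  m2 <- matrix(0, 8, 8, dimnames = list(lab, lab))
  m2[1:4, 1:4] <- 1; m2[5:8, 5:8] <- 1; diag(m2) <- 0
  m2[4, 5] <- m2[5, 4] <- 1
  write_adjacency(anatomical_network(m2, "two_cliques"),
                  put(file.path(out_dir, "two_cliques.csv")))

  regimes <- list(easy = c(0.8, 0.05), medium = c(0.45, 0.12), hard = c(0.2, 0.18))
  for (nm in names(regimes)) {
    g <- generate_skull_network(p_in = regimes[[nm]][1], p_out = regimes[[nm]][2],
                                seed = seed + match(nm, names(regimes)),
                                specimen_id = paste0("skull_", nm))
    write_adjacency(g$network, put(file.path(out_dir, paste0("skull_", nm, ".csv"))))
    utils::write.table(
      data.frame(node = names(g$membership), module = g$membership),
      put(file.path(out_dir, paste0("skull_", nm, "_modules.tsv"))),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      rbind(data.frame(left = g$laterality$pairs[, 1],
                       right = g$laterality$pairs[, 2]),
            data.frame(left = g$laterality$midline, right = "")),
      put(file.path(out_dir, paste0("skull_", nm, "_laterality.tsv"))),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # tree + trait table with habitat/size groupings
  tree <- generate_pure_birth_tree(53, seed = seed + 100)
  ape::write.tree(tree, put(file.path(out_dir, "tree53.nwk")))
  set.seed(seed + 200)
  habitat <- sample(.habitat_levels, 53, replace = TRUE, prob = c(0.55, 0.12, 0.33))
  size_cl <- sample(.size_levels, 53, replace = TRUE)
  traits <- simulate_bm_traits(
    tree, n_traits = 7,
    trait_names = c("N", "K", "D", "C", "L", "H", "P"),
    tip_groups = stats::setNames(habitat, tree$tip.label),
    group_effects = matrix(rep(c(1, 0, -1), 7), nrow = 3,
                           dimnames = list(.habitat_levels, NULL)),
    seed = seed + 300)
  grouping <- data.frame(taxon = traits$Taxon, habitat = traits$group,
                         size_class = size_cl, stringsAsFactors = FALSE)
  traits$group <- NULL
  utils::write.table(traits, put(file.path(out_dir, "traits53.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(grouping, put(file.path(out_dir, "groupings53.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(written)
}
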