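test_that("density matches the closed form, including printed-table cases", {
  # N/K pairs as printed for four taxa in the study table
  expect_equal(round(91 / choose(39, 2), 4), 0.1228)
  net <- two_cliques()
  expect_equal(connection_density(net),
               connection_count(net) / choose(node_count(net), 2))
  k2 <- complete_net(2)
  expect_equal(connection_density(k2), 1)
  expect_error(connection_density(anatomical_network(named_matrix(1, "A"))),
               "fewer than 2")
})

test_that("clustering coefficient handles triangles, paths and low degree", {
  expect_equal(mean_clustering(complete_net(3)), 1)
  # path A-B-C: only B has degree 2 and its neighbours are unconnected
  expect_equal(mean_clustering(path3()), 0)
  # zero-low-degree convention counts A and C as 0 too
  expect_equal(mean_clustering(path3(), low_degree = "zero"), 0)
  # triangle plus pendant: local = (1,1,1/1,NA) under exclusion, 0 under zero
  m <- add_edges(named_matrix(4, LETTERS[1:4]),
                 list(c("A", "B"), c("B", "C"), c("A", "C"), c("C", "D")))
  net <- anatomical_network(m)
  expect_equal(mean_clustering(net), mean(c(1, 1, 1 / 3)))
  expect_equal(mean_clustering(net, "zero"), mean(c(1, 1, 1 / 3, 0)))
  empty <- anatomical_network(named_matrix(3))
  expect_error(mean_clustering(empty), "degree >= 2")
})

test_that("mean path length averages finite unordered pairs only", {
  expect_equal(mean_path_length(path3()), 4 / 3)
  expect_equal(mean_path_length(complete_net(5)), 1)
  # two disjoint edges: only the two within-edge pairs are finite
  m <- add_edges(named_matrix(4, LETTERS[1:4]),
                 list(c("A", "B"), c("C", "D")))
  expect_equal(mean_path_length(anatomical_network(m)), 1)
  expect_error(mean_path_length(anatomical_network(named_matrix(3))),
               "no connections")
})

test_that("heterogeneity is the coefficient of variation of degrees", {
  expect_equal(degree_heterogeneity(complete_net(6)), 0)   # regular graph
  # star S4: degrees 4,1,1,1,1
  m <- add_edges(named_matrix(5, c("h", "l1", "l2", "l3", "l4")),
                 lapply(paste0("l", 1:4), function(l) c("h", l)))
  s4 <- anatomical_network(m)
  expect_equal(degree_heterogeneity(s4), stats::sd(c(4, 1, 1, 1, 1)) / 1.6)
  pop <- degree_heterogeneity(s4, "population")
  expect_equal(pop, stats::sd(c(4, 1, 1, 1, 1)) * sqrt(4 / 5) / 1.6)
  # adding an isolate increases H (more degree imbalance)
  m2 <- rbind(cbind(m, iso = 0), iso = 0)
  rownames(m2)[6] <- "iso"
  expect_gt(degree_heterogeneity(anatomical_network(m2)),
            degree_heterogeneity(s4))
  expect_error(degree_heterogeneity(anatomical_network(named_matrix(3))),
               "all degrees")
})

test_that("leading-eigenvector communities split cliques, keep K_n whole, isolate singletons", {
  net <- two_cliques(k = 5)
  com <- leading_eigen_communities(net)
  expect_equal(length(com$sizes), 2)
  expect_equal(length(unique(com$membership[paste0("a", 1:5)])), 1)
  expect_equal(length(unique(com$membership[paste0("b", 1:5)])), 1)

  expect_equal(max(leading_eigen_communities(complete_net(6))$membership), 1)

  # two isolated jugals form singleton communities
  m <- named_matrix(7, c(LETTERS[1:5], "jugal_L", "jugal_R"))
  m[1:5, 1:5] <- 1; diag(m) <- 0
  com2 <- leading_eigen_communities(anatomical_network(m))
  expect_equal(sum(com2$sizes == 1), 2)
  expect_equal(sum(com2$sizes), 7)
})

test_that("community partition maximizes Q among bipartitions on small graphs", {
  # where the exhaustive optimum is a bipartition, the spectral method finds it
  for (seed in c(2, 5, 8, 13)) {
    net <- two_cliques(k = 4)
    com <- leading_eigen_communities(net)
    best_q <- -Inf
    idx <- seq_len(node_count(net))
    for (mask in 1:(2^7 - 1)) { # nontrivial bipartitions up to symmetry
      side <- as.integer(intToBits(mask))[1:8]
      q <- q_oracle(net, side)
      best_q <- max(best_q, q)
    }
    expect_equal(newman_girvan_q(net, com$membership), best_q, tolerance = 1e-12)
  }
})

test_that("parcellation follows 1 - sum((N_i/N)^2) with its bounds", {
  expect_equal(parcellation(complete_net(5)), 0)
  expect_equal(parcellation(two_cliques(k = 5)), 0.5)
  for (seed in 1:10) {
    net <- random_er_net(12, 0.25, seed = seed)
    p <- parcellation(net)
    n <- node_count(net)
    expect_gte(p, 0)
    expect_lte(p, 1 - 1 / n + 1e-12)
    com <- leading_eigen_communities(net)
    expect_equal(p, 1 - sum((com$sizes / n)^2))
    if (length(com$sizes) == 1) expect_equal(p, 0)
  }
})

test_that("all parameters are invariant under node relabeling and mirroring", {
  g <- generate_skull_network(seed = 21, n_isolates = 1)
  net <- g$network
  base <- network_parameters(net, taxon = "t")
  # random relabeling
  set.seed(1)
  perm <- sample(node_count(net))
  a <- net$adjacency[perm, perm]
  relab <- anatomical_network(a, "t")
  expect_equal(network_parameters(relab, taxon = "t"), base)
  # mirror automorphism: swap _L and _R labels
  mirror <- net$nodes
  mirror <- ifelse(endsWith(mirror, "_L"), sub("_L$", "_R", mirror),
                   ifelse(endsWith(mirror, "_R"), sub("_R$", "_L", mirror), mirror))
  a2 <- net$adjacency
  dimnames(a2) <- list(mirror, mirror)
  ord <- match(net$nodes, mirror)
  mirrored <- anatomical_network(a2[ord, ord], "t")
  expect_equal(network_parameters(mirrored, taxon = "t"), base)
})

test_that("compute-all row propagates component errors for an empty network", {
  empty <- anatomical_network(named_matrix(5))
  expect_error(network_parameters(empty))
})
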