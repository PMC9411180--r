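test_that("Q agrees with an independent edge-list oracle over all partitions", {
  # every set partition of two 6-node graphs
  parts <- all_partitions(6)
  nets <- list(two_cliques(k = 3), random_er_net(6, 0.5, seed = 9))
  for (net in nets) {
    for (p in parts) {
      expect_equal(newman_girvan_q(net, p), q_oracle(net, p), tolerance = 1e-12)
    }
  }
})

test_that("Q special values: single module zero, disjoint triangles 0.5, singletons negative", {
  net <- two_cliques()
  expect_equal(newman_girvan_q(net, rep(1, 8)), 0)
  tri2 <- anatomical_network(add_edges(named_matrix(6, letters[1:6]),
    list(c("a", "b"), c("b", "c"), c("a", "c"),
         c("d", "e"), c("e", "f"), c("d", "f"))))
  expect_equal(newman_girvan_q(tri2, rep(1:2, each = 3)), 0.5)
  expect_lt(newman_girvan_q(net, seq_len(8)), 0)
  expect_error(newman_girvan_q(anatomical_network(named_matrix(3)), rep(1, 3)),
               "no connections")
  expect_equal(newman_girvan_q(net, rep(1:2, each = 4)),
               newman_girvan_q(net, rep(c(9, 4), each = 4))) # relabel invariance
})

test_that("Q_max cut recovers the two cliques and beats every other cut", {
  net <- two_cliques(k = 4, bridges = 1)
  hc <- upgma(gtom_dissimilarity(gtom(net)))
  qm <- q_modules(net, hc)
  expect_equal(qm$n_modules, 2)
  expect_equal(length(unique(qm$membership[paste0("a", 1:4)])), 1)
  expect_equal(length(unique(qm$membership[paste0("b", 1:4)])), 1)
  # profile covers every cut and is dominated by the returned Q
  expect_equal(qm$q_profile$k, 1:8)
  expect_true(all(qm$q_profile$Q <= qm$q_value + 1e-12))
  expect_equal(max(qm$q_profile$Q), qm$q_value)
})

test_that("Q_max on a complete graph is the single module, Q = 0", {
  net <- complete_net(6)
  qm <- q_modules(net, upgma(gtom_dissimilarity(gtom(net))))
  expect_equal(qm$n_modules, 1)
  expect_equal(qm$q_value, 0)
})

test_that("exact Mann-Whitney p equals exhaustive enumeration for n <= 8", {
  set.seed(5)
  for (m in 1:4) {
    for (n in 1:4) {
      x <- sample(seq(1, 100), m)
      y <- sample(setdiff(seq(1, 100), x), n)
      res <- mann_whitney_one_sided(x, y)
      expect_true(res$exact)
      expect_equal(res$p_value, mw_oracle_p(x, y), tolerance = 1e-12,
                   label = sprintf("m=%d n=%d", m, n))
    }
  }
  # the textbook case: all internal ranks above all external ranks
  res <- mann_whitney_one_sided(c(5, 6, 7), c(1, 1.5, 2))
  expect_equal(res$p_value, 0.05)
  # identical samples: no shift, p around 0.5 or larger
  res2 <- mann_whitney_one_sided(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_false(res2$exact) # ties force the approximation
  expect_gt(res2$p_value, 0.4)
})

test_that("ties and large samples switch to the corrected normal approximation", {
  x <- rep(1:6, 2); y <- rep(2:7, 2) # 24 observations, many ties
  res <- mann_whitney_one_sided(y, x)
  expect_false(res$exact)
  ref <- suppressWarnings(stats::wilcox.test(y, x, alternative = "greater"))
  expect_equal(res$p_value, ref$p.value)
})

test_that("S-modules flag a planted clique and mark the root degenerate", {
  set.seed(12)
  # 6-clique embedded in a sparse 18-node background
  n <- 18
  m <- named_matrix(n)
  up <- which(upper.tri(m))
  m[up] <- as.integer(stats::runif(length(up)) < 0.08)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m[1:6, 1:6] <- 1; diag(m) <- 0
  net <- anatomical_network(m, "planted_clique")
  hc <- upgma(gtom_dissimilarity(gtom(net)))
  s <- s_modules(net, hc)
  clique_row <- s[vapply(strsplit(s$members, ","), function(mm)
    setequal(mm, net$nodes[1:6]), logical(1)), ]
  expect_equal(nrow(clique_row), 1)
  expect_lt(clique_row$p_value, 0.001)
  expect_equal(clique_row$tier, "p<0.001")
  root <- s[s$size == n, ]
  expect_true(root$degenerate)
  expect_false(any(s$degenerate[s$size < n]))
  # tiers consistent with p-values
  recomputed <- vapply(s$p_value, skullnet:::.s_tier, character(1))
  expect_equal(s$tier, recomputed)
})

test_that("both planted modules are significant in most seeds", {
  hits <- 0L
  n_seed <- 30
  for (seed in seq_len(n_seed)) {
    g <- generate_skull_network(n_pairs = 10, n_midline = 4, n_modules = 2,
                                p_in = 0.8, p_out = 0.05, seed = seed)
    mods <- skull_modules(g$network)
    s <- mods$s
    found <- vapply(1:2, function(mod) {
      target <- sort(names(g$membership)[g$membership == mod])
      any(s$p_value < 0.05 & vapply(strsplit(s$members, ","),
                                    function(mm) setequal(mm, target), logical(1)))
    }, logical(1))
    if (all(found)) hits <- hits + 1L
  }
  expect_gte(hits / n_seed, 0.9)
})

test_that("module analysis is deterministic: asymmetry can only come from tie-breaks", {
  # a bilaterally symmetric network may yield asymmetric modules, but reruns
  # must give byte-identical output
  g <- generate_skull_network(seed = 77)
  r1 <- module_report(g$network)
  r2 <- module_report(g$network)
  expect_identical(as.character(r1), as.character(r2))
})

test_that("module report JSON carries Q_max, modules and S-tiers", {
  net <- two_cliques()
  txt <- module_report(net)
  parsed <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  expect_equal(parsed$specimen, "two_cliques")
  expect_equal(length(parsed$modules), 2)
  expect_true(all(vapply(parsed$s_modules, function(s)
    s$tier %in% c("p<0.001", "0.001<=p<0.01", "0.01<=p<0.05", "ns"), logical(1))))
})
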