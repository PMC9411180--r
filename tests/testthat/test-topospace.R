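make_param_table <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(Taxon = sprintf("t%d", seq_len(n)),
             N = sample(30:57, n, TRUE),
             K = sample(60:130, n, TRUE),
             D = runif(n, 0.07, 0.16),
             C = runif(n, 0.2, 0.6),
             L = runif(n, 2.8, 4.8),
             H = runif(n, 0.3, 0.6),
             P = runif(n, 0.6, 0.87),
             stringsAsFactors = FALSE)
}

test_that("taxon-tree matching prunes, renames via synonyms and drops", {
  tab <- make_param_table(6)
  tree <- generate_pure_birth_tree(8, seed = 2)
  # t1..t4 match tips directly; t5 via congener synonym; t6 unmatched
  tab$Taxon <- c("t1", "t2", "t3", "t4", "sp_nova", "no_proxy")
  m <- match_taxa_to_tree(tab, tree,
                          synonyms = c(sp_nova = "t7", no_proxy = "drop"))
  expect_setequal(m$table$Taxon, c("t1", "t2", "t3", "t4", "sp_nova"))
  expect_setequal(m$tree$tip.label, m$table$Taxon)
  expect_equal(m$dropped, "no_proxy")
  expect_equal(m$table$Taxon, m$tree$tip.label) # aligned order
  # collision: two taxa on one tip
  expect_error(match_taxa_to_tree(tab, tree,
                                  synonyms = c(sp_nova = "t1", no_proxy = "drop")),
               "same tip")
  # identity match with equal labels
  tab2 <- make_param_table(5)
  tree2 <- generate_pure_birth_tree(5, seed = 3)
  tab2$Taxon <- tree2$tip.label
  m2 <- match_taxa_to_tree(tab2, tree2)
  expect_equal(length(m2$dropped), 0)
  # pruning down to 2 tips still yields a valid tree
  tab3 <- tab2[1:2, ]
  m3 <- match_taxa_to_tree(tab3, tree2)
  expect_equal(ape::Ntip(m3$tree), 2)
})

test_that("correlation PCA matches an SVD oracle and sums variance to 100", {
  tab <- make_param_table(20, seed = 4)
  ts <- topospace_pca(tab)
  x <- scale(as.matrix(tab[, -1]))
  sv <- svd(x)
  scores_oracle <- sv$u %*% diag(sv$d)
  for (j in seq_len(ncol(ts$scores))) {
    expect_lt(min(max(abs(ts$scores[, j] - scores_oracle[, j])),
                  max(abs(ts$scores[, j] + scores_oracle[, j]))), 1e-10)
  }
  expect_equal(sum(ts$variance_fraction), 100)
  expect_true(all(diff(ts$variance_fraction) <= 1e-12))
  expect_true(all(abs(colSums(ts$loadings^2) - 1) < 1e-12))
  # variance fractions against singular values
  expect_equal(ts$variance_fraction,
               100 * sv$d^2 / sum(sv$d^2), ignore_attr = TRUE)
})

test_that("PCA rejects constant columns by name and rank deficiency pools variance", {
  tab <- make_param_table(10)
  tab$H <- 0.5
  expect_error(topospace_pca(tab), "H")
  tab2 <- make_param_table(12, seed = 6)
  tab2$K <- 2 * tab2$N # perfectly correlated pair
  ts <- topospace_pca(tab2)
  # the redundant direction contributes no extra component at the tail
  expect_lt(ts$variance_fraction[7], 1e-8)
})

test_that("phylogenetic PCA equals ordinary PCA on an equal-branch star tree", {
  tab <- make_param_table(15, seed = 8)
  tree <- star_tree(15)
  tab$Taxon <- tree$tip.label
  pc <- topospace_pca(tab)
  pp <- topospace_ppca(tab, tree)
  dev <- max(abs(abs(pc$scores[rownames(pp$scores), ]) - abs(pp$scores)))
  expect_lt(dev, 1e-8)
  expect_equal(pp$variance_fraction, pc$variance_fraction, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("phylogenetic PCA matches a hand GLS computation on 3 taxa", {
  # tree ((t1:1,t2:1):1,t3:2); C = [[2,1,0],[1,2,0],[0,0,2]]
  tree <- ape::read.tree(text = "((t1:1,t2:1):1,t3:2);")
  x <- matrix(c(1, 2, 4,
                3, 1, 2), 3, 2, dimnames = list(c("t1", "t2", "t3"), c("u", "v")))
  tab <- data.frame(Taxon = rownames(x), u = x[, 1], v = x[, 2])
  pp <- topospace_ppca(tab, tree)
  cmat <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3)
  cinv <- solve(cmat)
  one <- rep(1, 3)
  a <- drop(solve(t(one) %*% cinv %*% one) %*% t(one) %*% cinv %*% x)
  cent <- sweep(x, 2, a)
  r <- t(cent) %*% cinv %*% cent / 2
  sds <- sqrt(diag(r))
  rc <- r / outer(sds, sds)
  eg <- eigen(rc, symmetric = TRUE)
  scores <- sweep(sweep(x, 2, sds, "/"), 2, a / sds) %*% eg$vectors
  for (j in 1:2) {
    expect_lt(min(max(abs(pp$scores[, j] - scores[, j])),
                  max(abs(pp$scores[, j] + scores[, j]))), 1e-10)
  }
  expect_equal(pp$variance_fraction, 100 * eg$values / sum(eg$values),
               ignore_attr = TRUE)
})

test_that("pPCA agrees with an independent phylogenetic PCA implementation", {
  skip_if_not_installed("phytools")
  tree <- generate_pure_birth_tree(12, seed = 9)
  tab <- simulate_bm_traits(tree, seed = 11)
  pp <- topospace_ppca(tab, tree)
  x <- as.matrix(tab[, -1]); rownames(x) <- tab$Taxon
  ref <- phytools::phyl.pca(tree, x, mode = "corr")
  dev <- max(abs(abs(ref$S[rownames(pp$scores), ]) - abs(pp$scores)))
  expect_lt(dev, 1e-8)
})

test_that("pPCA recovers a planted dominant axis from BM simulations", {
  tree <- generate_pure_birth_tree(25, seed = 15)
  set.seed(16)
  cors <- replicate(40, {
    sim <- simulate_bm_traits(tree, n_traits = 5)
    base <- stats::setNames(sim[, 2], sim$Taxon)
    noise <- as.matrix(sim[, 3:6])
    traits <- sweep(cbind(base, base, base, base), 2,
                    c(1, 0.9, 0.8, 0.7), "*") + 0.3 * noise
    tab <- data.frame(Taxon = sim$Taxon, traits)
    pp <- topospace_ppca(tab, tree)
    abs(stats::cor(pp$scores[, 1], base[rownames(pp$scores)]))
  })
  expect_gt(mean(cors), 0.9)
})

test_that("scores are stable under taxon reordering up to sign", {
  tab <- make_param_table(12, seed = 20)
  ts1 <- topospace_pca(tab)
  set.seed(1)
  tab2 <- tab[sample(nrow(tab)), ]
  ts2 <- topospace_pca(tab2)
  for (j in seq_len(7)) {
    s1 <- ts1$scores[tab$Taxon, j]; s2 <- ts2$scores[tab$Taxon, j]
    expect_lt(min(max(abs(s1 - s2)), max(abs(s1 + s2))), 1e-10)
  }
})

test_that("convex hull overlap matches a Monte-Carlo oracle", {
  set.seed(33)
  a <- cbind(runif(40, 0, 2), runif(40, 0, 2))
  b <- cbind(runif(40, 1, 3), runif(40, 1, 3))
  scores <- rbind(a, b)
  labels <- rep(c("g1", "g2"), each = 40)
  res <- convex_hull_overlap(scores, labels)
  in_hull <- function(P, hull) {
    n <- nrow(hull); ok <- rep(TRUE, nrow(P))
    for (k in seq_len(n)) {
      q1 <- hull[k, ]; q2 <- hull[(k %% n) + 1, ]
      ok <- ok & ((q2[1] - q1[1]) * (P[, 2] - q1[2]) -
                  (q2[2] - q1[2]) * (P[, 1] - q1[1]) >= -1e-12)
    }
    ok
  }
  h1 <- skullnet:::.hull_ccw(a); h2 <- skullnet:::.hull_ccw(b)
  gx <- seq(0, 3, length.out = 700)
  grid <- as.matrix(expand.grid(gx, gx))
  mc <- mean(in_hull(grid, h1) & in_hull(grid, h2)) * 9
  expect_equal(res$overlap$intersection_area, mc, tolerance = 0.02)
  # identical point sets: intersection equals the hull area
  res2 <- convex_hull_overlap(rbind(a, a), rep(c("x", "y"), each = 40))
  expect_equal(res2$overlap$intersection_area, unname(res2$areas["x"]))
  # separated clusters: zero intersection
  res3 <- convex_hull_overlap(rbind(a, a + 10), rep(c("x", "y"), each = 40))
  expect_equal(res3$overlap$intersection_area, 0)
  # degenerate group with 2 points
  res4 <- convex_hull_overlap(rbind(a, a[1:2, ]), c(rep("x", 40), "y", "y"))
  expect_true(res4$degenerate["y"])
  expect_equal(unname(res4$areas["y"]), 0)
})
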