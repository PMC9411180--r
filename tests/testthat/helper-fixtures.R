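# Small graphs and oracles shared across tests. All fixtures are built in
# code; nothing is read from disk except files the tests write themselves.

named_matrix <- function(n, labels = NULL) {
  if (is.null(labels)) labels <- sprintf("n%02d", seq_len(n))
  matrix(0, n, n, dimnames = list(labels, labels))
}

add_edges <- function(m, edges) {
  for (e in edges) m[e[1], e[2]] <- m[e[2], e[1]] <- 1
  m
}

path3 <- function() {
  m <- add_edges(named_matrix(3, c("A", "B", "C")),
                 list(c("A", "B"), c("B", "C")))
  anatomical_network(m, "path_ABC")
}

complete_net <- function(n, labels = NULL) {
  m <- named_matrix(n, labels)
  m[] <- 1; diag(m) <- 0
  anatomical_network(m, paste0("K", n))
}

# two k-cliques joined by `bridges` edges between them
two_cliques <- function(k = 4, bridges = 1) {
  lab <- c(paste0("a", seq_len(k)), paste0("b", seq_len(k)))
  m <- named_matrix(2 * k, lab)
  m[seq_len(k), seq_len(k)] <- 1
  m[k + seq_len(k), k + seq_len(k)] <- 1
  diag(m) <- 0
  for (b in seq_len(bridges)) m[b, k + b] <- m[k + b, b] <- 1
  anatomical_network(m, "two_cliques")
}

random_er_net <- function(n, p, seed = NULL, id = "er") {
  if (!is.null(seed)) set.seed(seed)
  m <- named_matrix(n)
  up <- which(upper.tri(m))
  m[up] <- as.integer(stats::runif(length(up)) < p)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  anatomical_network(m, id)
}

# independent Q oracle: accumulate over the edge list rather than block sums
q_oracle <- function(net, membership) {
  a <- net$adjacency
  k_tot <- sum(a) / 2
  edges <- which(a == 1 & upper.tri(a), arr.ind = TRUE)
  mods <- unique(membership)
  q <- 0
  deg <- rowSums(a)
  for (s in mods) {
    idx <- which(membership == s)
    e_ss <- sum(edges[, 1] %in% idx & edges[, 2] %in% idx) / k_tot
    a_s <- sum(deg[idx]) / (2 * k_tot)
    q <- q + e_ss - a_s^2
  }
  q
}

# all set partitions of 1..n as membership vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(max(prefix) + 1)) grow(c(prefix, v))
  }
  grow(1L)
  out
}

# exhaustive one-sided Mann-Whitney p (internal > external) by enumerating
# which of the m+n observations belong to the first sample
mw_oracle_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - m * (m + 1) / 2
  u_obs <- u_of(seq_len(m))
  combos <- utils::combn(m + n, m)
  mean(apply(combos, 2, u_of) >= u_obs)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

star_tree <- function(n, len = 1) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(len, nrow(tr$edge))
  tr
}
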