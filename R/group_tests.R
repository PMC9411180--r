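#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Tests whether groups of points occupy different regions of a
#' multivariate space, using Anderson's pseudo-F computed from the Euclidean
#' distance matrix of the coordinates:
#' `F = (SS_between / (a - 1)) / (SS_within / (n - a))`, with the total sum
#' of squares `sum(d_ij^2) / n` over all pairs and the within-group sums
#' computed analogously inside each group. Significance comes from free
#' (unrestricted) permutation of the group labels:
#' `p = (#\{F_perm >= F_obs\} + 1) / (n_perm + 1)`.
#'
#' @param scores numeric matrix (observations x coordinates), e.g. topospace
#'   component scores. By default all columns are used; for a full-rank PCA
#'   this is equivalent to testing the standardized parameters themselves.
#' @param labels group label per row; at least 2 groups of at least 2.
#' @param n_perm number of label permutations (default 10000).
#' @param seed optional integer seed for the permutation stream.
#' @return object of class `permanova`: `f_statistic`, `df_between`,
#'   `df_within`, `p_value`, `n_permutations`, `groups`, `seed`.
#' @references Anderson, M. J. (2001) A new method for non-parametric
#'   multivariate analysis of variance. Austral Ecology 26:32-46.
#' @export
permanova <- function(scores, labels, n_perm = 10000, seed = NULL) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  stopifnot(nrow(scores) == length(labels))
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(tab < 2)) {
    stop("every group needs at least 2 members; too small: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  n <- nrow(scores)
  a <- length(tab)
  d2 <- as.matrix(stats::dist(scores))^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  if (ss_total <= 0) stop("degenerate data: all points identical", call. = FALSE)

  f_for <- function(lab) {
    ss_within <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
  }
  f_obs <- f_for(labels)
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (f_for(sample(labels)) >= f_obs) exceed <- exceed + 1L
  }
  structure(list(f_statistic = f_obs,
                 df_between = a - 1L,
                 df_within = n - a,
                 p_value = (exceed + 1) / (n_perm + 1),
                 n_permutations = n_perm,
                 groups = names(tab),
                 seed = seed),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA [%s]: F_%d,%d = %.3f, p = %.4g (%d permutations)\n",
              paste(x$groups, collapse = " vs "),
              x$df_between, x$df_within, x$f_statistic, x$p_value,
              x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA
#'
#' Runs [permanova()] on every unordered pair of categories of a grouping
#' with three or more categories, each test restricted to the rows of that
#' pair. P-values are reported raw (no correction across pairs).
#'
#' @inheritParams permanova
#' @return list of `permanova` results, named `"g1 vs g2"`.
#' @export
pairwise_permanova <- function(scores, labels, n_perm = 10000, seed = NULL) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 3) {
    stop("pairwise PERMANOVA needs at least 3 categories; use permanova()",
         call. = FALSE)
  }
  pairs <- utils::combn(groups, 2)
  out <- vector("list", ncol(pairs))
  for (r in seq_len(ncol(pairs))) {
    keep <- labels %in% pairs[, r]
    out[[r]] <- permanova(scores[keep, , drop = FALSE], labels[keep],
                          n_perm = n_perm,
                          seed = if (is.null(seed)) NULL else seed + r)
  }
  names(out) <- apply(pairs, 2, paste, collapse = " vs ")
  out
}

#' Classify taxa into size classes from skull lengths
#'
#' Applies a two-threshold rule from a break in the skull-length
#' distribution: lengths at or below `lower` are `miniaturized`, at or above
#' `upper` are `non-miniaturized`, and lengths strictly inside the gap are
#' flagged `ambiguous`.
#'
#' @param lengths named numeric vector (names = taxa) or data.frame with
#'   columns `taxon` and `skull_length` (mm).
#' @param lower,upper thresholds in mm, `lower <= upper`.
#' @return data.frame with `taxon`, `skull_length`, `class`.
#' @export
classify_size <- function(lengths, lower, upper) {
  if (lower > upper) stop("`lower` must not exceed `upper`", call. = FALSE)
  if (is.data.frame(lengths)) {
    taxa <- lengths$taxon
    vals <- lengths$skull_length
  } else {
    taxa <- names(lengths)
    vals <- unname(lengths)
    if (is.null(taxa)) taxa <- as.character(seq_along(vals))
  }
  if (any(vals <= 0)) stop("skull lengths must be positive", call. = FALSE)
  cls <- ifelse(vals <= lower, "miniaturized",
                ifelse(vals >= upper, "non-miniaturized", "ambiguous"))
  data.frame(taxon = taxa, skull_length = vals, class = cls,
             stringsAsFactors = FALSE)
}

#' Find a break in a length distribution
#'
#' Sorts the values and locates the largest gap between consecutive values;
#' if it is at least `min_gap` the gap's endpoints are returned as candidate
#' (lower, upper) size-class thresholds.
#'
#' @param lengths numeric vector of at least 3 values.
#' @param min_gap minimum gap width (same units as `lengths`).
#' @return numeric vector `c(lower, upper)` delimiting the break, or an
#'   empty numeric vector when no gap reaches `min_gap`.
#' @export
find_distribution_break <- function(lengths, min_gap) {
  if (length(lengths) < 3) stop("need at least 3 values", call. = FALSE)
  s <- sort(lengths)
  gaps <- diff(s)
  i <- which.max(gaps)
  if (gaps[i] < min_gap) return(numeric(0))
  c(lower = s[i], upper = s[i + 1])
}
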