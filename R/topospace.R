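#' Match a parameter table to a phylogeny
#'
#' Aligns the taxa of a per-network parameter table with the tips of a dated
#' phylogeny before phylogenetic analyses. Each table taxon is matched to a
#' tip with the same label, or renamed through `synonyms` (e.g. to a congener
#' standing in for an unsampled species), or dropped when mapped to `"drop"`
#' or left unmatched. Tips not used by any table row are pruned.
#'
#' @param table data.frame with a `Taxon` column (e.g. from
#'   [read_parameter_table()]).
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param synonyms optional named character vector or two-column data.frame
#'   mapping table taxa to tip labels (or to `"drop"`).
#' @return list with `table` (matched rows, in tree tip order), `tree`
#'   (pruned tree whose tip labels are the table taxa) and `dropped`
#'   (character vector of unmatched table taxa).
#' @export
match_taxa_to_tree <- function(table, tree, synonyms = NULL) {
  stopifnot(is.data.frame(table), "Taxon" %in% names(table),
            inherits(tree, "phylo"))
  map <- stats::setNames(table$Taxon, table$Taxon)
  if (!is.null(synonyms)) {
    if (is.data.frame(synonyms)) {
      syn <- stats::setNames(as.character(synonyms[[2]]), as.character(synonyms[[1]]))
    } else {
      syn <- synonyms
    }
    hit <- names(syn)[names(syn) %in% names(map)]
    map[hit] <- syn[hit]
  }
  matched <- map %in% tree$tip.label & map != "drop"
  dropped <- names(map)[!matched]
  map <- map[matched]
  if (anyDuplicated(map)) {
    stop("two table taxa map to the same tip: ",
         paste(unique(map[duplicated(map)]), collapse = ", "), call. = FALSE)
  }
  pruned <- ape::keep.tip(tree, unname(map))
  # relabel tips back to the table's taxon ids
  back <- stats::setNames(names(map), map)
  pruned$tip.label <- unname(back[pruned$tip.label])
  tab <- table[table$Taxon %in% names(map), , drop = FALSE]
  tab <- tab[match(pruned$tip.label, tab$Taxon), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, tree = pruned, dropped = dropped)
}

# shared: extract the numeric parameter block (all columns except Taxon)
.param_matrix <- function(table) {
  stopifnot(is.data.frame(table), "Taxon" %in% names(table))
  x <- as.matrix(table[setdiff(names(table), "Taxon")])
  if (!is.numeric(x)) stop("parameter columns must be numeric", call. = FALSE)
  if (anyNA(x)) stop("parameter table must not contain missing cells", call. = FALSE)
  rownames(x) <- table$Taxon
  x
}

# deterministic sign convention: the largest-magnitude loading of each
# component is made positive
.fix_signs <- function(loadings, scores) {
  for (j in seq_len(ncol(loadings))) {
    s <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (s < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Ordinary PCA of a network parameter table (topospace)
#'
#' Principal component analysis on the correlation matrix of the per-taxon
#' parameters (variables standardized, as they are on different scales).
#' The component scores span the "topospace": a morphospace whose axes
#' summarize connectivity structure rather than shape.
#'
#' @param table data.frame with a `Taxon` column and numeric parameter
#'   columns (canonically `N, K, D, C, L, H, P`).
#' @return list of class `topospace`: `scores` (taxa x components),
#'   `loadings` (variables x components, unit columns), `variance_fraction`
#'   (percent of total variance per component, summing to 100) and
#'   `kind = "pca"`. Component signs are fixed by making each component's
#'   largest-magnitude loading positive.
#' @export
topospace_pca <- function(table) {
  x <- .param_matrix(table)
  if (nrow(x) < 3) stop("need at least 3 taxa for a PCA", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(colnames(x)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  fixed <- .fix_signs(pc$rotation, pc$x)
  structure(list(scores = fixed$scores,
                 loadings = fixed$loadings,
                 variance_fraction = 100 * ev / sum(ev),
                 kind = "pca"),
            class = "topospace")
}

#' Phylogenetic PCA of a network parameter table
#'
#' Phylogenetically corrected PCA under Brownian motion (Revell 2009),
#' in correlation mode since the parameters are on different scales.
#' With `C` the tree's shared branch-length matrix, the GLS ancestral mean is
#' `a = (1' C^-1 1)^-1 1' C^-1 X`; the evolutionary covariance
#' `R = (X - 1a)' C^-1 (X - 1a) / (n - 1)` is converted to a correlation
#' matrix, whose eigenvectors give the component loadings; scores are
#' `(X_std - 1 a_std) V` with columns standardized by the evolutionary
#' standard deviations. On a star phylogeny with equal branch lengths this
#' reduces exactly to [topospace_pca()] (up to column signs).
#'
#' @param table parameter table matched to `tree` (see
#'   [match_taxa_to_tree()]); rows must correspond to tip labels.
#' @param tree [ape::phylo] with positive branch lengths.
#' @return list of class `topospace` with `scores`, `loadings`,
#'   `variance_fraction`, `evolutionary_correlation` and `kind = "ppca"`.
#' @references Revell, L. J. (2009) Size-correction and principal components
#'   for interspecific comparative studies. Evolution 63:3258-3268.
#' @export
topospace_ppca <- function(table, tree) {
  x <- .param_matrix(table)
  stopifnot(inherits(tree, "phylo"))
  if (!setequal(rownames(x), tree$tip.label)) {
    stop("table taxa and tree tips must match; run match_taxa_to_tree() first",
         call. = FALSE)
  }
  x <- x[tree$tip.label, , drop = FALSE]
  n <- nrow(x)
  if (n < 3) stop("need at least 3 taxa", call. = FALSE)
  cmat <- ape::vcv.phylo(tree)
  cinv <- tryCatch(solve(cmat), error = function(e) {
    stop("singular phylogenetic covariance (zero or duplicated branch lengths?)",
         call. = FALSE)
  })
  one <- matrix(1, n, 1)
  gls_mean <- function(xx) {
    as.numeric(solve(t(one) %*% cinv %*% one) %*% t(one) %*% cinv %*% xx)
  }
  a <- gls_mean(x)
  centred <- sweep(x, 2, a)
  r_evol <- t(centred) %*% cinv %*% centred / (n - 1)
  sds <- sqrt(diag(r_evol))
  if (any(sds == 0)) {
    stop("constant column(s) under the evolutionary model: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  x_std <- sweep(x, 2, sds, "/")
  a_std <- a / sds
  r_corr <- r_evol / outer(sds, sds)
  eig <- eigen(r_corr, symmetric = TRUE)
  v <- eig$vectors
  dimnames(v) <- list(colnames(x), paste0("pPC", seq_len(ncol(v))))
  scores <- sweep(x_std, 2, a_std) %*% v
  colnames(scores) <- colnames(v)
  fixed <- .fix_signs(v, scores)
  structure(list(scores = fixed$scores,
                 loadings = fixed$loadings,
                 variance_fraction = 100 * eig$values / sum(eig$values),
                 evolutionary_correlation = r_corr,
                 kind = "ppca"),
            class = "topospace")
}

#' @export
print.topospace <- function(x, ...) {
  cat(sprintf("Topospace (%s): %d taxa, %d components\n",
              x$kind, nrow(x$scores), ncol(x$scores)))
  vf <- x$variance_fraction
  cat("  variance: ",
      paste(sprintf("%s %.2f%%", colnames(x$scores)[seq_len(min(3, length(vf)))],
                    vf[seq_len(min(3, length(vf)))]), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write topospace scores or loadings as TSV
#'
#' @param ts a `topospace` result.
#' @param path output path.
#' @param what `"scores"` or `"loadings"`.
#' @return `path`, invisibly.
#' @export
write_topospace <- function(ts, path, what = c("scores", "loadings")) {
  what <- match.arg(what)
  m <- ts[[what]]
  df <- cbind(data.frame(id = rownames(m), kind = ts$kind, stringsAsFactors = FALSE),
              as.data.frame(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- convex hulls ---------------------------------------------------------

# area of a polygon given in order (shoelace); 0 for < 3 vertices
.polygon_area <- function(p) {
  if (is.null(p) || nrow(p) < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Sutherland-Hodgman clipping of convex polygon `subject` by convex polygon
# `clip` (both counter-clockwise)
.clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0) return(NULL)
    a <- clip[e, ]; b <- clip[(e %% nc) + 1, ]
    inside <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) >= -1e-12
    intersect_pt <- function(p, q) {
      d1 <- c(q[1] - p[1], q[2] - p[2])
      d2 <- c(b[1] - a[1], b[2] - a[2])
      denom <- d1[1] * d2[2] - d1[2] * d2[1]
      t <- ((a[1] - p[1]) * d2[2] - (a[2] - p[2]) * d2[1]) / denom
      p + t * d1
    }
    res <- matrix(numeric(0), ncol = 2)
    np <- nrow(out)
    for (i in seq_len(np)) {
      p <- out[i, ]; q <- out[(i %% np) + 1, ]
      pin <- inside(p); qin <- inside(q)
      if (pin && qin) {
        res <- rbind(res, q)
      } else if (pin && !qin) {
        res <- rbind(res, intersect_pt(p, q))
      } else if (!pin && qin) {
        res <- rbind(res, intersect_pt(p, q), q)
      }
    }
    out <- res
  }
  out
}

# counter-clockwise convex hull vertices of a 2-column matrix
.hull_ccw <- function(xy) {
  p <- xy[grDevices::chull(xy), , drop = FALSE]
  x <- p[, 1]; y <- p[, 2]
  signed <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  if (signed < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  p
}

#' Convex-hull areas and pairwise overlap in topospace
#'
#' Computes, on a chosen pair of component axes, the 2-D convex hull of each
#' group's scores and the area of intersection of every pair of hulls.
#' Groups with fewer than 3 points have a degenerate hull of area 0.
#'
#' @param scores numeric matrix of component scores (taxa x components).
#' @param labels group label per row of `scores`.
#' @param axes length-2 integer vector of component indices (default `c(1, 2)`).
#' @return list with `areas` (named numeric vector of hull areas; degenerate
#'   hulls are 0 and flagged in `degenerate`), `overlap` (data.frame of
#'   `group1, group2, intersection_area`), and `degenerate`.
#' @export
convex_hull_overlap <- function(scores, labels, axes = c(1, 2)) {
  stopifnot(length(axes) == 2, nrow(scores) == length(labels))
  xy <- scores[, axes, drop = FALSE]
  groups <- sort(unique(as.character(labels)))
  hulls <- lapply(groups, function(g) {
    p <- xy[labels == g, , drop = FALSE]
    if (nrow(p) < 3) return(NULL)
    .hull_ccw(p)
  })
  names(hulls) <- groups
  areas <- vapply(hulls, .polygon_area, numeric(1))
  degenerate <- vapply(hulls, is.null, logical(1))
  pairs <- utils::combn(groups, 2)
  overlap <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                        intersection_area = NA_real_, stringsAsFactors = FALSE)
  for (r in seq_len(ncol(pairs))) {
    h1 <- hulls[[pairs[1, r]]]; h2 <- hulls[[pairs[2, r]]]
    overlap$intersection_area[r] <-
      if (is.null(h1) || is.null(h2)) 0 else .polygon_area(.clip_convex(h1, h2))
  }
  list(areas = areas, overlap = overlap, degenerate = degenerate)
}
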