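#' Run configuration for the analysis pipeline
#'
#' Validates the tunable knobs shared by the pipeline commands before any
#' computation starts.
#'
#' @param gtom_steps GTOM neighbourhood order (integer >= 1).
#' @param clustering treatment of degree-0/1 nodes in the mean clustering
#'   coefficient: `"exclude-low-degree"` or `"zero-low-degree"`.
#' @param hetero_sd standard deviation convention for heterogeneity:
#'   `"sample"` or `"population"`.
#' @param permutations PERMANOVA permutation count.
#' @param seed integer RNG seed (or NULL).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(gtom_steps = 1,
                       clustering = c("exclude-low-degree", "zero-low-degree"),
                       hetero_sd = c("sample", "population"),
                       permutations = 10000, seed = NULL) {
  clustering <- match.arg(clustering)
  hetero_sd <- match.arg(hetero_sd)
  gtom_steps <- as.integer(gtom_steps)
  permutations <- as.integer(permutations)
  if (is.na(gtom_steps) || gtom_steps < 1) stop("gtom_steps must be >= 1", call. = FALSE)
  if (is.na(permutations) || permutations < 1) stop("permutations must be >= 1", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(gtom_steps = gtom_steps, clustering = clustering,
                 hetero_sd = hetero_sd, permutations = permutations,
                 seed = seed),
            class = "run_config")
}

# write a machine-readable record of inputs/config sufficient to reproduce a run
.write_manifest <- function(out_dir, command, inputs, config, outputs) {
  manifest <- list(
    command = command,
    inputs = inputs,
    config = unclass(config),
    outputs = outputs,
    package_version = as.character(utils::packageVersion("skullnet")),
    r_version = R.version.string
  )
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' Compute parameter tables for a batch of adjacency files
#'
#' Reads each adjacency file, computes the seven whole-network parameters
#' and collects them into one table (one row per specimen). Files that fail
#' validation are skipped and reported; the table still contains the valid
#' rows.
#'
#' @param inputs character vector of adjacency file paths.
#' @param out optional TSV output path (written with
#'   [write_parameter_table()]).
#' @param config a [run_config()].
#' @return list with `table` (data.frame), `failures` (named character
#'   vector of error messages, empty on full success).
#' @export
cmd_params <- function(inputs, out = NULL, config = run_config()) {
  if (length(inputs) < 1) stop("need at least one input file", call. = FALSE)
  low_degree <- if (config$clustering == "exclude-low-degree") "exclude" else "zero"
  rows <- list()
  failures <- character()
  for (f in inputs) {
    res <- tryCatch({
      net <- read_adjacency(f)
      network_parameters(net, low_degree = low_degree, sd_type = config$hetero_sd)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures[f] <- res
      message("skipping ", f, ": ", res)
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  tab <- if (length(rows) > 0) do.call(rbind, rows) else
    stop("no input file produced a valid network", call. = FALSE)
  if (!is.null(out)) {
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    write_parameter_table(tab, out)
    .write_manifest(dirname(out), "params", as.list(inputs), config, basename(out))
  }
  list(table = tab, failures = failures)
}

#' Module analysis of one adjacency file
#'
#' Runs the GTOM/UPGMA/Q-module/S-module chain on a single network and
#' writes the dendrogram (Newick) and JSON module report.
#'
#' @param input adjacency file path.
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @return the [skull_modules()] result, invisibly.
#' @export
cmd_modules <- function(input, out_dir, config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- read_adjacency(input)
  mods <- skull_modules(net, gtom_steps = config$gtom_steps)
  base <- tools::file_path_sans_ext(basename(input))
  nwk <- file.path(out_dir, paste0(base, "_dendrogram.nwk"))
  rep_path <- file.path(out_dir, paste0(base, "_modules.json"))
  dendrogram_newick(mods$dendrogram, nwk)
  module_report(net, mods, rep_path)
  .write_manifest(out_dir, "modules", input, config, basename(c(nwk, rep_path)))
  invisible(mods)
}

#' Topospace projection and group tests
#'
#' Projects a parameter table into topospace by correlation PCA and, when a
#' tree is supplied, by phylogenetic PCA after taxon matching; then tests
#' every grouping column with PERMANOVA (adding pairwise PERMANOVA for
#' groupings with more than two categories). Score tables and a JSON record
#' of every test (including seed and permutation count) are written when
#' `out_dir` is given.
#'
#' @param params parameter table path or data.frame (columns
#'   `Taxon, N, K, D, C, L, H, P`).
#' @param groupings grouping table path or data.frame (column `taxon` plus
#'   grouping columns).
#' @param tree optional Newick path or [ape::phylo]; when absent the
#'   phylogenetic PCA is skipped with a notice.
#' @param synonyms optional taxon-to-tip map for [match_taxa_to_tree()].
#' @param out_dir optional output directory.
#' @param config a [run_config()].
#' @return list with `pca`, `ppca` (NULL without a tree), `dropped`
#'   (taxa unmatched to the tree), and `tests` (nested list of PERMANOVA
#'   results per analysis kind and grouping).
#' @export
cmd_topospace <- function(params, groupings, tree = NULL, synonyms = NULL,
                          out_dir = NULL, config = run_config()) {
  tab <- if (is.character(params)) read_parameter_table(params) else params
  grp <- if (is.character(groupings)) read_grouping_table(groupings) else groupings
  if (!"taxon" %in% names(grp)) stop("groupings need a 'taxon' column", call. = FALSE)
  if (is.character(tree)) tree <- ape::read.tree(tree)

  pca <- topospace_pca(tab)
  ppca <- NULL
  dropped <- character()
  if (!is.null(tree)) {
    matched <- match_taxa_to_tree(tab, tree, synonyms)
    dropped <- matched$dropped
    if (nrow(matched$table) < 3) {
      stop("fewer than 3 taxa matched to the tree", call. = FALSE)
    }
    ppca <- topospace_ppca(matched$table, matched$tree)
  } else {
    message("no tree supplied: phylogenetic PCA skipped")
  }

  group_cols <- setdiff(names(grp), "taxon")
  run_tests <- function(ts) {
    scores <- ts$scores
    labels_all <- grp[match(rownames(scores), grp$taxon), , drop = FALSE]
    out <- list()
    for (gc in group_cols) {
      lab <- labels_all[[gc]]
      keep <- !is.na(lab)
      res <- list(omnibus = permanova(scores[keep, , drop = FALSE], lab[keep],
                                      n_perm = config$permutations,
                                      seed = config$seed))
      if (length(unique(lab[keep])) > 2) {
        res$pairwise <- pairwise_permanova(scores[keep, , drop = FALSE], lab[keep],
                                           n_perm = config$permutations,
                                           seed = config$seed)
      }
      out[[gc]] <- res
    }
    out
  }
  tests <- list(pca = run_tests(pca))
  if (!is.null(ppca)) tests$ppca <- run_tests(ppca)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_topospace(pca, file.path(out_dir, "pca_scores.tsv"), "scores")
    if (!is.null(ppca)) {
      write_topospace(ppca, file.path(out_dir, "ppca_scores.tsv"), "scores")
    }
    flatten <- function(x) {
      if (inherits(x, "permanova")) unclass(x) else lapply(x, flatten)
    }
    jsonlite::write_json(flatten(tests), file.path(out_dir, "permanova.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    .write_manifest(out_dir, "topospace",
                    list(params = if (is.character(params)) params else "in-memory",
                         groupings = if (is.character(groupings)) groupings else "in-memory"),
                    config,
                    c("pca_scores.tsv",
                      if (!is.null(ppca)) "ppca_scores.tsv", "permanova.json"))
  }
  list(pca = pca, ppca = ppca, dropped = dropped, tests = tests)
}
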