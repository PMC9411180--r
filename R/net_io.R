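#' Read a bone-articulation adjacency matrix
#'
#' Reads a square binary adjacency matrix from a delimited text file. The
#' first row and first column must carry the same bone labels in the same
#' order; entries must be 0 or 1, the matrix symmetric with a zero diagonal.
#'
#' @param path path to the file.
#' @param dialect `"auto"` (default; decided from the file extension, falling
#'   back to comma), `"csv"` or `"tsv"`. Spreadsheet (`"xlsx"`) input is not
#'   supported; export such workbooks to CSV first.
#' @param specimen_id label for the resulting network; defaults to the file
#'   name without extension.
#' @return a validated [anatomical_network()].
#' @export
read_adjacency <- function(path, dialect = c("auto", "csv", "tsv", "xlsx"),
                           specimen_id = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "xlsx") {
    stop("xlsx input is not supported; export the workbook sheet to CSV/TSV",
         call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- switch(dialect,
                csv = ",",
                tsv = "\t",
                auto = if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE)) "\t" else ",")
  raw <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  m <- as.matrix(raw)
  if (!is.numeric(m)) {
    stop("non-numeric entry in adjacency matrix of ", path, call. = FALSE)
  }
  if (is.null(specimen_id)) {
    specimen_id <- tools::file_path_sans_ext(basename(path))
  }
  anatomical_network(m, specimen_id)
}

#' Write a bone-articulation adjacency matrix
#'
#' Inverse of [read_adjacency()]: `read_adjacency(write_adjacency(net, f))`
#' reproduces `net` bit-exactly.
#'
#' @param net an `anatomical_network`
#' @param path output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(net, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  df <- as.data.frame(net$adjacency, check.names = FALSE)
  utils::write.table(cbind(data.frame(" " = rownames(df), check.names = FALSE), df),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-taxon network parameter table
#'
#' Serializes rows of whole-network parameters to TSV in the canonical column
#' order `Taxon, N, K, D, C, L, H, P`, with the five real-valued parameters
#' rendered to 4 decimal places.
#'
#' @param rows data.frame with columns `Taxon, N, K, D, C, L, H, P` (as
#'   produced by [network_parameters()] / [cmd_params()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_parameter_table()]
#' @export
write_parameter_table <- function(rows, path) {
  cols <- c("Taxon", "N", "K", "D", "C", "L", "H", "P")
  if (!is.data.frame(rows) || nrow(rows) == 0) {
    stop("`rows` must be a non-empty data.frame of network parameters", call. = FALSE)
  }
  if (!all(cols %in% names(rows))) {
    stop("parameter table must contain columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(rows$Taxon)) {
    stop("duplicate taxon ids: ",
         paste(unique(rows$Taxon[duplicated(rows$Taxon)]), collapse = ", "),
         call. = FALSE)
  }
  out <- rows[, cols]
  for (cc in c("D", "C", "L", "H", "P")) out[[cc]] <- sprintf("%.4f", out[[cc]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-taxon network parameter table
#'
#' @param path TSV file in the layout written by [write_parameter_table()].
#' @return data.frame with columns `Taxon, N, K, D, C, L, H, P`.
#' @export
read_parameter_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("Taxon", "N", "K", "D", "C", "L", "H", "P")
  if (!all(need %in% names(tab))) {
    stop("parameter table must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$Taxon)) stop("duplicate taxon ids in ", path, call. = FALSE)
  tab[need]
}

# Closed vocabularies for the grouping table. `habitat` distinguishes truly
# burrowing taxa from leaf-litter/loose-soil taxa and surface taxa; `size_class`
# follows a break-in-distribution skull-length threshold; `combined_class`
# crosses the two endpoint categories.
.habitat_levels <- c("fossorial", "semi-fossorial", "non-fossorial")
.size_levels <- c("miniaturized", "non-miniaturized")
.combined_levels <- c("min-foss", "non-min-non-foss", "mixed")

#' Read a per-taxon grouping table
#'
#' Reads categorical groupings used for topospace hypothesis tests. Expected
#' columns: `taxon` plus any of `higher_taxon`, `jaw_morphotype`, `habitat`,
#' `size_class`, `combined_class`. The habitat, size and combined columns are
#' validated against their closed vocabularies
#' (`fossorial|semi-fossorial|non-fossorial`,
#' `miniaturized|non-miniaturized`, `min-foss|non-min-non-foss|mixed`).
#'
#' @param path TSV file.
#' @return data.frame keyed by `taxon`.
#' @export
read_grouping_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"taxon" %in% names(tab)) stop("grouping table needs a 'taxon' column", call. = FALSE)
  if (anyNA(tab$taxon) || anyDuplicated(tab$taxon)) {
    stop("taxon ids must be present and unique", call. = FALSE)
  }
  check_vocab <- function(col, levels) {
    if (col %in% names(tab)) {
      bad <- setdiff(unique(tab[[col]]), levels)
      if (length(bad) > 0) {
        stop(sprintf("invalid %s value(s): %s (allowed: %s)", col,
                     paste(bad, collapse = ", "), paste(levels, collapse = ", ")),
             call. = FALSE)
      }
    }
  }
  check_vocab("habitat", .habitat_levels)
  check_vocab("size_class", .size_levels)
  check_vocab("combined_class", .combined_levels)
  if (anyNA(tab)) stop("grouping table must not contain missing values", call. = FALSE)
  tab
}
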