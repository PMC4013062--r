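#' Read a log2 expression matrix from TSV
#'
#' Expects a tab-separated file whose header row holds sample IDs and whose
#' first column holds feature IDs (transcript clusters, probesets, exons, or
#' genes). All values must be finite numbers; feature and sample IDs must be
#' unique; every row must have the same number of fields.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix, features x samples, with dimnames.
#' @export
read_expression <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) == 0) abort("expression file '%s' is empty", path)
  if (length(unique(nf)) != 1)
    abort("ragged expression file: row %d has %d fields, expected %d",
          which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1])
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2) abort("expression file needs a feature column and >=1 sample")
  feat <- as.character(df[[1]])
  if (anyDuplicated(feat))
    abort("duplicate feature ID: '%s'", feat[duplicated(feat)][1])
  sids <- colnames(df)[-1]
  if (anyDuplicated(sids))
    abort("duplicate sample ID: '%s'", sids[duplicated(sids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) &
                   !is.na(m), arr.ind = TRUE)[1, ]
    abort("non-numeric expression value at feature '%s', sample '%s'",
          feat[bad[1]], sids[bad[2]])
  }
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    abort("non-finite expression value at feature '%s', sample '%s'",
          feat[bad[1]], sids[bad[2]])
  }
  rownames(m) <- feat
  m
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]; numbers are written with 15 significant
#' digits so a read/write round trip is value-preserving.
#'
#' @param mat Numeric matrix with feature rownames and sample colnames.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pheno_required_cols <- c("sample_id", "pedigree_id", "af_group", "age", "sex")

#' Read a phenotype table from CSV
#'
#' Validates the per-sample phenotype table: mandatory columns
#' (`sample_id`, `pedigree_id`, `af_group`, `age`, `sex`), unique sample
#' IDs, `af_group` in \{none, prevalent, incident\}, `event = 1` only for
#' incident samples, and non-missing `followup_time` for all non-prevalent
#' samples (when survival columns are present).
#'
#' @param path Path to the CSV file.
#' @return A validated `data.frame`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_phenotypes(df)
}

#' @rdname read_phenotypes
#' @param df A phenotype `data.frame` to validate in place.
#' @export
validate_phenotypes <- function(df) {
  missing <- setdiff(pheno_required_cols, colnames(df))
  if (length(missing))
    abort("phenotype table lacks mandatory column(s): %s",
          paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    abort("duplicate sample_id: '%s'", df$sample_id[duplicated(df$sample_id)][1])
  bad <- setdiff(unique(df$af_group), c("none", "prevalent", "incident"))
  if (length(bad))
    abort("invalid af_group value(s): %s", paste(bad, collapse = ", "))
  if ("event" %in% colnames(df)) {
    if (any(df$event == 1 & df$af_group != "incident", na.rm = TRUE))
      abort("event = 1 found outside the incident-AF group")
    if ("followup_time" %in% colnames(df) &&
        any(is.na(df$followup_time) & df$af_group != "prevalent"))
      abort("followup_time missing for non-prevalent sample(s)")
  }
  df
}

#' Write a phenotype table to CSV
#' @param df Phenotype `data.frame`.
#' @param path Output path.
#' @export
write_phenotypes <- function(df, path) {
  utils::write.csv(validate_phenotypes(df), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a protein-protein interaction network
#'
#' Reads an undirected PPI graph from either a two-column tab-separated
#' edge list (`format = "tsv"`) or a SIF file (`format = "sif"`; each line
#' `node relation target1 target2 ...` yields one edge per target, and a
#' line with a single token declares an isolated node). The result is a
#' simple graph: duplicate edges (in either orientation) are collapsed and
#' self-loops are dropped with a warning reporting the count. An empty file
#' yields an empty network.
#'
#' @param path Path to the network file.
#' @param format `"tsv"` or `"sif"`.
#' @return An undirected, simple, named `igraph` object.
#' @export
read_network <- function(path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(igraph::make_empty_graph(0, directed = FALSE))
  if (format == "tsv") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- lengths(parts) < 2L
    if (any(short))
      abort("network TSV line %d has fewer than 2 columns", which(short)[1])
    from <- vapply(parts, `[[`, "", 1L)
    to <- vapply(parts, `[[`, "", 2L)
    iso <- character(0)
  } else {
    parts <- strsplit(lines, "[ \t]+")
    iso <- unlist(lapply(parts[lengths(parts) == 1L], `[[`, 1L))
    edged <- parts[lengths(parts) >= 3L]
    from <- rep(vapply(edged, `[[`, "", 1L),
                vapply(edged, function(x) length(x) - 2L, 0L))
    to <- unlist(lapply(edged, function(x) x[-(1:2)]))
    if (is.null(to)) to <- character(0)
  }
  build_network(from, to, isolated = iso)
}

# Assemble a simple undirected graph from parallel endpoint vectors,
# dropping self-loops (warned, with count) and duplicate edges.
build_network <- function(from, to, isolated = character(0)) {
  loops <- from == to
  if (any(loops)) {
    warning(sprintf("%d self-loop%s removed", sum(loops),
                    if (sum(loops) == 1) "" else "s"), call. = FALSE)
    isolated <- c(isolated, from[loops])
    from <- from[!loops]
    to <- to[!loops]
  }
  nodes <- unique(c(from, to, isolated))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  igraph::simplify(g)
}

#' Write a network as a two-column edge-list TSV
#' @param graph An `igraph` object (treated as undirected).
#' @param path Output path.
#' @export
write_network <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  utils::write.table(data.frame(gene_a = el[, 1], gene_b = el[, 2]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each GMT line is `name<TAB>description<TAB>member1<TAB>member2...`.
#' Set names must be unique and member lists non-empty.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_collection`: a named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("GMT file '%s' is empty", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short))
    abort("GMT line %d has no member genes", which(short)[1])
  nms <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nms))
    abort("duplicate gene-set name: '%s'", nms[duplicated(nms)][1])
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- nms
  structure(sets, descriptions = vapply(parts, `[[`, "", 2L),
            class = "gene_set_collection")
}

#' Write gene sets in GMT format
#' @param sets A `gene_set_collection` or named list of character vectors.
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d\n", length(x),
              min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Write / read per-feature association results
#'
#' Results are written as TSV with the fixed column order `feature_id`,
#' `effect`, `se`, `p`, `q` (any further columns, e.g. `n_used` or `note`,
#' follow). Numbers carry 15 significant digits, so a write/read round trip
#' preserves them.
#'
#' @param results An association result `data.frame` (see [fit_prevalent()]).
#' @param path File path.
#' @export
write_results <- function(results, path) {
  lead <- c("feature_id", "effect", "se", "p", "q")
  missing <- setdiff(lead, colnames(results))
  if (length(missing))
    abort("results lack column(s): %s", paste(missing, collapse = ", "))
  results <- results[, c(lead, setdiff(colnames(results), lead)), drop = FALSE]
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(feature_id = "character"))
}

#' Read a feature-to-gene mapping table
#'
#' Two-column TSV (`feature_id`, `gene_id`) used to collapse expression
#' features (e.g. probesets or transcript clusters) onto the gene symbols of
#' the PPI network before scoring.
#'
#' @param path Path to the mapping TSV.
#' @return `data.frame` with columns `feature_id` and `gene_id`.
#' @export
read_feature_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) abort("feature map needs two columns")
  colnames(df)[1:2] <- c("feature_id", "gene_id")
  df[, 1:2]
}
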