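#' Read and write FASTA
#'
#' Thin wrappers over Biostrings for nucleotide and protein FASTA.
#'
#' @param x Named [Biostrings::DNAStringSet]/[Biostrings::AAStringSet] or
#'   named character vector.
#' @param path File path.
#' @param type `"dna"` or `"aa"`.
#' @name fasta_io
#' @export
write_fasta <- function(x, path, type = c("dna", "aa")) {
  type <- match.arg(type)
  set <- if (methods::is(x, "XStringSet")) x
  else if (type == "dna") Biostrings::DNAStringSet(x)
  else Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname fasta_io
#' @export
read_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  if (type == "dna") Biostrings::readDNAStringSet(path) else
    Biostrings::readAAStringSet(path)
}

#' Read and write a numeric matrix as TSV
#'
#' First column `gene` holds row names; the header holds sample ids.
#'
#' @param m Matrix with row and column names.
#' @param path File path.
#' @name matrix_io
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname matrix_io
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write a two-column gene-to-term annotation map as TSV
#'
#' @param map Data frame `gene`, `term`.
#' @param path File path.
#' @name annotation_io
#' @export
write_annotation_tsv <- function(map, path) {
  write.table(map[, c("gene", "term")], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname annotation_io
#' @export
read_annotation_tsv <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("gene", "term")
  df
}

#' Write a cluster set as a two-column TSV (representative, member)
#'
#' @param cs A `cluster_set` from [remove_redundancy()].
#' @param path File path.
#' @export
write_cluster_tsv <- function(cs, path) {
  rows <- do.call(rbind, lapply(names(cs$clusters), function(r)
    data.frame(representative = r, member = cs$clusters[[r]],
               stringsAsFactors = FALSE)))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a correlation graph as GraphML and as an edge-list TSV
#'
#' @param g An [igraph] graph from [build_graph()].
#' @param path_graphml,path_edges Output paths (either may be `NULL`).
#' @export
write_graph_files <- function(g, path_graphml = NULL, path_edges = NULL) {
  if (!is.null(path_graphml)) igraph::write_graph(g, path_graphml,
                                                  format = "graphml")
  if (!is.null(path_edges)) {
    ends <- igraph::as_edgelist(g)
    df <- data.frame(from = ends[, 1L], to = ends[, 2L],
                     r = igraph::E(g)$weight, stringsAsFactors = FALSE)
    write.table(df, path_edges, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
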