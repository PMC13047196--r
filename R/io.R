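# Readers and writers for the three standard inputs (OTU table, metadata,
# tree) and shared validation. Dialect: tab-separated UTF-8 text, '.'
# decimal, first column = sample id; trees are Newick.

validate_counts <- function(counts) {
  if (is.null(dim(counts)) || nrow(counts) < 2 || ncol(counts) < 2) {
    stop("format error: count table needs at least 2 samples and 2 taxa")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    stop("format error: duplicate sample id: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- unique(colnames(counts)[duplicated(colnames(counts))])
    stop("format error: duplicate taxon id: ", paste(dup, collapse = ", "))
  }
  if (any(!is.finite(counts))) stop("format error: non-finite counts")
  if (any(counts < 0)) stop("format error: negative counts")
  if (any(counts != round(counts))) stop("format error: non-integer counts")
  invisible(counts)
}

#' Read an OTU count table
#'
#' Tab-separated text, header row of taxon ids, first column sample ids.
#' Malformed input (duplicate ids, negative or non-integer counts) is
#' rejected rather than coerced.
#'
#' @param path Path to a TSV file.
#' @return Integer matrix (samples x taxa) with dimnames.
#' @export
read_count_table <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("format error: expected sample id column plus >= 2 taxa")
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("format error: non-numeric counts")
  rownames(m) <- ids
  validate_counts(m)
  storage.mode(m) <- "integer"
  m
}

#' Write an OTU count table
#' @param counts Samples x taxa matrix.
#' @param path Output TSV path.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' @param path Path to a TSV with a \code{sample_id} column.
#' @return data.frame keyed by \code{sample_id}.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("format error: metadata must have a 'sample_id' column")
  }
  if (anyDuplicated(df$sample_id)) {
    dup <- unique(df$sample_id[duplicated(df$sample_id)])
    stop("format error: duplicate sample id: ", paste(dup, collapse = ", "))
  }
  env_cols <- setdiff(names(df), c("sample_id", "group", "stage", "replicate"))
  num <- vapply(df[env_cols], is.numeric, logical(1))
  if (any(!num)) stop("format error: non-numeric metadata column: ",
                      paste(env_cols[!num], collapse = ", "))
  if (any(!vapply(df[env_cols], function(x) all(is.finite(x)), logical(1)))) {
    stop("format error: non-finite metadata values")
  }
  rownames(df) <- df$sample_id
  df
}

#' Write a sample metadata table
#' @param metadata data.frame with a \code{sample_id} column.
#' @param path Output TSV path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a rooted phylogeny (Newick)
#'
#' Thin wrappers over \code{ape} that additionally check rooting and branch
#' lengths.
#'
#' @param path Newick file path.
#' @return A \code{phylo} object.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("format error: tree must have non-negative branch lengths")
  }
  if (!ape::is.rooted(tree)) stop("format error: tree must be rooted")
  tree
}

#' @rdname read_tree
#' @param tree A \code{phylo} object.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Align a count table and metadata by sample id
#'
#' Checks the two sample id sets match and reorders the metadata into count
#' table order; mismatches abort with the offending ids named. Taxa missing
#' from a supplied tree are reported via message.
#'
#' @param counts Samples x taxa matrix.
#' @param metadata Metadata data.frame.
#' @param tree Optional phylogeny to cross-check taxon coverage.
#' @return The metadata reordered to match \code{rownames(counts)}.
#' @export
align_samples <- function(counts, metadata, tree = NULL) {
  missing_meta <- setdiff(rownames(counts), metadata$sample_id)
  extra_meta <- setdiff(metadata$sample_id, rownames(counts))
  if (length(missing_meta) || length(extra_meta)) {
    stop("alignment error: samples without metadata: [",
         paste(missing_meta, collapse = ", "), "]; metadata without counts: [",
         paste(extra_meta, collapse = ", "), "]")
  }
  if (!is.null(tree)) {
    absent <- setdiff(colnames(counts), tree$tip.label)
    if (length(absent)) {
      message(length(absent), " taxa absent from the tree: ",
              paste(utils::head(absent, 5), collapse = ", "),
              if (length(absent) > 5) ", ..." else "")
    }
  }
  metadata[rownames(counts), , drop = FALSE]
}

#' Relative abundances per sample
#'
#' @param counts Samples x taxa matrix with strictly positive row sums.
#' @return Real matrix whose rows each sum to 1.
#' @export
relative_abundance <- function(counts) {
  rs <- rowSums(counts)
  if (any(rs <= 0)) {
    bad <- rownames(counts)[rs <= 0]
    if (is.null(bad)) bad <- which(rs <= 0)
    stop("degenerate sample (zero total count): ", paste(bad, collapse = ", "))
  }
  sweep(counts, 1, rs, "/")
}
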