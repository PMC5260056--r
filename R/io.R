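#' Coerce to a validated expression matrix
#'
#' An expression matrix is a numeric genes-by-conditions matrix with unique
#' gene rownames. Inference additionally requires at least 2 genes and 3
#' conditions.
#'
#' @param x Numeric matrix or data frame.
#' @param for_inference Enforce the minimum size for inference.
#' @return Numeric matrix with rownames.
#' @export
as_expression_matrix <- function(x, for_inference = TRUE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression data must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x))) {
    rownames(x) <- paste0("G", seq_len(nrow(x)))
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at gene '%s', condition %d",
                 rownames(x)[bad[1L]], bad[2L]), call. = FALSE)
  }
  if (for_inference && (nrow(x) < 2L || ncol(x) < 3L)) {
    stop("inference requires >= 2 genes and >= 3 conditions", call. = FALSE)
  }
  x
}

#' Read an expression matrix from tab-separated text
#'
#' Expects one header row and one label column; `#`-prefixed lines are
#' ignored. With `orientation = "samples"` (the DREAM layout, samples in
#' rows and genes in columns) the parsed table is transposed so the result
#' is always genes x conditions.
#'
#' @param path Path to a TSV file.
#' @param orientation `"genes"` (genes in rows, default) or `"samples"`.
#' @return Expression matrix, genes in rows.
#' @export
read_expression <- function(path, orientation = c("genes", "samples")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a label column plus data columns",
                          call. = FALSE)
  labels <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1L]
      stop(sprintf(
        "non-numeric cell at row '%s', column '%s' of %s",
        labels[if (is.na(bad)) 1L else bad], names(vals)[j], path),
        call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- labels
  if (orientation == "samples") m <- t(m)
  if (anyDuplicated(rownames(m))) {
    stop("duplicate gene labels in ", path, call. = FALSE)
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at gene '%s', condition '%s' in %s",
                 rownames(m)[bad[1L]], colnames(m)[bad[2L]], path),
         call. = FALSE)
  }
  as_expression_matrix(m, for_inference = FALSE)
}

#' Write an expression matrix as tab-separated text
#'
#' @param expr Expression matrix, genes in rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the interaction and relation files of an inferred network
#'
#' Produces the two result files of an inference run: the interaction file
#' `<prefix>_interaction.tsv` records the raw correlation value (final
#' MI/CMI weight) of every gene pair, and the relation file
#' `<prefix>_relation.tsv` records pairs judged to interact directly. By
#' default the relation file lists only retained edges (value 1); with
#' `emit_zeros = TRUE` every pair appears with an explicit 0/1. Pairs are
#' emitted with lexically ordered labels so output is deterministic.
#'
#' @param state A `network_state`.
#' @param prefix Output path prefix.
#' @param emit_zeros Write all pairs with explicit 0/1 relations.
#' @param digits Significant decimals for weights (`NA` = full precision).
#' @return Character vector of the two paths written, invisibly.
#' @export
write_network <- function(state, prefix, emit_zeros = FALSE, digits = 6L) {
  stopifnot(inherits(state, "network_state"))
  idx <- which(upper.tri(state$weights), arr.ind = TRUE)
  a <- state$genes[idx[, 1L]]
  b <- state$genes[idx[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  w <- state$weights[idx]
  rel <- as.integer(state$adjacency[idx])
  ord <- order(a, b, method = "radix")
  a <- a[ord]; b <- b[ord]; w <- w[ord]; rel <- rel[ord]
  wtxt <- if (is.na(digits)) format(w, digits = 17, trim = TRUE)
          else formatC(w, digits = digits, format = "f")
  ipath <- paste0(prefix, "_interaction.tsv")
  rpath <- paste0(prefix, "_relation.tsv")
  write_atomic(data.frame(gene_a = a, gene_b = b, weight = wtxt), ipath)
  rdf <- if (emit_zeros) {
    data.frame(gene_a = a, gene_b = b, relation = rel)
  } else {
    data.frame(gene_a = a[rel == 1L], gene_b = b[rel == 1L],
               relation = rel[rel == 1L])
  }
  write_atomic(rdf, rpath)
  invisible(c(interaction = ipath, relation = rpath))
}

# Write a TSV via a temp file + atomic rename so failures never leave a
# partial output behind.
write_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!file.rename(tmp, path)) stop("cannot write ", path, call. = FALSE)
  invisible(path)
}

#' Read the interaction file back as a pair-score table
#'
#' @param path Path written by [write_network()].
#' @return Data frame with `gene_a`, `gene_b`, `weight`.
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  df$weight <- as.numeric(df$weight)
  df
}

#' Read a DREAM-format gold standard
#'
#' Three tab-separated columns: gene, gene, 0/1. Rows labeled 1 are true
#' interactions; rows labeled 0 contribute genes to the known universe.
#' Reciprocal and duplicate rows collapse to one unordered pair.
#'
#' @param path Path to the gold-standard TSV (no header).
#' @param genes Optional full gene universe; defaults to the labels seen in
#'   the file.
#' @return A [gold_standard()].
#' @export
read_gold <- function(path, genes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("gold standard needs 3 columns", call. = FALSE)
  flag <- df[[3L]]
  if (!all(flag %in% c(0L, 1L))) {
    stop("gold-standard relation column must be 0 or 1; saw: ",
         paste(unique(flag[!flag %in% c(0L, 1L)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(genes)) genes <- sort(unique(c(df[[1L]], df[[2L]])))
  pos <- df[flag == 1L, 1:2, drop = FALSE]
  if (nrow(pos) == 0L) gold_standard(character(0), genes)
  else gold_standard(pos, genes)
}

#' Write a gold standard in DREAM format
#'
#' @param gold A `gold_standard`.
#' @param path Output path.
#' @param emit_zeros Also write non-interacting pairs with relation 0.
#' @return `path`, invisibly.
#' @export
write_gold <- function(gold, path, emit_zeros = FALSE) {
  stopifnot(inherits(gold, "gold_standard"))
  keys <- if (emit_zeros) all_pair_keys(gold$genes) else gold$positive_pairs
  parts <- strsplit(keys, "|", fixed = TRUE)
  df <- data.frame(
    a = vapply(parts, `[`, "", 1L),
    b = vapply(parts, `[`, "", 2L),
    rel = as.integer(keys %in% gold$positive_pairs))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
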