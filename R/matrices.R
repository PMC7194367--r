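#' Labeled matrix containers
#'
#' The package works with three labeled matrix types that share a common
#' internal layout (a numeric matrix plus row/column identifiers):
#'
#' * `expression_matrix()` — a G x C signal matrix `Y` (genes or enhancers in
#'   rows, conditions in columns), optionally double-centered;
#' * `motif_score_matrix()` — a T x G matrix `M` of motif log-odds scores
#'   (motifs in rows, genes in columns), optionally row-standardized;
#' * `motif_activity_matrix()` — a T x C matrix of motif activities
#'   `omega` (either a simulated prior draw or a posterior estimate).
#'
#' All entries must be finite and all labels unique; constructors validate
#' this and store the labels as `dimnames` on `$values`.
#'
#' @param values numeric matrix.
#' @param gene_ids,condition_ids,motif_ids character label vectors; default to
#'   the corresponding `dimnames` of `values`, or `g1..`, `c1..`, `m1..` when
#'   absent.
#' @param centered logical; has the matrix been double-centered?
#' @param normalized logical; have motif rows been standardized?
#' @param kind for activities, `"simulated_prior"` or `"posterior"`.
#'
#' @return An object of class `"expression_matrix"`, `"motif_score_matrix"`
#'   or `"motif_activity_matrix"`: a list with element `values` and the
#'   metadata flags above.
#' @examples
#' y <- expression_matrix(matrix(rnorm(12), 4, 3))
#' dim(y$values)
#' @name labeled-matrices
NULL

default_labels <- function(n, prefix) paste0(prefix, seq_len(n))

check_labels <- function(labels, n, what) {
  if (length(labels) != n) {
    stop(sprintf("%s: expected %d labels, got %d", what, n, length(labels)),
         call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop(sprintf("%s: duplicate labels: %s", what,
                 paste(unique(labels[duplicated(labels)]), collapse = ", ")),
         call. = FALSE)
  }
  as.character(labels)
}

check_finite <- function(values, what) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop(sprintf("%s: 'values' must be a numeric matrix", what), call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop(sprintf("%s: all entries must be finite", what), call. = FALSE)
  }
  invisible(values)
}

#' @rdname labeled-matrices
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              condition_ids = colnames(values),
                              centered = FALSE) {
  check_finite(values, "expression_matrix")
  if (is.null(gene_ids)) gene_ids <- default_labels(nrow(values), "g")
  if (is.null(condition_ids)) condition_ids <- default_labels(ncol(values), "c")
  gene_ids <- check_labels(gene_ids, nrow(values), "gene_ids")
  condition_ids <- check_labels(condition_ids, ncol(values), "condition_ids")
  dimnames(values) <- list(gene_ids, condition_ids)
  structure(list(values = values, centered = isTRUE(centered)),
            class = "expression_matrix")
}

#' @rdname labeled-matrices
#' @export
motif_score_matrix <- function(values, motif_ids = rownames(values),
                               gene_ids = colnames(values),
                               normalized = FALSE) {
  check_finite(values, "motif_score_matrix")
  if (is.null(motif_ids)) motif_ids <- default_labels(nrow(values), "m")
  if (is.null(gene_ids)) gene_ids <- default_labels(ncol(values), "g")
  motif_ids <- check_labels(motif_ids, nrow(values), "motif_ids")
  gene_ids <- check_labels(gene_ids, ncol(values), "gene_ids")
  dimnames(values) <- list(motif_ids, gene_ids)
  structure(list(values = values, normalized = isTRUE(normalized)),
            class = "motif_score_matrix")
}

#' @rdname labeled-matrices
#' @export
motif_activity_matrix <- function(values, motif_ids = rownames(values),
                                  condition_ids = colnames(values),
                                  kind = c("posterior", "simulated_prior")) {
  kind <- match.arg(kind)
  check_finite(values, "motif_activity_matrix")
  if (is.null(motif_ids)) motif_ids <- default_labels(nrow(values), "m")
  if (is.null(condition_ids)) condition_ids <- default_labels(ncol(values), "c")
  motif_ids <- check_labels(motif_ids, nrow(values), "motif_ids")
  condition_ids <- check_labels(condition_ids, ncol(values), "condition_ids")
  dimnames(values) <- list(motif_ids, condition_ids)
  structure(list(values = values, kind = kind),
            class = "motif_activity_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d conditions (centered: %s)\n",
              nrow(x$values), ncol(x$values), x$centered))
  invisible(x)
}

#' @export
print.motif_score_matrix <- function(x, ...) {
  cat(sprintf("motif_score_matrix: %d motifs x %d genes (normalized: %s)\n",
              nrow(x$values), ncol(x$values), x$normalized))
  invisible(x)
}

#' @export
print.motif_activity_matrix <- function(x, ...) {
  cat(sprintf("motif_activity_matrix [%s]: %d motifs x %d conditions\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a labeled matrix from TSV
#'
#' Reads a tab-separated file with one header row of column labels and one
#' leading column of row labels (the header of the label column itself is
#' free text and ignored). Parsing is strict: any non-numeric body cell,
#' ragged row, or duplicate/missing label is an error rather than a silent
#' `NA`.
#'
#' @param path path to a TSV file.
#' @param orientation `"rows_are_genes"` returns an [expression_matrix()];
#'   `"rows_are_motifs"` returns a [motif_score_matrix()].
#' @return An `expression_matrix` or `motif_score_matrix` with labels in
#'   file order.
#' @seealso [write_labeled_matrix()]
#' @export
read_labeled_matrix <- function(path,
                                orientation = c("rows_are_genes",
                                                "rows_are_motifs")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) {
    stop("labeled matrix TSV needs a header row and at least one data row",
         call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  ncols <- length(header) - 1L
  if (ncols < 1) stop("no data columns in ", path, call. = FALSE)
  col_labels <- header[-1]
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != ncols + 1L)) {
    stop(sprintf("ragged rows in %s: line(s) %s", path,
                 paste(which(widths != ncols + 1L) + 1L, collapse = ", ")),
         call. = FALSE)
  }
  row_labels <- vapply(body, `[[`, character(1), 1L)
  cells <- vapply(body, function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) {
      stop(sprintf("non-numeric cell in row '%s' of %s", f[[1]], path),
           call. = FALSE)
    }
    v
  }, numeric(ncols))
  values <- if (ncols == 1L) matrix(cells, ncol = 1L) else t(cells)
  row_labels <- check_labels(row_labels, nrow(values), "row labels")
  col_labels <- check_labels(col_labels, ncol(values), "column labels")
  if (orientation == "rows_are_genes") {
    expression_matrix(values, gene_ids = row_labels,
                      condition_ids = col_labels)
  } else {
    motif_score_matrix(values, motif_ids = row_labels, gene_ids = col_labels)
  }
}

#' Write a labeled matrix to TSV
#'
#' Writes any of the labeled matrix containers (or a plain named matrix) as
#' tab-separated text with 17 significant digits, so that a read/write round
#' trip reproduces the values bit-for-bit.
#'
#' @param m a labeled matrix object or a numeric matrix with dimnames.
#' @param path output file path.
#' @param row_label_header text for the top-left header cell.
#' @return Invisibly, `path`.
#' @export
write_labeled_matrix <- function(m, path, row_label_header = "id") {
  values <- if (is.matrix(m)) m else m$values
  if (!is.matrix(values) || nrow(values) == 0L || ncol(values) == 0L) {
    stop("cannot write an empty matrix", call. = FALSE)
  }
  check_finite(values, "write_labeled_matrix")
  if (is.null(rownames(values))) rownames(values) <- default_labels(nrow(values), "r")
  if (is.null(colnames(values))) colnames(values) <- default_labels(ncol(values), "c")
  header <- paste(c(row_label_header, colnames(values)), collapse = "\t")
  body <- vapply(seq_len(nrow(values)), function(i) {
    paste(c(rownames(values)[i], sprintf("%.17g", values[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Double-center an expression matrix
#'
#' Removes gene (row) and condition (column) means, adding the grand mean
#' back, so that every row mean and every column mean of the result is
#' exactly zero:
#' \deqn{y'_{g,c} = y_{g,c} - \bar y_{g\cdot} - \bar y_{\cdot c} + \bar y}
#' This is the normalization applied to the signal matrix before model
#' fitting; the linear motif model is only identified on the doubly
#' centered scale, since any additive gene or condition effect is absorbed
#' by the margins.
#'
#' @param y an [expression_matrix()] with `centered = FALSE`.
#' @return The centered `expression_matrix` (flag set).
#' @examples
#' y <- expression_matrix(matrix(c(1, 0, 0, 0), 2, 2))
#' double_center(y)$values
#' @export
double_center <- function(y) {
  stopifnot(inherits(y, "expression_matrix"))
  if (isTRUE(y$centered)) {
    stop("matrix is already double-centered", call. = FALSE)
  }
  v <- y$values
  rm_ <- rowMeans(v)
  cm_ <- colMeans(v)
  gm <- mean(v)
  v <- v - outer(rm_, rep(1, ncol(v))) - outer(rep(1, nrow(v)), cm_) + gm
  expression_matrix(v, centered = TRUE)
}

#' Standardize motif score rows
#'
#' Standardizes each motif row of the score matrix to mean zero and unit
#' standard deviation across genes (population convention, dividing by
#' `sqrt(mean((x - mean(x))^2))`), the usual treatment of design columns
#' before ridge-type shrinkage. Rows with zero variance are set to all
#' zeros and counted in the `zero_variance_motifs` attribute.
#'
#' @param m a [motif_score_matrix()] with `normalized = FALSE`.
#' @return The normalized `motif_score_matrix`; attribute
#'   `zero_variance_motifs` lists motifs whose row had no variance.
#' @export
normalize_motif_scores <- function(m) {
  stopifnot(inherits(m, "motif_score_matrix"))
  if (isTRUE(m$normalized)) {
    stop("motif scores are already normalized", call. = FALSE)
  }
  v <- m$values
  mu <- rowMeans(v)
  centered <- v - mu
  sds <- sqrt(rowMeans(centered^2))
  flat <- sds <= 0
  sds[flat] <- 1
  out <- centered / sds
  out[flat, ] <- 0
  if (any(flat)) {
    warning(sprintf("%d motif row(s) with zero variance set to 0", sum(flat)),
            call. = FALSE)
  }
  res <- motif_score_matrix(out, normalized = TRUE)
  attr(res, "zero_variance_motifs") <- rownames(v)[flat]
  res
}
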