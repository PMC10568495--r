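#' Construct a count matrix
#'
#' A `count_matrix` holds a non-negative integer gene x column matrix (columns
#' are cells or bulk samples) together with a column-to-sample mapping. Cell
#' level matrices are kept sparse (`Matrix::dgCMatrix`); all downstream math is
#' defined on the values, not the representation.
#'
#' @param values matrix or sparse Matrix with unique row names (gene ids) and
#'   unique column names (cell barcodes or sample names).
#' @param sample_of_column named character vector mapping every column to a
#'   sample label; defaults to each column being its own sample.
#' @return an object of class `count_matrix` with fields `values`,
#'   `gene_ids`, `column_ids`, `sample_of_column`.
#' @export
count_matrix <- function(values, sample_of_column = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene ids as rownames and column ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicated column ids")
  if (min(values) < 0) stop("negative counts are not allowed")
  if (is.null(sample_of_column)) {
    sample_of_column <- stats::setNames(colnames(values), colnames(values))
  } else {
    if (is.null(names(sample_of_column)))
      names(sample_of_column) <- colnames(values)
    if (!setequal(names(sample_of_column), colnames(values)))
      stop("sample_of_column must map every column to exactly one sample")
    sample_of_column <- sample_of_column[colnames(values)]
  }
  structure(
    list(values = values,
         gene_ids = rownames(values),
         column_ids = colnames(values),
         sample_of_column = sample_of_column),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d columns (%d sample%s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sample_of_column)),
              if (length(unique(x$sample_of_column)) == 1) "" else "s"))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Sample names of a count matrix
#' @param x a `count_matrix`
#' @return character vector of unique sample labels, in column order
#' @export
samples_of <- function(x) unique(unname(x$sample_of_column))

#' Strip ENSEMBL-style version suffixes from gene identifiers
#'
#' Removes a trailing ".<digits>" so that files from different exporters share
#' an identifier namespace.
#' @param ids character vector of gene ids
#' @return ids without version suffixes
#' @export
strip_gene_versions <- function(ids) sub("\\.[0-9]+$", "", ids)

read_id_column <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  x[[1L]]
}

#' Read a 10x-style MatrixMarket triplet directory
#'
#' Expects `matrix.mtx`, a feature list (`features.tsv` or `genes.tsv`) and
#' `barcodes.tsv`, plain or gzipped, with genes on matrix rows.
#'
#' @param dir_path directory containing the triplet
#' @param strip_versions strip ".N" version suffixes from feature ids
#'   (default TRUE)
#' @param sample optional sample label applied to all barcodes
#' @return a `count_matrix` (sparse)
#' @export
read_counts_mtx <- function(dir_path, strip_versions = TRUE, sample = NULL) {
  find1 <- function(names) {
    for (nm in names) {
      p <- file.path(dir_path, nm)
      if (file.exists(p)) return(p)
    }
    stop("missing ", names[1L], " in ", dir_path)
  }
  mtx <- find1(c("matrix.mtx", "matrix.mtx.gz"))
  feats <- find1(c("features.tsv", "features.tsv.gz", "genes.tsv", "genes.tsv.gz"))
  bars <- find1(c("barcodes.tsv", "barcodes.tsv.gz"))
  m <- Matrix::readMM(mtx)
  m <- methods::as(methods::as(m, "dMatrix"), "CsparseMatrix")
  if (Matrix::nnzero(m) == 0L) stop("no entries: matrix is all zero in ", mtx)
  gene_ids <- read_id_column(feats)
  barcodes <- read_id_column(bars)
  if (length(gene_ids) != nrow(m))
    stop(sprintf("dimension mismatch: %d features vs %d matrix rows",
                 length(gene_ids), nrow(m)))
  if (length(barcodes) != ncol(m))
    stop(sprintf("dimension mismatch: %d barcodes vs %d matrix columns",
                 length(barcodes), ncol(m)))
  if (any(m@x != round(m@x))) stop("non-integer values in ", mtx)
  if (strip_versions) gene_ids <- strip_gene_versions(gene_ids)
  if (anyDuplicated(gene_ids)) stop("duplicated feature ids")
  dimnames(m) <- list(gene_ids, barcodes)
  soc <- if (is.null(sample)) NULL else stats::setNames(rep(sample, ncol(m)), barcodes)
  count_matrix(m, sample_of_column = soc)
}

#' Write a count matrix as a 10x-style MatrixMarket triplet
#' @param x a `count_matrix`
#' @param dir_path output directory (created if needed)
#' @return `dir_path`, invisibly
#' @export
write_counts_mtx <- function(x, dir_path) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(x$values, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir_path, "matrix.mtx"))
  writeLines(x$gene_ids, file.path(dir_path, "features.tsv"))
  writeLines(x$column_ids, file.path(dir_path, "barcodes.tsv"))
  invisible(dir_path)
}

#' Read a TSV count table
#'
#' First column holds gene ids (or column ids when `orientation` is
#' `"genes_in_columns"`); the header row holds the other dimension's ids.
#'
#' @param path TSV file
#' @param orientation `"genes_in_rows"` (default) or `"genes_in_columns"`
#' @param strip_versions strip ".N" suffixes from gene ids
#' @return a `count_matrix` (dense)
#' @export
read_counts_tsv <- function(path, orientation = c("genes_in_rows", "genes_in_columns"),
                            strip_versions = TRUE) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m) || anyNA(m))
    stop("non-numeric or missing cell in ", path)
  rownames(m) <- ids
  if (orientation == "genes_in_columns") m <- t(m)
  if (strip_versions) rownames(m) <- strip_gene_versions(rownames(m))
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", path)
  count_matrix(m)
}

#' Write a count matrix (or any gene x column matrix) as TSV
#' @param x a `count_matrix` or matrix
#' @param path output file
#' @param id_name header for the identifier column
#' @return `path`, invisibly
#' @export
write_counts_tsv <- function(x, path, id_name = "gene_id") {
  m <- if (inherits(x, "count_matrix")) as.matrix(x$values) else as.matrix(x)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set name, description, then member gene ids.
#' @param path GMT file
#' @return list with `sets` (named list of character vectors, member order
#'   preserved) and `descriptions` (named character)
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1L], " has fewer than 3 fields")
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms)) stop("duplicate set name: ",
                               nms[duplicated(nms)][1L])
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nms
  desc <- stats::setNames(vapply(fields, `[[`, "", 2L), nms)
  list(sets = sets, descriptions = desc)
}

#' Write gene sets in GMT format
#' @param gsc list as returned by [read_gmt()], or a bare named list of
#'   character vectors
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gmt <- function(gsc, path) {
  if (is.null(gsc$sets)) gsc <- list(sets = gsc, descriptions = NULL)
  desc <- gsc$descriptions
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(gsc$sets)),
                                             names(gsc$sets))
  lines <- vapply(names(gsc$sets), function(nm)
    paste(c(nm, desc[[nm]], gsc$sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Align bulk, single-cell and factor inputs to a common gene universe
#'
#' Takes the ordered intersection of gene ids (order of the bulk matrix) and
#' reports what was dropped on each side.
#'
#' @param bulk a `count_matrix` of bulk counts
#' @param sc a `count_matrix` of single-cell counts
#' @param factors optional gene x factor data.frame/matrix with gene rownames
#' @return list with `genes` (common ids), `bulk`, `sc`, `factors` (subset to
#'   the common universe), and `dropped` (per-side id lists)
#' @export
align_gene_universe <- function(bulk, sc, factors = NULL) {
  common <- intersect(bulk$gene_ids, sc$gene_ids)
  if (!is.null(factors)) common <- intersect(common, rownames(factors))
  if (length(common) == 0L) stop("empty gene intersection")
  out <- list(
    genes = common,
    bulk = count_matrix(bulk$values[common, , drop = FALSE], bulk$sample_of_column),
    sc = count_matrix(sc$values[common, , drop = FALSE], sc$sample_of_column),
    factors = if (is.null(factors)) NULL else factors[common, , drop = FALSE],
    dropped = list(bulk = setdiff(bulk$gene_ids, common),
                   sc = setdiff(sc$gene_ids, common),
                   factors = if (is.null(factors)) character(0)
                             else setdiff(rownames(factors), common)))
  out
}

#' Read a YAML sample sheet
#'
#' The sheet lists, per sample, the path to its single-cell counts, the bulk
#' column name, and optional cell-label / batch fields. Every referenced path
#' is checked before the pipeline starts.
#'
#' @param path YAML file
#' @param check_paths verify that referenced files exist (default TRUE)
#' @return the parsed sheet (list)
#' @export
read_sample_sheet <- function(path, check_paths = TRUE) {
  sheet <- yaml::read_yaml(path)
  if (is.null(sheet$samples) || !length(sheet$samples))
    stop("sample sheet has no samples")
  base <- dirname(normalizePath(path))
  if (check_paths) {
    for (s in sheet$samples) {
      for (field in c("sc_counts", "bulk_counts", "cell_labels")) {
        p <- s[[field]]
        if (!is.null(p)) {
          full <- if (startsWith(p, "/")) p else file.path(base, p)
          if (!file.exists(full))
            stop("sample '", s$name, "': missing file ", p)
        }
      }
    }
    if (!is.null(sheet$bulk_counts)) {
      p <- sheet$bulk_counts
      full <- if (startsWith(p, "/")) p else file.path(base, p)
      if (!file.exists(full)) stop("missing bulk counts file ", p)
    }
  }
  sheet
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over Biostrings for the factor computations that take raw
#' sequences (GC content, mappability).
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("read_fasta requires the Biostrings package")
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
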