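#' Read a UMI count matrix
#'
#' Reads single-cell counts into a [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment]
#' with genes in rows, cells in columns and a `counts` assay. Three formats
#' are supported:
#'
#' * `mtx_dir` — a directory with `matrix.mtx` (genes x cells, Matrix
#'   Market), `genes.tsv` and `barcodes.tsv` (identifier in the first
#'   column).
#' * `dense_tsv` — a dense table, one row per cell, first column `cell_id`,
#'   remaining columns named by gene.
#' * `h5ad` — an AnnData HDF5 container; converted through the bundled
#'   python/anndata bridge (raw counts taken from `X` or a named layer).
#'
#' All entries are validated to be non-negative integers; sparse input is
#' densified transparently, so downstream code sees identical values either
#' way.
#'
#' @param path File or directory path.
#' @param format One of `"mtx_dir"`, `"dense_tsv"`, `"h5ad"`.
#' @param layer For `h5ad` only: name of the layer holding raw counts
#'   (`NULL` uses `X`).
#' @return A `SingleCellExperiment` with integer `counts`.
#' @export
readCounts <- function(path, format = c("mtx_dir", "dense_tsv", "h5ad"),
                       layer = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  switch(format,
    mtx_dir = readCountsMtxDir(path),
    dense_tsv = readCountsDenseTsv(path),
    h5ad = readCountsH5ad(path, layer)
  )
}

readCountsMtxDir <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  genes <- file.path(dir, "genes.tsv")
  barcodes <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, genes, barcodes)) {
    if (!file.exists(f)) stop("missing file in mtx directory: ", f)
  }
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("malformed Matrix Market file '",
                                         mtx, "': ", conditionMessage(e)))
  readIdColumn <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1)
  }
  geneIds <- readIdColumn(genes)
  cellIds <- readIdColumn(barcodes)
  m <- as.matrix(m)
  if (nrow(m) != length(geneIds)) {
    stop("matrix has ", nrow(m), " rows but genes.tsv lists ",
         length(geneIds), " genes")
  }
  if (ncol(m) != length(cellIds)) {
    stop("matrix has ", ncol(m), " columns but barcodes.tsv lists ",
         length(cellIds), " cells")
  }
  dimnames(m) <- list(geneIds, cellIds)
  makeCountsSCE(m)
}

readCountsDenseTsv <- function(path) {
  tab <- tryCatch(read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE),
                  error = function(e) stop("malformed TSV '", path, "': ",
                                           conditionMessage(e)))
  if (!ncol(tab) || names(tab)[1] != "cell_id") {
    stop("dense TSV must have 'cell_id' as its first column")
  }
  cellIds <- as.character(tab[[1]])
  m <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(m) <- cellIds
  makeCountsSCE(m)
}

readCountsH5ad <- function(path, layer = NULL) {
  tmp <- tempfile("h5ad_mtx_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  args <- c(path, tmp, if (!is.null(layer)) layer)
  runPythonScript("h5ad_to_mtx.py", args)
  readCountsMtxDir(tmp)
}

# Validate and assemble the genes x cells counts container.
makeCountsSCE <- function(m) {
  if (is.null(dim(m)) || ncol(m) == 0L) stop("no cells in count matrix")
  if (nrow(m) == 0L) stop("no genes in count matrix")
  bad <- which(!is.finite(m) | m < 0 | m != floor(m))
  if (length(bad)) {
    i <- bad[1]
    stop("invalid count entry at gene ", ((i - 1) %% nrow(m)) + 1,
         ", cell ", ((i - 1) %/% nrow(m)) + 1,
         ": counts must be non-negative integers (found ", m[i], ")")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("gene and cell identifiers are required")
  }
  if (anyDuplicated(rownames(m))) stop("duplicated gene identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicated cell identifiers")
  storage.mode(m) <- "double"
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

#' Write counts as a Matrix Market directory
#'
#' Writes `matrix.mtx` (genes x cells), `genes.tsv` and `barcodes.tsv`, the
#' layout [readCounts()] reads back.
#'
#' @param sce A `SingleCellExperiment` with a `counts` assay.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
writeCountsMtx <- function(sce, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- Matrix::Matrix(counts(sce), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(sce), file.path(dir, "genes.tsv"))
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @importFrom SummarizedExperiment assay assay<- assayNames colData
#'   colData<- rowData
counts <- function(sce) assay(sce, "counts")

#' Gene identifiers of a counts container
#' @param sce A `SingleCellExperiment`.
#' @return Character vector.
#' @export
geneIds <- function(sce) rownames(sce)

#' Cell identifiers of a counts container
#' @param sce A `SingleCellExperiment`.
#' @return Character vector.
#' @export
cellIds <- function(sce) colnames(sce)

#' Read a per-cell label table
#'
#' Two-column TSV (`cell_id`, `label`); an empty label field marks a missing
#' label. Binary labels must be 0/1 where observed.
#'
#' @param path TSV path.
#' @param kind `"binary"` or `"continuous"`.
#' @return A data.frame with columns `cell_id`, `label` and attribute
#'   `kind`.
#' @export
readLabels <- function(path, kind = c("binary", "continuous")) {
  kind <- match.arg(kind)
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character"))
  if (!all(c("cell_id", "label") %in% names(tab))) {
    stop("label TSV must have columns cell_id and label")
  }
  lab <- suppressWarnings(as.numeric(tab$label))
  lab[!nzchar(trimws(tab$label))] <- NA_real_
  makeLabelTable(tab$cell_id, lab, kind)
}

makeLabelTable <- function(cellIds, label, kind) {
  if (kind == "binary") {
    obs <- label[!is.na(label)]
    if (length(obs) && !all(obs %in% c(0, 1))) {
      stop("binary labels must be 0 or 1")
    }
  }
  out <- data.frame(cell_id = as.character(cellIds), label = label,
                    stringsAsFactors = FALSE)
  attr(out, "kind") <- kind
  out
}

#' Write a label table as TSV
#' @param labels A label table from [readLabels()] or the generator.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeLabels <- function(labels, path) {
  out <- labels
  out$label <- ifelse(is.na(out$label), "", format(out$label, digits = 15,
                                                   trim = TRUE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
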