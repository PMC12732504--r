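#' Filter cells by quality thresholds
#'
#' Retains cells with at least `minNonzeroGenes` genes detected, at least
#' `minTotalCounts` total counts, and fewer than `maxNonzeroGenes` detected
#' genes. The gene axis and the order of surviving cells are unchanged.
#'
#' @param sce Counts container from [readCounts()].
#' @param minNonzeroGenes Minimum number of genes with non-zero counts
#'   (inclusive).
#' @param minTotalCounts Minimum total UMI count (inclusive).
#' @param maxNonzeroGenes Upper bound on detected genes (exclusive:
#'   "fewer than").
#' @return Filtered `SingleCellExperiment`.
#' @export
filterCells <- function(sce, minNonzeroGenes = 200, minTotalCounts = 500,
                        maxNonzeroGenes = 5000) {
  stopifnot(minNonzeroGenes > 0, minTotalCounts > 0,
            minNonzeroGenes <= maxNonzeroGenes)
  m <- counts(sce)
  nz <- colSums(m > 0)
  tot <- colSums(m)
  keep <- nz >= minNonzeroGenes & tot >= minTotalCounts & nz < maxNonzeroGenes
  if (!any(keep)) stop("empty result: no cells pass the filters")
  sce[, keep]
}

#' Filter genes by detection frequency
#'
#' Removes genes with non-zero counts in fewer than `minCells` cells; the
#' cell axis is unchanged.
#'
#' @param sce Counts container.
#' @param minCells Minimum number of cells with non-zero counts (inclusive).
#' @return Filtered `SingleCellExperiment`.
#' @export
filterGenes <- function(sce, minCells = 5) {
  stopifnot(minCells >= 1)
  keep <- rowSums(counts(sce) > 0) >= minCells
  if (!any(keep)) stop("empty result: no genes pass the filter")
  sce[keep, ]
}

#' Mean-scale and log1p-normalize counts
#'
#' Divides each cell's counts by that cell's mean count across genes (its
#' total divided by the number of genes) and applies `log1p`. The scale
#' factors are stored in `colData(sce)$scaleFactor`, and
#' [inverseNormalize()] recovers the raw counts exactly (up to integer
#' rounding).
#'
#' @param sce Counts container; all-zero cells must have been filtered out.
#' @return The container with an added `lognorm` assay and per-cell
#'   `scaleFactor`.
#' @export
normalizeLog1p <- function(sce) {
  m <- counts(sce)
  sf <- colMeans(m)
  if (any(sf <= 0)) {
    stop("zero scale factor: all-zero cell present; run filterCells first")
  }
  assay(sce, "lognorm") <- log1p(sweep(m, 2, sf, "/"))
  colData(sce)$scaleFactor <- sf
  sce
}

#' Invert the log1p normalization
#'
#' Applies `expm1`, multiplies by the stored per-cell scale factor and
#' rounds to the nearest integer, recovering the raw counts.
#'
#' @param sce Container with a `lognorm` assay and `scaleFactor` column.
#' @return Integer matrix of recovered counts (genes x cells).
#' @export
inverseNormalize <- function(sce) {
  if (!"lognorm" %in% assayNames(sce)) stop("no lognorm assay present")
  sf <- colData(sce)$scaleFactor
  if (is.null(sf)) stop("no scaleFactor stored; run normalizeLog1p first")
  round(sweep(expm1(assay(sce, "lognorm")), 2, sf, "*"))
}

# Binned dispersion statistic: variance/mean of normalized values per gene,
# z-scored within bins of similar mean expression.
hvgDispersion <- function(lognorm, nBins = 20) {
  mu <- rowMeans(lognorm)
  v <- apply(lognorm, 1, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = nBins, labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    idx <- bins == b
    s <- sd(disp[idx])
    if (!is.finite(s) || s == 0) s <- 1
    z[idx] <- (disp[idx] - mean(disp[idx])) / s
  }
  z
}

#' Select highly variable genes
#'
#' Ranks genes by a binned dispersion statistic (variance/mean of the
#' normalized values, z-scored within bins of similar mean) and returns the
#' top `nTop`. Genes in `forceInclude` are always selected, displacing the
#' lowest-ranked picks so the result size stays exactly `nTop`.
#'
#' @param sce Container with a `lognorm` assay (see [normalizeLog1p()]).
#' @param nTop Number of genes to select.
#' @param forceInclude Gene identifiers that must be in the selection.
#' @param nBins Number of mean-expression bins for the dispersion z-score.
#' @return Character vector of `nTop` gene identifiers, ordered by rank
#'   (forced genes keep their natural rank position or are appended).
#' @export
selectHVGs <- function(sce, nTop, forceInclude = character(), nBins = 20) {
  if (!"lognorm" %in% assayNames(sce)) stop("no lognorm assay present")
  genes <- rownames(sce)
  if (nTop > length(genes)) stop("nTop exceeds the number of genes")
  missing <- setdiff(forceInclude, genes)
  if (length(missing)) {
    stop("unknown forced gene id(s): ", paste(missing, collapse = ", "))
  }
  ln <- assay(sce, "lognorm")
  z <- hvgDispersion(ln, nBins = nBins)
  # ties in the z-score (e.g. singleton bins) fall back to the raw
  # dispersion, then to the identifier for full determinism
  mu <- rowMeans(ln)
  disp <- ifelse(mu > 0, apply(ln, 1, var) / mu, 0)
  ord <- genes[order(-z, -disp, genes)]
  sel <- ord[seq_len(nTop)]
  add <- setdiff(forceInclude, sel)
  if (length(add)) {
    droppable <- setdiff(rev(sel), forceInclude)[seq_along(add)]
    sel <- c(setdiff(sel, droppable), add)
  }
  sel
}

#' Split cells into train/validation/test partitions
#'
#' Random permutation under `seed`, then contiguous assignment by fraction:
#' validation and test sizes are floored, the remainder goes to training,
#' so each partition deviates from its exact fraction by less than one
#' cell.
#'
#' @param sce Counts container (or anything with cell columns).
#' @param fractions Train/val/test fractions summing to 1.
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return The container with a `partition` factor
#'   (`train`/`val`/`test`) in `colData`.
#' @export
splitCells <- function(sce, fractions = c(0.82, 0.09, 0.09), seed = 1) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9)
  n <- ncol(sce)
  if (n < 3) stop("need at least 3 cells to split")
  nVal <- floor(fractions[2] * n)
  nTest <- floor(fractions[3] * n)
  nTrain <- n - nVal - nTest
  set.seed(seed)
  perm <- sample.int(n)
  part <- rep(c("train", "val", "test"), c(nTrain, nVal, nTest))
  assignment <- character(n)
  assignment[perm] <- part
  colData(sce)$partition <- factor(assignment,
                                   levels = c("train", "val", "test"))
  sce
}

#' One-call preprocessing pipeline
#'
#' Applies the standard filtering order (cells, then genes), normalizes,
#' selects highly variable genes, restricts the matrix to them, and assigns
#' the train/val/test split.
#'
#' @inheritParams filterCells
#' @inheritParams filterGenes
#' @inheritParams selectHVGs
#' @inheritParams splitCells
#' @param nHVGs Number of highly variable genes to keep (`NULL` keeps all).
#' @return Preprocessed `SingleCellExperiment` restricted to the selected
#'   genes, with `lognorm`, `scaleFactor` and `partition` filled in.
#' @export
preprocessCounts <- function(sce, minNonzeroGenes = 200,
                             minTotalCounts = 500, maxNonzeroGenes = 5000,
                             minCells = 5, nHVGs = NULL,
                             forceInclude = character(),
                             fractions = c(0.82, 0.09, 0.09), seed = 1) {
  sce <- filterCells(sce, minNonzeroGenes, minTotalCounts, maxNonzeroGenes)
  sce <- filterGenes(sce, minCells)
  sce <- normalizeLog1p(sce)
  if (!is.null(nHVGs)) {
    hv <- selectHVGs(sce, nHVGs, forceInclude)
    sce <- sce[hv, ]
    # scale factors were computed on the full gene set; renormalize on the
    # HVG subset so training inputs are self-consistent
    sce <- normalizeLog1p(sce)
  }
  splitCells(sce, fractions, seed)
}
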