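## Alignment scoring: empirical perturbation axis, per-gene cosine and
## magnitude-weighted scores, symmetric-change baseline, top-K selection.

#' Empirical perturbation axis between two labeled populations
#'
#' `a = mean(z | label == 1) - mean(z | label == 0)`: the mean latent
#' displacement from the unperturbed to the perturbed group (e.g.,
#' healthy to disease).
#'
#' @param latents Matrix of latent embeddings, one cell per row, cell
#'   identifiers as rownames when `labels` is a label table.
#' @param labels Either a binary label table (columns `cell_id`, `label`;
#'   see [readLabels()]) or a 0/1 vector aligned with the rows of
#'   `latents`. Missing labels are ignored.
#' @return A [PerturbationAxis-class]; a zero-norm axis triggers a
#'   warning here and an error at scoring time.
#' @export
perturbationAxis <- function(latents, labels) {
  latents <- as.matrix(latents)
  if (is.data.frame(labels)) {
    idx <- match(labels$cell_id, rownames(latents))
    ok <- !is.na(idx) & !is.na(labels$label)
    lab <- rep(NA_real_, nrow(latents))
    lab[idx[ok]] <- labels$label[ok]
  } else {
    lab <- as.numeric(labels)
  }
  g0 <- which(lab == 0); g1 <- which(lab == 1)
  if (!length(g0) || !length(g1)) {
    stop("both label groups must be non-empty")
  }
  m0 <- colMeans(latents[g0, , drop = FALSE])
  m1 <- colMeans(latents[g1, , drop = FALSE])
  a <- m1 - m0
  if (sqrt(sum(a^2)) == 0) {
    warning("zero-norm perturbation axis; scoring will refuse it")
  }
  gm <- rbind(unperturbed = m0, perturbed = m1)
  new("PerturbationAxis", axis = a, groupMeans = gm,
      groupSizes = c(length(g0), length(g1)))
}

checkAxis <- function(axis) {
  nrm <- sqrt(sum(axis@axis^2))
  if (nrm == 0) stop("zero-norm perturbation axis: scoring undefined")
  nrm
}

#' Cosine alignment score of one gene
#'
#' Average cosine similarity between the gene's gradient field and the
#' perturbation axis over the evaluation points `Z`; always in
#' `[-1, 1]`. Points with zero-norm gradient (cosine undefined) are
#' skipped and counted; a warning is emitted when more than half are
#' skipped, an error when all are.
#'
#' @param model An [NBVAE-class] model.
#' @param gene Gene identifier or index.
#' @param Z Evaluation points (rows), typically encoded cells.
#' @param axis A [PerturbationAxis-class].
#' @return Scalar score with attributes `nEval` and `nSkipped`.
#' @export
alignmentScore <- function(model, gene, Z, axis) {
  aNorm <- checkAxis(axis)
  Z <- asRowMatrix(Z, model@config$latentDim)
  if (!nrow(Z)) stop("empty evaluation set")
  grd <- outputGradient(model, Z, gene)
  gNorm <- sqrt(rowSums(grd^2))
  keep <- gNorm > 0
  if (!any(keep)) stop("all gradients have zero norm: score undefined")
  if (mean(keep) < 0.5) {
    warning("more than half of the evaluation points have zero-norm ",
            "gradients and were skipped")
  }
  cosv <- (grd[keep, , drop = FALSE] %*% axis@axis) /
    (gNorm[keep] * aNorm)
  s <- mean(cosv)
  attr(s, "nEval") <- nrow(Z)
  attr(s, "nSkipped") <- sum(!keep)
  s
}

#' Magnitude-weighted alignment score of one gene
#'
#' Mean projection of the gene's gradients onto the unit perturbation
#' axis: couples direction with local effect size, hence unbounded.
#' Zero-norm gradients contribute 0.
#'
#' @inheritParams alignmentScore
#' @return Scalar score.
#' @export
magnitudeWeightedScore <- function(model, gene, Z, axis) {
  aNorm <- checkAxis(axis)
  Z <- asRowMatrix(Z, model@config$latentDim)
  if (!nrow(Z)) stop("empty evaluation set")
  grd <- outputGradient(model, Z, gene)
  mean(grd %*% axis@axis) / aNorm
}

#' Score all genes by gradient alignment with the perturbation axis
#'
#' Computes, for every decoder gene, the cosine alignment score `s`, the
#' magnitude-weighted score `sTilde`, and the rank by `|s|` (descending,
#' ties broken by gene identifier) over a shared set of evaluation
#' points. One decoder Jacobian per evaluation point serves all genes.
#'
#' @param model An [NBVAE-class] model.
#' @param Z Evaluation points (rows), e.g. all encoded cells of both
#'   conditions, or a subset restricting the score to a region of latent
#'   space.
#' @param axis A [PerturbationAxis-class].
#' @return A `data.frame` with columns `gene_id`, `s`, `sTilde`, `rank`,
#'   `n_eval_points`, `n_skipped`, ordered by rank; evaluation metadata
#'   in `attr(, "evalInfo")`.
#' @export
scoreGenes <- function(model, Z, axis) {
  aNorm <- checkAxis(axis)
  Z <- asRowMatrix(Z, model@config$latentDim)
  if (!nrow(Z)) stop("empty evaluation set")
  G <- length(model@geneIds)
  sumCos <- numeric(G)
  nValid <- integer(G)
  sumProj <- numeric(G)
  for (i in seq_len(nrow(Z))) {
    J <- decoderJacobian(model, Z[i, ])        # latentDim x genes
    proj <- drop(axis@axis %*% J)              # per-gene projection on a
    nrm <- sqrt(colSums(J^2))
    ok <- nrm > 0
    sumCos[ok] <- sumCos[ok] + proj[ok] / (nrm[ok] * aNorm)
    nValid <- nValid + ok
    sumProj <- sumProj + proj / aNorm
  }
  if (any(nValid == 0)) {
    warning(sum(nValid == 0), " gene(s) had zero-norm gradients at every ",
            "evaluation point; their score is NA")
  }
  s <- ifelse(nValid > 0, sumCos / pmax(nValid, 1), NA_real_)
  sTilde <- sumProj / nrow(Z)
  ord <- order(-abs(s), model@geneIds, na.last = TRUE)
  rank <- integer(G)
  rank[ord] <- seq_len(G)
  out <- data.frame(gene_id = model@geneIds, s = s, sTilde = sTilde,
                    rank = rank, n_eval_points = nrow(Z),
                    n_skipped = nrow(Z) - nValid,
                    stringsAsFactors = FALSE)
  attr(out, "evalInfo") <- list(nPoints = nrow(Z),
                                axisNorm = aNorm,
                                groupSizes = axis@groupSizes)
  out
}

#' Symmetric-change baseline score
#'
#' Decodes the NB means at the coordinate-wise median latent of each
#' condition and scores each gene by the symmetric change
#' `b = (m1 - m0) / (0.5 * (m1 + m0))`, bounded in `[-2, 2]`. Genes with
#' `m1 = m0 = 0` are assigned 0.
#'
#' @param model An [NBVAE-class] model.
#' @param latents Latent embeddings with cell identifiers as rownames.
#' @param labels Binary label table or 0/1 vector (as in
#'   [perturbationAxis()]).
#' @return Named numeric vector of per-gene baseline scores.
#' @export
baselineSymmetricChange <- function(model, latents, labels) {
  latents <- as.matrix(latents)
  if (is.data.frame(labels)) {
    idx <- match(labels$cell_id, rownames(latents))
    ok <- !is.na(idx) & !is.na(labels$label)
    lab <- rep(NA_real_, nrow(latents))
    lab[idx[ok]] <- labels$label[ok]
  } else lab <- as.numeric(labels)
  g0 <- which(lab == 0); g1 <- which(lab == 1)
  if (!length(g0) || !length(g1)) {
    stop("both conditions must be non-empty")
  }
  zMed0 <- apply(latents[g0, , drop = FALSE], 2, median)
  zMed1 <- apply(latents[g1, , drop = FALSE], 2, median)
  m0 <- drop(decodeMean(model, zMed0))
  m1 <- drop(decodeMean(model, zMed1))
  denom <- 0.5 * (m1 + m0)
  b <- ifelse(denom == 0, 0, (m1 - m0) / denom)
  names(b) <- model@geneIds
  b
}

#' Top-K genes by absolute score
#'
#' @param scores Either the data.frame from [scoreGenes()] or a named
#'   numeric vector of per-gene scores.
#' @param k Number of genes to return (default 200).
#' @return Character vector of gene identifiers sorted by `|score|`
#'   descending, ties broken by identifier ascending (deterministic).
#' @export
topKGenes <- function(scores, k = 200) {
  if (is.data.frame(scores)) {
    ids <- scores$gene_id; val <- scores$s
  } else {
    ids <- names(scores); val <- as.numeric(scores)
  }
  if (k > length(ids)) stop("k exceeds the number of genes")
  ids[order(-abs(val), ids, na.last = TRUE)][seq_len(k)]
}

#' Write gene scores as TSV
#' @param scores data.frame from [scoreGenes()], optionally with a
#'   baseline column `b` added.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeScores <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
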