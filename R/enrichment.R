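## Overrepresentation analysis: GMT parsing, one-sided hypergeometric
## test, Benjamini-Hochberg FDR. This is the standard ORA computation
## (the same statistic hosted ORA services compute), implemented in-repo
## so it is testable offline.

#' Read a GMT gene-set collection
#'
#' Tab-separated lines `name<TAB>description<TAB>member1<TAB>member2...`.
#' Lines with fewer than three fields are skipped with a warning, as are
#' empty lines; duplicated set names are an error. Set members are kept
#' verbatim; intersection with the universe happens at test time.
#'
#' @param path GMT file path.
#' @param universe Background gene universe (character vector). Defaults
#'   to the union of all set members; in practice pass the genes scored
#'   by the model.
#' @return A [GeneSetCollection-class].
#' @export
readGMT <- function(path, universe = NULL) {
  lines <- readLines(path)
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) {
      warning("empty line ", i, " skipped")
      next
    }
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      warning("malformed GMT line ", i, " (fewer than 3 fields) skipped")
      next
    }
    nm <- fields[1]
    if (nm %in% names(sets)) stop("duplicate set name: ", nm)
    sets[[nm]] <- unique(fields[-(1:2)])
    desc[nm] <- fields[2]
  }
  if (is.null(universe)) universe <- unique(unlist(sets))
  new("GeneSetCollection", sets = sets, descriptions = desc,
      universe = unique(universe))
}

#' One-sided hypergeometric overrepresentation test
#'
#' Upper-tail probability `P(X >= overlap)` of drawing at least the
#' observed overlap when `|selected|` genes are drawn without replacement
#' from the universe containing `|geneset|` successes. Selected genes and
#' the gene set are intersected with the universe first.
#'
#' @param selected Character vector of selected genes (e.g. top-K).
#' @param universe Background universe.
#' @param geneset Character vector of gene-set members.
#' @return List with `p`, `overlap`, `setSize` (in universe),
#'   `selectedSize`, `universeSize`.
#' @export
oraTest <- function(selected, universe, geneset) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  selected <- intersect(unique(selected), universe)
  if (!length(selected)) stop("empty selection after universe intersection")
  geneset <- intersect(unique(geneset), universe)
  k <- length(intersect(selected, geneset))
  K <- length(geneset)
  N <- length(universe)
  n <- length(selected)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(p = p, overlap = k, setSize = K, selectedSize = n,
       universeSize = N)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (delegates to
#' `stats::p.adjust(method = "BH")`); order of the input is preserved.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted values, same order as input.
#' @export
bhFDR <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Overrepresentation analysis of a gene selection
#'
#' Tests every set of the collection (after intersecting with the
#' universe and applying the set-size filters) against the selection and
#' adjusts p-values by Benjamini-Hochberg.
#'
#' @param selected Character vector of selected genes.
#' @param collection A [GeneSetCollection-class].
#' @param minSize,maxSize Set-size filters applied after universe
#'   intersection (defaults 5 and 500).
#' @return data.frame with one row per tested set (`set`, `description`,
#'   `overlap`, `set_size`, `selected_size`, `universe_size`, `p`,
#'   `fdr`), sorted by p-value.
#' @export
runORA <- function(selected, collection, minSize = 5, maxSize = 500) {
  uni <- collection@universe
  sizes <- vapply(collection@sets,
                  function(s) length(intersect(s, uni)), integer(1))
  keep <- sizes >= minSize & sizes <= maxSize
  if (!any(keep)) {
    return(data.frame(set = character(), description = character(),
                      overlap = integer(), set_size = integer(),
                      selected_size = integer(), universe_size = integer(),
                      p = numeric(), fdr = numeric()))
  }
  res <- lapply(names(collection@sets)[keep], function(nm) {
    t <- oraTest(selected, uni, collection@sets[[nm]])
    data.frame(set = nm,
               description = unname(collection@descriptions[nm]),
               overlap = t$overlap, set_size = t$setSize,
               selected_size = t$selectedSize,
               universe_size = t$universeSize, p = t$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bhFDR(out$p)
  out[order(out$p, out$set), , drop = FALSE]
}
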