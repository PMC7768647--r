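#' @import methods
NULL

#' Weighted bipartite phenolic-gene interaction network
#'
#' An `InteractionNetwork` holds the two node sets of the bipartite graph
#' (phenolics on one side, CSC genes on the other) together with the edge
#' table. Each edge carries the raw interaction count (how many times the
#' phenolic was reported to interact with the gene) and its normalized
#' weight, the absolute z-score of the count. Both node sets are derived
#' from the edge table, so every retained phenolic and every retained gene
#' has degree at least one by construction.
#'
#' @slot edges data.frame with columns `phenolic`, `gene`, `raw`
#'   (non-negative count) and `norm` (non-negative absolute z-score).
#' @slot phenolics character vector of unique phenolic identifiers, sorted.
#' @slot genes character vector of the retained gene symbols, sorted; this
#'   is the ordered set of n genes that survived preprocessing.
#' @slot scope scope used for the z-score normalization, `"global"` (one
#'   mean/sd over all edges) or `"perPhenolic"`.
#'
#' @seealso [buildNetwork()], [normalizeWeights()]
#' @exportClass InteractionNetwork
setClass("InteractionNetwork",
  slots = c(
    edges = "data.frame",
    phenolics = "character",
    genes = "character",
    scope = "character"
  )
)

setValidity("InteractionNetwork", function(object) {
  e <- object@edges
  need <- c("phenolic", "gene", "raw", "norm")
  if (!all(need %in% names(e)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  if (nrow(e) == 0L)
    return("network must contain at least one edge")
  if (anyDuplicated(paste(e$phenolic, e$gene, sep = "\r")))
    return("duplicate (phenolic, gene) edges")
  if (any(e$raw < 0))
    return("raw weights must be non-negative")
  if (any(!is.finite(e$norm)) || any(e$norm < 0))
    return("normalized weights must be finite and non-negative")
  if (!setequal(object@phenolics, unique(e$phenolic)))
    return("phenolic set must equal the phenolics incident to edges")
  if (!setequal(object@genes, unique(e$gene)))
    return("gene set must equal the genes incident to edges")
  if (!object@scope %in% c("global", "perPhenolic"))
    return("scope must be 'global' or 'perPhenolic'")
  TRUE
})

#' Per-gene disease-association scores
#'
#' A `GeneScores` object stores, for each gene, the disease-association
#' counts and the derived disease specificity index (DSI, in \[0, 1\]) and
#' disease pleiotropy index (DPI, in \[0, 100\]). Either index may be `NA`
#' when the source catalogue has no score for the gene; such genes are
#' treated as unscored and dropped during preprocessing.
#'
#' @slot scores data.frame with columns `gene`, `n_d` (diseases associated
#'   to the gene), `n_dc` (distinct MeSH disease classes), `dsi`, `dpi`.
#'   Count columns are `NA` when scores were supplied directly.
#' @slot nT total number of diseases in the catalogue (NA if unknown).
#' @slot nTc total number of MeSH disease classes (NA if unknown).
#'
#' @seealso [GeneScores()], [loadGeneScores()], [geneWeights()]
#' @exportClass GeneScores
setClass("GeneScores",
  slots = c(scores = "data.frame", nT = "integer", nTc = "integer")
)

setValidity("GeneScores", function(object) {
  s <- object@scores
  need <- c("gene", "n_d", "n_dc", "dsi", "dpi")
  if (!all(need %in% names(s)))
    return(paste("scores must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(s$gene))
    return("duplicate gene symbols in score table")
  ok_dsi <- is.na(s$dsi) | (s$dsi >= -1e-12 & s$dsi <= 1 + 1e-12)
  if (!all(ok_dsi))
    return("dsi values must lie in [0, 1]")
  ok_dpi <- is.na(s$dpi) | (s$dpi >= -1e-9 & s$dpi <= 100 + 1e-9)
  if (!all(ok_dpi))
    return("dpi values must lie in [0, 100]")
  if (!is.na(object@nT) && object@nT < 2L)
    return("nT must be at least 2")
  if (!is.na(object@nTc) && object@nTc < 1L)
    return("nTc must be at least 1")
  cnt <- !is.na(s$n_d)
  if (any(s$n_d[cnt] < 0))
    return("n_d must be non-negative")
  if (any(!is.na(s$n_dc) & s$n_dc < 0))
    return("n_dc must be non-negative")
  TRUE
})

#' State of a phenolic ranking run
#'
#' Holds the per-phenolic rank values (renormalized to sum to one for the
#' normalized engines), the per-phenolic score multipliers s(p) where
#' applicable, the iteration count, the convergence flag, and the final
#' ordering (descending value, ties broken lexicographically by
#' identifier).
#'
#' @slot values named numeric vector of rank values, one per phenolic.
#' @slot sScores named numeric vector of s(p) multipliers (empty for the
#'   classic PageRank engine).
#' @slot iteration number of update iterations performed.
#' @slot converged whether the stopping criterion was met before the
#'   iteration cap.
#' @slot order phenolic identifiers sorted by decreasing rank value.
#'
#' @seealso [rankPhenolics()], [pagerankClassic()], [initializeRanks()]
#' @exportClass RankState
setClass("RankState",
  slots = c(
    values = "numeric",
    sScores = "numeric",
    iteration = "numeric",
    converged = "logical",
    order = "character"
  )
)

setValidity("RankState", function(object) {
  v <- object@values
  if (is.null(names(v)) || anyDuplicated(names(v)))
    return("values must be uniquely named by phenolic id")
  if (any(!is.finite(v)) || any(v < 0))
    return("rank values must be finite and non-negative")
  if (!setequal(object@order, names(v)) ||
      length(object@order) != length(v))
    return("order must be a permutation of the phenolic ids")
  if (length(object@sScores) &&
      !setequal(names(object@sScores), names(v)))
    return("sScores must be named by the same phenolic ids")
  if (object@iteration < 0L)
    return("iteration must be non-negative")
  TRUE
})

setMethod("show", "InteractionNetwork", function(object) {
  cat(sprintf(
    "InteractionNetwork: %d phenolics x %d genes, %d edges (%s scope)\n",
    length(object@phenolics), length(object@genes), nrow(object@edges),
    object@scope
  ))
  cat(sprintf("  raw counts: %g-%g; normalized |z|: %.4g-%.4g\n",
    min(object@edges$raw), max(object@edges$raw),
    min(object@edges$norm), max(object@edges$norm)))
})

setMethod("show", "GeneScores", function(object) {
  s <- object@scores
  scored <- sum(!is.na(s$dsi) & !is.na(s$dpi))
  cat(sprintf("GeneScores: %d genes (%d fully scored)\n", nrow(s), scored))
  if (!is.na(object@nT))
    cat(sprintf("  catalogue: N_T = %d diseases, N_TC = %s classes\n",
      object@nT, ifelse(is.na(object@nTc), "?", object@nTc)))
})

setMethod("show", "RankState", function(object) {
  cat(sprintf("RankState: %d phenolics, %g update steps, converged: %s\n",
    length(object@values), object@iteration, object@converged))
  top <- head(object@order, 5L)
  cat("  top: ", paste(sprintf("%s (%.4g)", top, object@values[top]),
    collapse = ", "), "\n", sep = "")
})
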