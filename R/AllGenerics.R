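#' Accessors for phenoRank objects
#'
#' Small accessor generics for the S4 containers: node sets and edge table
#' of an [InteractionNetwork], score table and catalogue totals of a
#' [GeneScores], and values / ordering / convergence state of a
#' [RankState].
#'
#' @param x an `InteractionNetwork`, `GeneScores` or `RankState` object.
#' @return `phenolics` and `genes` return character vectors; `edgeTable`
#'   and `scoreTable` return data.frames; `rankValues` and `sScores`
#'   return named numeric vectors; `rankOrder` returns a character vector;
#'   `iterations` an integer; `isConverged` a logical.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("phenolics", function(x) standardGeneric("phenolics"))

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname accessors
#' @export
setGeneric("rankValues", function(x) standardGeneric("rankValues"))

#' @rdname accessors
#' @export
setGeneric("rankOrder", function(x) standardGeneric("rankOrder"))

#' @rdname accessors
#' @export
setGeneric("sScores", function(x) standardGeneric("sScores"))

#' @rdname accessors
#' @export
setGeneric("iterations", function(x) standardGeneric("iterations"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname accessors
setMethod("phenolics", "InteractionNetwork", function(x) x@phenolics)

#' @rdname accessors
setMethod("genes", "InteractionNetwork", function(x) x@genes)

#' @rdname accessors
setMethod("edgeTable", "InteractionNetwork", function(x) x@edges)

#' @rdname accessors
setMethod("genes", "GeneScores", function(x) x@scores$gene)

#' @rdname accessors
setMethod("scoreTable", "GeneScores", function(x) x@scores)

#' @rdname accessors
setMethod("rankValues", "RankState", function(x) x@values)

#' @rdname accessors
setMethod("rankOrder", "RankState", function(x) x@order)

#' @rdname accessors
setMethod("sScores", "RankState", function(x) x@sScores)

#' @rdname accessors
setMethod("iterations", "RankState", function(x) x@iteration)

#' @rdname accessors
setMethod("isConverged", "RankState", function(x) x@converged)
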