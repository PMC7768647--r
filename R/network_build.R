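#' Read a phenolic-gene interaction edge list
#'
#' Parses a 3-column tab-separated file (phenolic id, gene symbol,
#' interaction count). A header line is tolerated and detected by a
#' non-numeric third field. Duplicate (phenolic, gene) pairs are summed.
#' Fields are whitespace-trimmed; gene symbols are matched
#' case-sensitively everywhere downstream.
#'
#' @param path path to the edge-list file (UTF-8).
#' @return data.frame with columns `phenolic`, `gene`, `count`
#'   (one row per deduplicated pair).
#' @export
loadInteractions <- function(path) {
  if (!file.exists(path))
    stop("interaction file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(phenolic = character(), gene = character(),
                      count = integer(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("line ", bad[1L], ": expected 3 tab-separated fields")
  first_count <- trimws(parts[[1L]][3L])
  start <- if (grepl("^[0-9]+$", first_count)) 1L else 2L
  if (start > length(lines))
    return(data.frame(phenolic = character(), gene = character(),
                      count = integer(), stringsAsFactors = FALSE))
  rows <- seq(start, length(lines))
  fields <- vapply(parts[rows], function(f) trimws(f[1:3]), character(3L))
  phen <- fields[1L, ]; gene <- fields[2L, ]; cnt <- fields[3L, ]
  bad <- which(!grepl("^[0-9]+$", cnt))
  if (length(bad))
    stop("line ", rows[bad[1L]], ": count '", cnt[bad[1L]],
         "' is not a non-negative integer")
  count <- as.integer(cnt)
  if (any(!nzchar(phen)) || any(!nzchar(gene)))
    stop("empty phenolic id or gene symbol in interaction file")
  key <- paste(phen, gene, sep = "\r")
  agg <- rowsum(count, key)
  first <- !duplicated(key)
  out <- data.frame(phenolic = phen[first], gene = gene[first],
                    count = as.integer(agg[key[first], 1L]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a CSC gene list
#'
#' One gene symbol per line; lines starting with `#` are comments and
#' blank lines are skipped. Symbols are whitespace-trimmed and duplicates
#' collapsed.
#'
#' @param path path to the gene-list file.
#' @return character vector of unique CSC gene symbols.
#' @export
loadCscGenes <- function(path) {
  if (!file.exists(path))
    stop("CSC gene list not found: ", path)
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

#' Restrict interaction records to the CSC gene universe
#'
#' Implements the preprocessing intersection: for every phenolic, only the
#' interacting genes that are also CSC genes are retained (the common
#' genes between each interacting set and the CSC set). Matching is
#' case-sensitive string equality on trimmed symbols.
#'
#' @param records interaction data.frame from [loadInteractions()].
#' @param cscGenes character vector of CSC gene symbols (non-empty).
#' @return the surviving records; a warning is raised (not an error) when
#'   the intersection is empty.
#' @export
intersectWithCsc <- function(records, cscGenes) {
  cscGenes <- unique(trimws(cscGenes))
  if (length(cscGenes) == 0L)
    stop("CSC gene set must be non-empty")
  keep <- records$gene %in% cscGenes
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("no interaction genes overlap the CSC gene set")
  out
}

#' Drop records for genes without both DSI and DPI
#'
#' Genes absent from the score catalogue, or present with only one of the
#' two indices, are excluded: both DSI and DPI enter the ranking update,
#' so a gene counts as scored only when both are available.
#'
#' @param records interaction data.frame.
#' @param scores a [GeneScores] object.
#' @return list with `records` (surviving rows) and `genes` (the ordered
#'   retained gene set, sorted).
#' @export
dropUnscoredGenes <- function(records, scores) {
  stopifnot(is(scores, "GeneScores"))
  s <- scoreTable(scores)
  scored <- s$gene[!is.na(s$dsi) & !is.na(s$dpi)]
  keep <- records$gene %in% scored
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, genes = sort(unique(out$gene)))
}

#' Build the weighted bipartite network
#'
#' Assembles an [InteractionNetwork] from preprocessed interaction
#' records and normalizes the edge weights (absolute z-scores of the raw
#' counts; see [normalizeWeights()]).
#'
#' @param records interaction data.frame with columns `phenolic`, `gene`,
#'   `count`; pairs must already be unique (as produced by
#'   [loadInteractions()]).
#' @param scope normalization scope, `"global"` (default: one mean and
#'   standard deviation over all retained edges) or `"perPhenolic"`.
#' @return an [InteractionNetwork].
#' @export
buildNetwork <- function(records, scope = c("global", "perPhenolic")) {
  scope <- match.arg(scope)
  if (nrow(records) == 0L)
    stop("cannot build a network from zero interaction records")
  if (any(records$count < 0))
    stop("interaction counts must be non-negative")
  if (anyDuplicated(paste(records$phenolic, records$gene, sep = "\r")))
    stop("duplicate (phenolic, gene) records; deduplicate first")
  edges <- data.frame(
    phenolic = records$phenolic, gene = records$gene,
    raw = as.numeric(records$count), norm = NA_real_,
    stringsAsFactors = FALSE
  )
  edges$norm <- .absZscore(edges$raw, edges$phenolic, scope)
  new("InteractionNetwork",
    edges = edges,
    phenolics = sort(unique(edges$phenolic)),
    genes = sort(unique(edges$gene)),
    scope = scope)
}

# |(w - mu) / sigma| with population sigma; all weights 1 when sigma = 0
# so a flat network degrades to gene-weight-driven scores.
.absZscore <- function(w, group, scope) {
  z_one <- function(x) {
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))
    if (sigma == 0) rep(1, length(x)) else abs((x - mu) / sigma)
  }
  if (scope == "global") {
    z_one(w)
  } else {
    out <- numeric(length(w))
    for (g in unique(group)) {
      idx <- group == g
      out[idx] <- z_one(w[idx])
    }
    out
  }
}

#' Recompute normalized edge weights
#'
#' Raw interaction counts are z-scored (mean subtracted, divided by the
#' population standard deviation) and the absolute value taken. With the
#' default global scope a single mean/sd is computed over all retained
#' edges; with per-phenolic scope each phenolic's edges are normalized
#' against their own mean/sd. If the standard deviation is zero every
#' normalized weight is set to 1.
#'
#' @param network an [InteractionNetwork].
#' @param scope `"global"` or `"perPhenolic"`; defaults to the scope
#'   stored in the network.
#' @return the network with the `norm` column recomputed.
#' @export
normalizeWeights <- function(network, scope = network@scope) {
  stopifnot(is(network, "InteractionNetwork"))
  scope <- match.arg(scope, c("global", "perPhenolic"))
  e <- network@edges
  if (nrow(e) == 0L)
    stop("cannot normalize a network with zero edges")
  e$norm <- .absZscore(e$raw, e$phenolic, scope)
  initialize(network, edges = e, scope = scope)
}

#' Export a network edge table for audit
#'
#' Writes a 4-column TSV (phenolic, gene, raw_weight, norm_weight).
#'
#' @param network an [InteractionNetwork].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
exportNetwork <- function(network, path) {
  stopifnot(is(network, "InteractionNetwork"))
  e <- network@edges
  out <- data.frame(phenolic = e$phenolic, gene = e$gene,
                    raw_weight = e$raw, norm_weight = e$norm)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
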