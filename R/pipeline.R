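#' Run the full phenolic-ranking pipeline
#'
#' Executes load -> CSC intersection -> unscored-gene exclusion ->
#' weight normalization -> scoring -> ranking, logging the four
#' cardinalities along the way: phenolics m, CSC genes q, common genes s
#' (interaction genes inside the CSC universe) and retained genes n
#' (common genes with both DSI and DPI). Any stage failure raises an
#' error naming the stage.
#'
#' @param interactions path to the 3-column interaction TSV.
#' @param cscGenes path to the CSC gene list.
#' @param geneScores path to the gene-score TSV.
#' @param nT,nTc catalogue totals when the score file carries counts.
#' @param gwMode gene-weight combination rule; see [combineGeneWeight()].
#' @param normScope `"global"` or `"perPhenolic"` edge-weight
#'   normalization.
#' @param tol,maxIter,seed ranking parameters; see [rankPhenolics()].
#' @param outDir optional output directory; when given, writes
#'   `ranking.tsv` (rank, phenolic, final value, s score, degree),
#'   `network.tsv` (audit edge table) and `report.json` (configuration,
#'   cardinalities, iterations, convergence).
#' @return invisibly, a list with `network` ([InteractionNetwork]),
#'   `state` ([RankState]), `cardinalities` (m, q, s, n) and `ranking`
#'   (the output data.frame).
#' @export
runRankPipeline <- function(interactions, cscGenes, geneScores,
                            nT = NA_integer_, nTc = NA_integer_,
                            gwMode = "mean", normScope = "global",
                            tol = 1e-9, maxIter = 100L, seed = 1L,
                            outDir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  records <- stage("load-interactions", loadInteractions(interactions))
  csc <- stage("load-csc-genes", loadCscGenes(cscGenes))
  scores <- stage("load-gene-scores",
                  loadGeneScores(geneScores, nT = nT, nTc = nTc))
  m <- length(unique(records$phenolic))
  q <- length(csc)

  common <- stage("csc-intersection", intersectWithCsc(records, csc))
  s_card <- length(unique(common$gene))
  kept <- stage("drop-unscored", dropUnscoredGenes(common, scores))
  n_card <- length(kept$genes)
  message(sprintf(
    "phenolics m=%d, CSC genes q=%d, common genes s=%d, retained genes n=%d",
    m, q, s_card, n_card))

  network <- stage("build-network",
                   buildNetwork(kept$records, scope = normScope))
  gw <- stage("gene-weights", {
    w <- geneWeights(scores, mode = gwMode)
    w[genes(network)]
  })
  state <- stage("rank", rankPhenolics(network, gw, tol = tol,
                                       maxIter = maxIter, seed = seed))

  deg <- table(edgeTable(network)$phenolic)
  ord <- rankOrder(state)
  ranking <- data.frame(
    rank = seq_along(ord),
    phenolic = ord,
    final_value = unname(rankValues(state)[ord]),
    s_score = unname(sScores(state)[ord]),
    degree = as.integer(deg[ord]),
    stringsAsFactors = FALSE
  )

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(ranking, file.path(outDir, "ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    exportNetwork(network, file.path(outDir, "network.tsv"))
    report <- list(
      config = list(gwMode = gwMode, normScope = normScope, tol = tol,
                    maxIter = maxIter, seed = seed, nT = nT, nTc = nTc),
      cardinalities = list(m = m, q = q, s = s_card, n = n_card),
      iterations = iterations(state),
      converged = isConverged(state)
    )
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(network = network, state = state,
                 cardinalities = c(m = m, q = q, s = s_card, n = n_card),
                 ranking = ranking))
}

#' Screen property tables from files
#'
#' File-level wrapper around [screenCompounds()]: reads a
#' molecular-property CSV and/or an ADMET CSV (header aliases accepted)
#' and optionally writes the combined per-compound report as CSV and
#' JSON.
#'
#' @param propsFile path to a molecular-property CSV, or NULL.
#' @param admetFile path to an ADMET CSV, or NULL.
#' @param outDir optional output directory for `screen.csv` and
#'   `screen.json`.
#' @return the report data.frame, invisibly when `outDir` is given.
#' @export
screenFiles <- function(propsFile = NULL, admetFile = NULL,
                        outDir = NULL) {
  props <- if (!is.null(propsFile)) loadMolecularProperties(propsFile)
  admet <- if (!is.null(admetFile)) loadAdmetTable(admetFile)
  report <- screenCompounds(props, admet)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(outDir, "screen.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(outDir, "screen.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}

#' Read a run configuration file
#'
#' Loads a YAML (or flat `key: value`) run configuration; recognized
#' keys mirror the [runRankPipeline()] arguments (`interactions`,
#' `csc_genes`, `gene_scores`, `n_t`, `n_tc`, `gw_mode`, `norm_scope`,
#' `damping`, `tol`, `max_iter`, `seed`, `out`). Command-line flags are
#' expected to override file values; the CLI applies that precedence.
#'
#' @param path path to the YAML file.
#' @return named list of configuration values.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg))
    stop("config file must define a key-value mapping")
  known <- c("interactions", "csc_genes", "gene_scores", "n_t", "n_tc",
             "gw_mode", "norm_scope", "damping", "tol", "max_iter",
             "seed", "out")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg
}
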