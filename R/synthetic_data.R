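#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the scale of the curated study data: 21 phenolics, a
#' 1200-gene interaction universe of which 1118 are CSC genes, edge
#' density 0.3, interaction counts from a 1-shifted Poisson (every drawn
#' edge has count >= 1), and DisGeNet-style catalogue totals N_T = 30170
#' diseases and N_TC = 29 MeSH disease classes. An optional planted
#' phenolic has its counts on the top-decile-gw genes multiplied by
#' `boostFactor`, giving it a deliberately dominant score for recovery
#' tests.
#'
#' @param nPhenolics number of phenolics.
#' @param nGenes number of genes in the interaction universe.
#' @param nCsc number of genes flagged as CSC (`<= nGenes`).
#' @param density edge probability in (0, 1].
#' @param countMean mean of the Poisson part of the count law; drawn
#'   counts are `1 + Poisson(countMean)`.
#' @param plantedPhenolic id of the phenolic to plant (e.g. `"P01"`), or
#'   NULL for no planted signal.
#' @param boostFactor multiplier (>= 1) applied to the planted
#'   phenolic's counts on the top-decile-gw genes.
#' @param nT,nTc catalogue totals used to draw and score gene
#'   associations.
#' @param seed integer seed; all generator randomness flows from it.
#' @return a validated list of class `synthConfig`.
#' @export
synthConfig <- function(nPhenolics = 21L, nGenes = 1200L, nCsc = 1118L,
                        density = 0.3, countMean = 2,
                        plantedPhenolic = NULL, boostFactor = 5,
                        nT = 30170L, nTc = 29L, seed = 1L) {
  cfg <- list(
    nPhenolics = as.integer(nPhenolics), nGenes = as.integer(nGenes),
    nCsc = as.integer(nCsc), density = density, countMean = countMean,
    plantedPhenolic = plantedPhenolic, boostFactor = boostFactor,
    nT = as.integer(nT), nTc = as.integer(nTc), seed = as.integer(seed)
  )
  if (cfg$nPhenolics < 1L) stop("nPhenolics must be at least 1")
  if (cfg$nGenes < 1L) stop("nGenes must be at least 1")
  if (cfg$nCsc < 1L || cfg$nCsc > cfg$nGenes)
    stop("nCsc must lie in [1, nGenes]")
  if (!is.numeric(cfg$density) || cfg$density <= 0 || cfg$density > 1)
    stop("density must lie in (0, 1]")
  if (cfg$countMean < 0) stop("countMean must be non-negative")
  if (cfg$boostFactor < 1) stop("boostFactor must be at least 1")
  if (cfg$nT < 2L) stop("nT must be at least 2")
  if (cfg$nTc < 1L) stop("nTc must be at least 1")
  if (!is.null(cfg$plantedPhenolic)) {
    cfg$plantedPhenolic <- as.character(cfg$plantedPhenolic)
    ids <- sprintf("P%02d", seq_len(cfg$nPhenolics))
    if (!cfg$plantedPhenolic %in% ids)
      stop("plantedPhenolic must be one of ", ids[1L], "..",
           ids[length(ids)])
  }
  class(cfg) <- "synthConfig"
  cfg
}

#' Generate a synthetic interaction dataset
#'
#' Writes the three input files the ranking pipeline consumes --
#' `interactions.tsv` (phenolic, gene, count), `csc_genes.txt` (one
#' symbol per line) and `gene_scores.tsv` (gene, n_d, n_dc) -- plus a
#' `truth.json` record of the configuration and planted signal. Every
#' possible (phenolic, gene) edge is drawn independently with
#' probability `density`; counts follow a 1-shifted Poisson; each gene
#' receives `n_d` uniform in \[1, nT\] (so DSI is always defined) and
#' `n_dc` uniform in \[0, nTc\]. When a phenolic is planted, its counts
#' on the genes in the top decile of combined gene weight gw are
#' multiplied by `boostFactor`. Output is byte-identical for a given
#' configuration and seed.
#'
#' @param config a [synthConfig()] list.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the four file paths and the truth
#'   record.
#' @export
generateSyntheticData <- function(config = synthConfig(),
                                  dir = tempfile("synth")) {
  stopifnot(inherits(config, "synthConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  pids <- sprintf("P%02d", seq_len(config$nPhenolics))
  gids <- sprintf("G%05d", seq_len(config$nGenes))

  csc <- sort(sample(gids, config$nCsc))
  n_d <- sample.int(config$nT, config$nGenes, replace = TRUE)
  n_dc <- sample.int(config$nTc + 1L, config$nGenes, replace = TRUE) - 1L
  dsi <- computeDsi(n_d, config$nT)
  dpi <- computeDpi(n_dc, config$nTc)
  gw <- combineGeneWeight(dsi, dpi, "mean")
  top_decile <- gids[gw >= stats::quantile(gw, 0.9)]

  ne <- config$nPhenolics * config$nGenes
  present <- stats::runif(ne) < config$density
  phen <- rep(pids, each = config$nGenes)[present]
  gene <- rep(gids, times = config$nPhenolics)[present]
  count <- 1L + stats::rpois(sum(present), config$countMean)
  if (!is.null(config$plantedPhenolic)) {
    boost <- phen == config$plantedPhenolic & gene %in% top_decile
    count[boost] <- as.integer(round(count[boost] * config$boostFactor))
  }

  interactions_path <- file.path(dir, "interactions.tsv")
  csc_path <- file.path(dir, "csc_genes.txt")
  scores_path <- file.path(dir, "gene_scores.tsv")
  truth_path <- file.path(dir, "truth.json")

  utils::write.table(
    data.frame(phenolic = phen, gene = gene, count = count),
    interactions_path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c("# synthetic CSC gene list", csc), csc_path)
  utils::write.table(
    data.frame(gene = gids, n_d = n_d, n_dc = n_dc),
    scores_path, sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- list(
    config = unclass(config)[!vapply(unclass(config), is.null, TRUE)],
    planted = config$plantedPhenolic,
    boosted_genes = if (is.null(config$plantedPhenolic)) character(0)
                    else top_decile,
    n_edges = sum(present)
  )
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(interactions = interactions_path, csc = csc_path,
                 scores = scores_path, truth_file = truth_path,
                 truth = truth))
}

#' Packaged fixtures: the curated phenolic and property tables
#'
#' Returns the three tables shipped with the package: the 21 curated
#' phenolics with chemical formulas and dietary sources, the
#' molecular-property table for the top five ranked phenolics, and their
#' ADMET profile table.
#'
#' @return list with data.frames `phenolics` (21 rows), `properties`
#'   (5 rows, canonical molecular-property columns) and `admet` (5 rows,
#'   canonical ADMET columns).
#' @export
loadFixtures <- function() {
  ext <- function(f) system.file("extdata", f, package = "phenoRank",
                                 mustWork = TRUE)
  phen <- utils::read.delim(ext("phenolics_table1.tsv"),
                            stringsAsFactors = FALSE)
  list(
    phenolics = phen,
    properties = loadMolecularProperties(
      ext("molecular_properties_table2.csv")),
    admet = loadAdmetTable(ext("admet_table3.csv"))
  )
}
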