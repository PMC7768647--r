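#' Disease specificity index (DSI)
#'
#' DSI measures how disease-specific a gene's associations are:
#' `DSI = log2(N_d / N_T) / log2(1 / N_T)`, where `N_d` is the number of
#' diseases associated to the gene and `N_T` the total number of diseases
#' in the catalogue. A gene associated with a single disease scores 1; a
#' gene associated with every disease scores 0.
#'
#' @param n_d number of diseases associated to the gene; vectorized.
#'   Must satisfy `1 <= n_d <= n_t` (a gene with no associations has no
#'   defined DSI and should have been dropped upstream).
#' @param n_t total number of diseases in the catalogue, at least 2.
#' @return numeric vector of DSI values in \[0, 1\].
#' @examples
#' computeDsi(1, 30170)   # 1: maximally specific
#' computeDsi(2, 4)       # 0.5
#' @export
computeDsi <- function(n_d, n_t) {
  if (length(n_t) != 1L || is.na(n_t) || n_t < 2)
    stop("n_t must be a single catalogue size >= 2")
  if (any(is.na(n_d)) || any(n_d < 1))
    stop("n_d must be >= 1 (DSI is undefined for a gene with no diseases)")
  if (any(n_d > n_t))
    stop("n_d cannot exceed the catalogue size n_t")
  # + 0 normalizes the IEEE negative zero arising at n_d = n_t
  log2(n_d / n_t) / log2(1 / n_t) + 0
}

#' Disease pleiotropy index (DPI)
#'
#' DPI measures how many distinct MeSH disease classes a gene's associated
#' diseases span, as a percentage: `DPI = (N_dc / N_TC) * 100`.
#'
#' @param n_dc number of distinct MeSH disease classes for the gene;
#'   vectorized.
#' @param n_tc total number of MeSH disease classes, at least 1.
#' @return numeric vector of DPI values in \[0, 100\].
#' @examples
#' computeDpi(29, 29)  # 100
#' computeDpi(7, 28)   # 25
#' @export
computeDpi <- function(n_dc, n_tc) {
  if (length(n_tc) != 1L || is.na(n_tc) || n_tc < 1)
    stop("n_tc must be a single class count >= 1")
  if (any(is.na(n_dc)) || any(n_dc < 0))
    stop("n_dc must be non-negative")
  if (any(n_dc > n_tc))
    stop("n_dc cannot exceed the total class count n_tc")
  (n_dc / n_tc) * 100
}

#' Combine DSI and DPI into a single gene weight
#'
#' The ranking update weights each gene by one number gw in \[0, 1\]
#' derived from its DSI and DPI. DPI is first rescaled to \[0, 1\] by
#' dividing by 100; the two are then merged according to `mode`:
#' arithmetic mean (default), product, or either index alone.
#'
#' @param dsi DSI values in \[0, 1\]; vectorized.
#' @param dpi DPI values in \[0, 100\]; vectorized.
#' @param mode one of `"mean"`, `"product"`, `"dsi_only"`, `"dpi_only"`.
#' @return numeric vector of gene weights in \[0, 1\].
#' @examples
#' combineGeneWeight(0.5, 50)               # 0.5
#' combineGeneWeight(0.5, 50, "product")    # 0.25
#' @export
combineGeneWeight <- function(dsi, dpi,
                              mode = c("mean", "product",
                                       "dsi_only", "dpi_only")) {
  mode <- match.arg(mode)
  if (any(dsi < -1e-12 | dsi > 1 + 1e-12, na.rm = TRUE))
    stop("dsi must lie in [0, 1]")
  if (any(dpi < -1e-9 | dpi > 100 + 1e-9, na.rm = TRUE))
    stop("dpi must lie in [0, 100]")
  p <- dpi / 100
  switch(mode,
    mean = (dsi + p) / 2,
    product = dsi * p,
    dsi_only = dsi + 0 * p,
    dpi_only = p + 0 * dsi
  )
}

#' Construct a GeneScores object
#'
#' Builds the per-gene score container either from disease-association
#' counts (`n_d`, `n_dc`, with catalogue totals `nT`, `nTc`, from which
#' DSI and DPI are computed) or from precomputed `dsi`/`dpi` columns.
#' When both counts and precomputed scores are supplied, the precomputed
#' scores take precedence.
#'
#' @param genes character vector of gene symbols (whitespace-trimmed,
#'   matched case-sensitively).
#' @param n_d,n_dc integer association counts, or NULL.
#' @param dsi,dpi precomputed scores, or NULL.
#' @param nT,nTc catalogue totals (required when scores are derived from
#'   counts).
#' @return a [GeneScores] object.
#' @export
GeneScores <- function(genes, n_d = NULL, n_dc = NULL,
                       dsi = NULL, dpi = NULL,
                       nT = NA_integer_, nTc = NA_integer_) {
  genes <- trimws(as.character(genes))
  if (anyDuplicated(genes))
    stop("duplicate gene symbols in score input")
  n <- length(genes)
  fill <- function(x) if (is.null(x)) rep(NA_real_, n) else as.numeric(x)
  n_d <- fill(n_d); n_dc <- fill(n_dc)
  dsi <- fill(dsi); dpi <- fill(dpi)
  nT <- as.integer(nT); nTc <- as.integer(nTc)

  from_counts <- is.na(dsi) & !is.na(n_d)
  if (any(from_counts)) {
    if (is.na(nT))
      stop("catalogue total nT is required to derive DSI from counts")
    dsi[from_counts] <- computeDsi(n_d[from_counts], nT)
  }
  from_counts <- is.na(dpi) & !is.na(n_dc)
  if (any(from_counts)) {
    if (is.na(nTc))
      stop("catalogue total nTc is required to derive DPI from counts")
    dpi[from_counts] <- computeDpi(n_dc[from_counts], nTc)
  }
  new("GeneScores",
    scores = data.frame(gene = genes, n_d = n_d, n_dc = n_dc,
                        dsi = dsi, dpi = dpi, stringsAsFactors = FALSE),
    nT = nT, nTc = nTc)
}

#' Read a gene-score table from a TSV file
#'
#' Accepts either count columns (`gene`, `n_d`, `n_dc`; catalogue totals
#' supplied via `nT`/`nTc`) or precomputed score columns (`gene`, `dsi`,
#' `dpi`). Files carrying both are allowed; precomputed scores win.
#'
#' @param path path to a tab-separated file with a header row.
#' @param nT,nTc catalogue totals, needed only for count input.
#' @return a [GeneScores] object.
#' @export
loadGeneScores <- function(path, nT = NA_integer_, nTc = NA_integer_) {
  if (!file.exists(path))
    stop("gene-score file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  names(tab) <- tolower(trimws(names(tab)))
  if (!"gene" %in% names(tab))
    stop("gene-score file must have a 'gene' column")
  has_counts <- all(c("n_d", "n_dc") %in% names(tab))
  has_scores <- all(c("dsi", "dpi") %in% names(tab))
  if (!has_counts && !has_scores)
    stop("gene-score file must have either (n_d, n_dc) or (dsi, dpi) columns")
  GeneScores(
    genes = tab$gene,
    n_d = if (has_counts) tab$n_d else NULL,
    n_dc = if (has_counts) tab$n_dc else NULL,
    dsi = if (has_scores) tab$dsi else NULL,
    dpi = if (has_scores) tab$dpi else NULL,
    nT = nT, nTc = nTc
  )
}

#' Combined gene weights for a score set
#'
#' @param scores a [GeneScores] object.
#' @param mode combination rule passed to [combineGeneWeight()].
#' @return named numeric vector of gene weights gw in \[0, 1\]; genes
#'   lacking either score get `NA` (and should have been dropped by
#'   [dropUnscoredGenes()]).
#' @export
geneWeights <- function(scores, mode = "mean") {
  stopifnot(is(scores, "GeneScores"))
  s <- scoreTable(scores)
  gw <- rep(NA_real_, nrow(s))
  ok <- !is.na(s$dsi) & !is.na(s$dpi)
  if (any(ok))
    gw[ok] <- combineGeneWeight(s$dsi[ok], s$dpi[ok], mode)
  names(gw) <- s$gene
  gw
}
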