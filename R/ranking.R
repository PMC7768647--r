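#' Classic PageRank by power iteration
#'
#' Reference engine for the ranking module: the damped random-surfer
#' recursion `PR(A) = (1-d)/N + d * sum_i PR(T_i)/C(T_i)` iterated to a
#' fixed point. `C(T_i)` is the out-degree of page `T_i`; dangling nodes
#' (out-degree zero) spread their mass uniformly. With `normalized =
#' TRUE` (default) the teleport term is divided by the node count so the
#' rank vector is a probability distribution summing to one; with
#' `normalized = FALSE` the teleport term is the literal `(1 - d)` and
#' the fixed point sums to N instead.
#'
#' @param adjacency square numeric adjacency matrix of a directed graph;
#'   `adjacency[i, j] > 0` means an edge i -> j. Row/column names, when
#'   present, name the nodes.
#' @param damping damping factor d in (0, 1); default 0.85.
#' @param tol convergence tolerance on the max-norm change between
#'   successive rank vectors; default 1e-9.
#' @param maxIter iteration cap; non-convergence within the cap returns
#'   the current state with `converged = FALSE` and a warning.
#' @param normalized divide the teleport term by the node count (TRUE,
#'   default) or use the literal form (FALSE).
#' @return a [RankState].
#' @examples
#' A <- matrix(0, 2, 2); A[1, 2] <- A[2, 1] <- 1
#' rankValues(pagerankClassic(A))  # 0.5, 0.5
#' @export
pagerankClassic <- function(adjacency, damping = 0.85, tol = 1e-9,
                            maxIter = 100L, normalized = TRUE) {
  A <- as.matrix(adjacency)
  if (nrow(A) == 0L || nrow(A) != ncol(A))
    stop("adjacency must be a non-empty square matrix")
  if (any(A < 0))
    stop("adjacency weights must be non-negative")
  if (damping <= 0 || damping >= 1)
    stop("damping must lie strictly between 0 and 1")
  n <- nrow(A)
  ids <- rownames(A)
  if (is.null(ids)) ids <- sprintf("n%d", seq_len(n))

  out_deg <- rowSums(A)
  dangling <- out_deg == 0
  # column-stochastic link matrix M[j, i] = A[i, j] / C(i)
  M <- t(A / ifelse(out_deg == 0, 1, out_deg))
  tele <- if (normalized) 1 / n else 1

  r <- rep(tele, n)
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    r_new <- (1 - damping) * tele +
      damping * (as.vector(M %*% r) + sum(r[dangling]) / n)
    delta <- max(abs(r_new - r))
    r <- r_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("PageRank did not converge within ", maxIter, " iterations")
  names(r) <- ids
  new("RankState", values = r, sScores = numeric(0),
      iteration = iter, converged = converged,
      order = ids[order(-r, ids)])
}

#' Seeded random initialization of phenolic ranks
#'
#' Draws a uniform (0, 1) value per phenolic from a seeded generator and
#' renormalizes to sum one; the initial ordering is the descending order
#' of those values.
#'
#' @param phenolics character vector of phenolic identifiers.
#' @param seed integer seed; the same seed reproduces the same state.
#' @return a [RankState] with `iteration = 0`.
#' @export
initializeRanks <- function(phenolics, seed = 1L) {
  phenolics <- as.character(phenolics)
  if (length(phenolics) == 0L)
    stop("at least one phenolic is required")
  if (anyDuplicated(phenolics))
    stop("phenolic ids must be unique")
  r <- local({
    set.seed(as.integer(seed))
    stats::runif(length(phenolics))
  })
  r <- r / sum(r)
  names(r) <- phenolics
  new("RankState", values = r, sScores = numeric(0),
      iteration = 0L, converged = FALSE,
      order = phenolics[order(-r, phenolics)])
}

#' Per-phenolic score multiplier s(p)
#'
#' For a phenolic interacting with x genes, the multiplier is the
#' gene-weighted normalized edge mass divided by the degree:
#' `s(p) = sum_i norm_i * gw_i / x`. This is the constant factor applied
#' to the phenolic's rank at every iteration of [rankPhenolics()].
#'
#' @param network an [InteractionNetwork].
#' @param geneWeights named numeric vector of gene weights gw in
#'   \[0, 1\], covering every retained gene of the network.
#' @return named numeric vector of s(p) values, one per phenolic (ordered
#'   as `phenolics(network)`).
#' @export
phenolicScores <- function(network, geneWeights) {
  stopifnot(is(network, "InteractionNetwork"))
  e <- edgeTable(network)
  gw <- geneWeights[e$gene]
  if (any(is.na(gw))) {
    missing <- unique(e$gene[is.na(gw)])
    stop("no gene weight for retained gene(s): ",
         paste(head(missing, 5L), collapse = ", "))
  }
  if (any(geneWeights < 0, na.rm = TRUE))
    stop("gene weights must be non-negative")
  num <- rowsum(e$norm * gw, e$phenolic)
  deg <- rowsum(rep(1, nrow(e)), e$phenolic)
  s <- (num / deg)[, 1L]
  s[phenolics(network)]
}

#' Rank phenolics by iterated multiplicative update
#'
#' The core ranking engine: starting from seeded random ranks, each
#' iteration multiplies every phenolic's rank by its fixed score
#' multiplier s(p) (see [phenolicScores()]) and renormalizes the vector
#' to sum one. Iteration stops when the ranking is stationary -- the
#' ordering is unchanged between consecutive checks, is concordant
#' with the multipliers (so no further swap is pending among numerically
#' vanished values), and the max-norm value change is below `tol` -- or
#' once `maxIter` update steps have been applied. Because the update is
#' multiplicative with constant factors, the stationary ordering is the
#' descending s(p) ordering whenever the s(p) are distinct, independent
#' of the random start.
#'
#' Numerics: k update steps compose exactly to
#' `log r_k = log r_0 + k log s` up to renormalization, so the engine
#' works in log space and checks convergence on a geometric schedule of
#' step counts (1, 2, 4, ..., capped at `maxIter`). Near-tied
#' multipliers can need millions of elementary steps before their
#' ordering settles; the closed-form composition reaches that point at
#' logarithmic cost without approximating the update. When the
#' multipliers carry no information (all equal, including all-zero),
#' the engine returns uniform values with lexicographic ordering and a
#' warning.
#'
#' @param network an [InteractionNetwork].
#' @param geneWeights named numeric vector of gene weights gw, or a
#'   [GeneScores] object (combined with `gwMode`).
#' @param gwMode combination rule when `geneWeights` is a `GeneScores`
#'   object; see [combineGeneWeight()].
#' @param tol convergence tolerance on the max-norm value change;
#'   default 1e-9.
#' @param maxIter cap on the number of update steps; default 100.
#'   Large caps (1e9) are cheap because of the geometric schedule.
#' @param seed seed for the random initialization.
#' @return a [RankState]; `rankOrder()` of the result is the deliverable
#'   ranking (descending value, ties lexicographic).
#' @export
rankPhenolics <- function(network, geneWeights, gwMode = "mean",
                          tol = 1e-9, maxIter = 100L, seed = 1L) {
  stopifnot(is(network, "InteractionNetwork"))
  if (is(geneWeights, "GeneScores"))
    geneWeights <- geneWeights(geneWeights, mode = gwMode)
  if (tol <= 0) stop("tol must be positive")
  if (maxIter < 1) stop("maxIter must be at least 1")
  s <- phenolicScores(network, geneWeights)
  ids <- names(s)
  n <- length(ids)

  if (max(s) - min(s) == 0) {
    if (all(s == 0))
      warning("all phenolic scores are zero; returning uniform ranking")
    else
      warning("all phenolic scores are equal; returning uniform ranking")
    v <- rep(1 / n, n); names(v) <- ids
    return(new("RankState", values = v, sScores = s, iteration = 0,
               converged = TRUE, order = sort(ids)))
  }

  init <- initializeRanks(ids, seed = seed)
  log_r0 <- log(rankValues(init))
  log_s <- log(s)  # -Inf for s = 0 is fine: mass vanishes after one step

  at_k <- function(k) {
    log_r <- log_r0 + k * log_s
    log_r <- log_r - .logSumExp(log_r)
    list(vals = exp(log_r), ord = order(-log_r, ids))
  }

  # geometric checkpoint schedule: 1, 2, 4, ..., then exactly maxIter
  ks <- 2^(0:floor(log2(maxIter)))
  if (ks[length(ks)] < maxIter) ks <- c(ks, maxIter)

  prev <- list(vals = rankValues(init), ord = order(-log_r0, ids))
  converged <- FALSE
  iter <- 0
  for (k in ks) {
    cur <- at_k(k)
    iter <- k
    stationary <- identical(cur$ord, prev$ord) &&
      max(abs(cur$vals - prev$vals)) < tol &&
      .concordant(s[cur$ord])
    prev <- cur
    if (stationary) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("ranking did not stabilize within ", maxIter, " steps")
  vals <- prev$vals
  names(vals) <- ids
  new("RankState", values = vals, sScores = s, iteration = iter,
      converged = converged, order = ids[prev$ord])
}

.logSumExp <- function(x) {
  m <- max(x[is.finite(x)])
  m + log(sum(exp(x - m)))
}

# A ranking is a true fixed point of the multiplicative update iff the
# multipliers are non-increasing along it (ties keep their ratio forever).
.concordant <- function(s_sorted) {
  all(diff(s_sorted) <= 0)
}
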