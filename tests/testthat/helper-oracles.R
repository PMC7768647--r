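# Independent oracles and small fixture builders used across the suite.

# Principal eigenvector of the Google matrix, computed by a dense
# eigensolve -- independent of the power-iteration engine under test.
eigenPagerank <- function(A, damping = 0.85) {
  n <- nrow(A)
  out_deg <- rowSums(A)
  P <- t(A / ifelse(out_deg == 0, 1, out_deg))
  P[, out_deg == 0] <- 1 / n
  G <- damping * P + (1 - damping) / n
  ev <- eigen(G)$vectors[, 1L]
  ev <- Re(ev)
  ev / sum(ev)
}

randomDigraph <- function(n, p) {
  A <- matrix(rbinom(n * n, 1, p), n, n)
  diag(A) <- 0
  A
}

makeRecords <- function(phenolic, gene, count) {
  data.frame(phenolic = phenolic, gene = gene, count = count,
             stringsAsFactors = FALSE)
}

writeInteractionFile <- function(lines, header = TRUE) {
  path <- tempfile(fileext = ".tsv")
  if (header) lines <- c("phenolic\tgene\tcount", lines)
  writeLines(lines, path)
  path
}

# Brute-force recomputation of the per-phenolic multiplier s(p) straight
# from the emitted files, with the formulas written out independently of
# the package's code path.
bruteForceScores <- function(files, nT, nTc) {
  rec <- read.delim(files$interactions, stringsAsFactors = FALSE)
  csc <- readLines(files$csc)
  csc <- trimws(csc[!startsWith(trimws(csc), "#")])
  csc <- csc[nzchar(csc)]
  sc <- read.delim(files$scores, stringsAsFactors = FALSE)
  rec <- rec[rec$gene %in% csc, , drop = FALSE]

  dsi <- log2(sc$n_d / nT) / log2(1 / nT)
  dpi <- (sc$n_dc / nTc) * 100
  gw <- (dsi + dpi / 100) / 2
  names(gw) <- sc$gene

  mu <- mean(rec$count)
  sigma <- sqrt(mean((rec$count - mu)^2))
  z <- if (sigma == 0) rep(1, nrow(rec)) else abs((rec$count - mu) / sigma)
  vapply(split(seq_len(nrow(rec)), rec$phenolic),
         function(i) mean(z[i] * gw[rec$gene[i]]), numeric(1))
}
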