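test_that("interaction loader deduplicates, detects headers and rejects bad counts", {
  # duplicate pair summed, header detected by non-numeric third field
  path <- writeInteractionFile(c("P1\tG1\t2", "P1\tG2\t3", "P1\tG1\t4"))
  rec <- loadInteractions(path)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$count[rec$gene == "G1"], 6L)
  expect_equal(rec$count[rec$gene == "G2"], 3L)

  # same content without a header parses identically
  rec2 <- loadInteractions(
    writeInteractionFile(c("P1\tG1\t2", "P1\tG2\t3", "P1\tG1\t4"),
                         header = FALSE))
  expect_equal(rec2, rec)

  # empty file -> empty record set
  empty <- tempfile()
  file.create(empty)
  expect_equal(nrow(loadInteractions(empty)), 0L)

  # malformed count rejected with the offending line number
  bad <- writeInteractionFile(c("P1\tG1\t2", "P1\tG2\t-2"))
  expect_error(loadInteractions(bad), "line 3")
  expect_error(
    loadInteractions(writeInteractionFile(c("P1\tG1\t2", "P2\tG2\t1.5"),
                                          header = FALSE)),
    "line 2")
  expect_error(loadInteractions(tempfile()), "not found")
})

test_that("CSC intersection keeps only CSC genes and warns on empty overlap", {
  rec <- makeRecords(c("P1", "P1", "P2"), c("A", "B", "C"), c(1L, 2L, 3L))

  kept <- intersectWithCsc(rec, c("B", "C"))
  expect_setequal(kept$gene, c("B", "C"))
  expect_false("A" %in% kept$gene)

  # superset of record genes is the identity
  expect_equal(intersectWithCsc(rec, c("A", "B", "C", "D")), rec)

  # disjoint -> empty with a warning, not an error
  expect_warning(out <- intersectWithCsc(rec, "Z"), "overlap")
  expect_equal(nrow(out), 0L)

  expect_error(intersectWithCsc(rec, character(0)), "non-empty")

  # idempotence
  twice <- intersectWithCsc(kept, c("B", "C"))
  expect_equal(twice, kept)
})

test_that("genes lacking either score are excluded, and exclusion is idempotent", {
  rec <- makeRecords(rep("P1", 5), paste0("G", 1:5), 1:5)
  sc <- GeneScores(paste0("G", 1:5),
                   dsi = c(0.5, 0.5, NA, 0.5, 0.5),
                   dpi = c(50, 50, 50, NA, 50))
  out <- dropUnscoredGenes(rec, sc)
  # G3 lacks DSI, G4 lacks DPI: both dropped, both scores required
  expect_equal(out$genes, c("G1", "G2", "G5"))
  expect_setequal(out$records$gene, out$genes)

  again <- dropUnscoredGenes(out$records, sc)
  expect_equal(again, out)

  # all scored -> identity
  sc_full <- GeneScores(paste0("G", 1:5), dsi = rep(0.5, 5),
                        dpi = rep(50, 5))
  expect_equal(dropUnscoredGenes(rec, sc_full)$records, rec)
})

test_that("edge weights are absolute global z-scores with a flat fallback", {
  # raw {1, 3}: mu = 2, population sd = 1 -> |z| = {1, 1}
  net <- buildNetwork(makeRecords("P1", c("G1", "G2"), c(1L, 3L)))
  expect_equal(edgeTable(net)$norm, c(1, 1))

  # raw {0, 2, 4}: mu = 2, sd = sqrt(8/3) -> {1.2247, 0, 1.2247}
  net3 <- buildNetwork(makeRecords("P1", c("G1", "G2", "G3"),
                                   c(0L, 2L, 4L)))
  expect_equal(edgeTable(net3)$norm, c(1.224745, 0, 1.224745),
               tolerance = 1e-6)

  # all equal -> sigma = 0 fallback: every weight 1
  flat <- buildNetwork(makeRecords("P1", c("G1", "G2", "G3"),
                                   c(7L, 7L, 7L)))
  expect_equal(edgeTable(flat)$norm, rep(1, 3))

  expect_error(buildNetwork(makeRecords(character(0), character(0),
                                        integer(0))), "zero")
})

test_that("normalization is invariant to edge order and raw-count shifts", {
  set.seed(11)
  rec <- makeRecords(rep(c("P1", "P2"), each = 6),
                     paste0("G", rep(1:6, 2)),
                     rpois(12, 4) + 1L)
  net <- buildNetwork(rec)
  e <- edgeTable(net)

  shuffled <- rec[sample(nrow(rec)), ]
  e2 <- edgeTable(buildNetwork(shuffled))
  key <- function(d) paste(d$phenolic, d$gene)
  expect_equal(e2$norm[match(key(e), key(e2))], e$norm)

  # shifting every count by a constant leaves the z-scores unchanged
  shifted <- rec
  shifted$count <- shifted$count + 10L
  expect_equal(edgeTable(buildNetwork(shifted))$norm, e$norm)
})

test_that("per-phenolic scope normalizes each phenolic against its own edges", {
  rec <- makeRecords(c("P1", "P1", "P2", "P2"),
                     c("G1", "G2", "G1", "G2"),
                     c(1L, 3L, 10L, 30L))
  net <- buildNetwork(rec, scope = "perPhenolic")
  # both phenolics have two edges below/above their own mean -> |z| = 1
  expect_equal(edgeTable(net)$norm, rep(1, 4))

  # global scope sees one wide distribution instead
  glob <- normalizeWeights(net, scope = "global")
  expect_false(all(edgeTable(glob)$norm == 1))
  expect_equal(normalizeWeights(glob, "perPhenolic")@edges$norm, rep(1, 4))
})

test_that("network audit export round-trips the edge table", {
  net <- buildNetwork(makeRecords(c("P1", "P2"), c("G1", "G1"),
                                  c(2L, 5L)))
  path <- tempfile(fileext = ".tsv")
  exportNetwork(net, path)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(names(back),
               c("phenolic", "gene", "raw_weight", "norm_weight"))
  expect_equal(back$raw_weight, edgeTable(net)$raw)
  expect_equal(back$norm_weight, edgeTable(net)$norm, tolerance = 1e-12)
})
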