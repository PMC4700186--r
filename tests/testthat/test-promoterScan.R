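library(GenomicRanges)
library(Biostrings)

test_that("promoter extraction obeys strand and coordinate conventions", {
  set.seed(44)
  chr <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
               collapse = "")
  genome <- DNAStringSet(c(chr1 = chr))
  genes <- GRanges("chr1", IRanges::IRanges(c(3001, 2001), c(3600, 2600)),
                   strand = c("+", "-"))
  names(genes) <- c("plus", "minus")
  prom <- extractPromoters(genome, genes, length = 2000)
  expect_equal(as.character(prom[["plus"]]), substr(chr, 1001, 3000))
  expect_equal(as.character(prom[["minus"]]),
               as.character(reverseComplement(DNAString(
                 substr(chr, 2601, 4600)))))
  expect_false(any(mcols(prom)$truncated))
  ## start codon near the chromosome edge truncates with a warning
  edge <- GRanges("chr1", IRanges::IRanges(500, 900), strand = "+")
  names(edge) <- "edge"
  expect_warning(pe <- extractPromoters(genome, edge, length = 2000),
                 "truncated")
  expect_equal(nchar(as.character(pe[["edge"]])), 499L)
  expect_true(mcols(pe)$truncated)
  bad <- GRanges("chrX", IRanges::IRanges(10, 20), strand = "+")
  names(bad) <- "x"
  expect_error(extractPromoters(genome, bad), "chrX")
})

test_that("element hits match literals and reverse complements", {
  hits <- scanElements(c(g1 = "TTGACC"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$start, 1L)
  ## GGTCAA is the reverse complement of W-box word TTGACC
  rc <- scanElements(c(g1 = "GGTCAA"))
  expect_equal(nrow(rc), 1L)
  expect_equal(rc$strand, "-")
  expect_equal(rc$match, "TTGACC")
  ## N bases never match
  expect_equal(nrow(scanElements(c(g1 = "TTGACN"))), 0L)
  ## palindromic G-box reports a hit on each strand at the same site
  gb <- scanElements(c(g1 = "CACGTG"),
                     elements = cisElements()[cisElements()$name == "G-box", ])
  expect_equal(nrow(gb), 2L)
  expect_setequal(gb$strand, c("+", "-"))
  expect_equal(unique(gb$start), 1L)
})

test_that("element scanning equals the brute-force window oracle", {
  set.seed(19)
  for (i in 1:30) {
    proms <- setNames(
      vapply(1:3, function(j)
        paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
              collapse = ""), ""),
      paste0("g", 1:3))
    mine <- scanElements(proms)
    oracle <- bruteScanElements(proms, cisElements())
    expect_equal(mine, oracle)
  }
  ## single-strand mode agrees too
  proms <- c(g1 = paste(rep("TTGACT", 40), collapse = ""))
  expect_equal(scanElements(proms, bothStrands = FALSE),
               bruteScanElements(proms, cisElements(), bothStrands = FALSE))
})

test_that("total hit count is invariant under reverse complement", {
  set.seed(23)
  proms <- setNames(
    vapply(1:4, function(j)
      paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
            collapse = ""), ""),
    paste0("g", 1:4))
  fwd <- scanElements(proms)
  rcp <- vapply(proms, function(s)
    as.character(reverseComplement(DNAString(s))), "")
  rev <- scanElements(setNames(rcp, names(proms)))
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(table(fwd$element), table(rev$element))
})

test_that("planted element counts are recovered exactly", {
  els <- cisElements()
  counts <- matrix(0L, 10, nrow(els),
                   dimnames = list(paste0("g", 1:10), els$name))
  counts[1:9, "W-box"] <- 1L            # W-box in 9 of 10 genes
  counts["g1", "CG-box"] <- 8L          # one gene with eight CG-boxes
  sim <- simPromoters(seed = 3, plantCounts = counts, length = 2000)
  hits <- scanElements(sim$promoters)
  ## collapse palindromic double-strand hits so each planted site counts once
  sm <- summarizeElements(hits, sim$promoters, collapsePalindromes = TRUE)
  expect_equal(unname(sm$counts), unname(counts))
  expect_equal(sm$wboxFraction, 0.9)
  ## truth strands round-trip through the scanner
  wbox_truth <- sim$truth[sim$truth$element == "W-box", ]
  wbox_hits <- hits[hits$element == "W-box", ]
  expect_equal(sort(wbox_hits$start), sort(wbox_truth$start))
})

test_that("element summaries conserve counts and handle empties", {
  proms <- DNAStringSet(c(g1 = "AAAAAA", g2 = "AAAAAA"))
  empty <- scanElements(proms)
  sm <- summarizeElements(empty, proms)
  expect_true(all(sm$counts == 0L))
  expect_equal(sm$wboxFraction, 0)
  expect_length(sm$genesOverK, 0L)
  ## palindrome collapsing halves double-stranded G-box hits
  gb <- DNAStringSet(c(g1 = "CACGTGAAA"))
  hits <- scanElements(gb)
  both <- summarizeElements(hits, gb)
  one <- summarizeElements(hits, gb, collapsePalindromes = TRUE)
  expect_equal(unname(both$counts[1, "G-box"]), 2L)
  expect_equal(unname(one$counts[1, "G-box"]), 1L)
})
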