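library(GenomicRanges)

model <- function(starts, ends, strand = "+") {
  GRanges("chr1", IRanges::IRanges(starts, ends), strand = strand)
}

test_that("intron counts are exon counts minus one, strand-invariant", {
  single <- model(100, 500)
  three <- model(c(100, 700, 1300), c(300, 900, 1500))
  grl <- GRangesList(g1 = single, g2 = three)
  expect_equal(countIntrons(grl), c(g1 = 0L, g2 = 2L))
  flipped <- GRangesList(g2 = model(c(100, 700, 1300), c(300, 900, 1500),
                                    strand = "-"))
  expect_equal(unname(countIntrons(flipped)), 2L)
  expect_error(countIntrons(GRangesList(g = model(c(100, 150), c(200, 250)))),
               "overlapping exons")
})

test_that("intronless partition reproduces the curated family", {
  tab <- zmvqFamilyTable()
  s <- intronlessSummary(tab)
  expect_equal(s$intronlessCount, 54L)
  expect_length(s$intronedIds, 7L)
  expect_setequal(s$intronedIds,
                  c("ZmVQ1", "ZmVQ9", "ZmVQ20", "ZmVQ37", "ZmVQ38",
                    "ZmVQ51", "ZmVQ57"))
  ## the curated ZmVQ9 row has two introns
  expect_equal(tab$intron_number[tab$gene_id == "ZmVQ9"], 2L)
  empty <- intronlessSummary(setNames(integer(0), character(0)))
  expect_equal(empty$intronlessCount, 0L)
  expect_length(empty$intronedIds, 0L)
  expect_error(intronlessSummary(c(a = 1L, b = NA)), "\\bb\\b")
})

test_that("copy-number grouping at threshold 1 equals exact-equality grouping", {
  set.seed(3)
  seqs <- setNames(vapply(1:12, function(i) randomProtein(40), ""),
                   paste0("p", 1:12))
  seqs["p7"] <- seqs["p2"]          # planted duplicate pair
  cn <- copyNumberGroups(seqs, identityThreshold = 1.0)
  ## oracle: group by exact sequence equality
  oracle <- as.integer(table(seqs)[seqs])
  expect_equal(unname(cn$copyNumber), oracle)
  expect_equal(sum(lengths(cn$groups)), length(seqs))
  expect_equal(sum(cn$copyNumber > 1L), 2L)
})

test_that("identical triples and all-distinct sets give expected copy numbers", {
  trip <- c(a = "MKVLL", b = "MKVLL", c = "MKVLL")
  cn <- copyNumberGroups(trip)
  expect_equal(unname(cn$copyNumber), c(3L, 3L, 3L))
  expect_length(cn$groups, 1L)
  distinct <- c(a = "MKVLL", b = "MKVLA", c = "AKVLL")
  expect_equal(unname(copyNumberGroups(distinct, 1.0)$copyNumber),
               c(1L, 1L, 1L))
  empty <- copyNumberGroups(character(0))
  expect_length(empty$groups, 0L)
})

test_that("planted duplicates in the synthetic genome are grouped", {
  sim <- simGenomeGff(seed = 5, intronCounts = rep(0L, 20L),
                      duplicateGroups = c(2L, 3L))
  cn <- copyNumberGroups(sim$proteins)
  expect_equal(unname(cn$copyNumber[1:5]), c(2L, 2L, 3L, 3L, 3L))
  expect_equal(sum(cn$copyNumber == 1L), 15L)
  ## truth bookkeeping agrees
  expect_equal(sim$truth$copy_group[1:5], c(1L, 1L, 3L, 3L, 3L))
})

test_that("single-copy counting matches the curated family", {
  tab <- zmvqFamilyTable()
  expect_equal(singleCopyCount(tab), 57L)
  expect_setequal(tab$gene_id[tab$copy_number > 1L],
                  c("ZmVQ15", "ZmVQ28", "ZmVQ48", "ZmVQ49"))
  expect_equal(singleCopyCount(data.frame(copy_number = 1L)), 1L)
})

test_that("synthetic gene models carry the planted intron structure", {
  sim <- simGenomeGff(seed = 9)
  counts <- countIntrons(sim$models)
  expect_equal(unname(counts), sim$truth$introns)
  s <- intronlessSummary(counts)
  expect_equal(s$intronlessCount, 54L)
  expect_length(s$intronedIds, 7L)
  allSingle <- simGenomeGff(seed = 2, intronCounts = rep(0L, 10L))
  expect_equal(intronlessSummary(countIntrons(allSingle$models))$intronlessCount,
               10L)
})

test_that("GFF3 exon features round-trip into gene models", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t100\t900\t.\t+\t.\tID=g1",
    "chr1\ttest\texon\t100\t300\t.\t+\t.\tParent=g1",
    "chr1\ttest\texon\t500\t900\t.\t+\t.\tParent=g1",
    "chr1\ttest\tgene\t2000\t2400\t.\t-\t.\tID=g2",
    "chr1\ttest\texon\t2000\t2400\t.\t-\t.\tParent=g2"), f)
  mods <- readGeneModelsGff3(f)
  expect_equal(countIntrons(mods), c(g1 = 1L, g2 = 0L))
  expect_equal(as.character(GenomicRanges::strand(mods[["g2"]])), "-")
})
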