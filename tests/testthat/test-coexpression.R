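test_that("correlation matrix matches the textbook formula", {
  set.seed(67)
  m <- matrix(runif(60, 1, 50), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  r <- pearsonMatrix(m)
  handCor <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in 1:9) {
    for (j in (i + 1):10) {
      expect_equal(r[i, j], handCor(m[i, ], m[j, ]), tolerance = 1e-12)
    }
  }
  expect_equal(diag(r), setNames(rep(1, 10), rownames(m)))
  expect_error(pearsonMatrix(m[, 1:2]), "at least 3")
})

test_that("affine copies correlate at +1 and negations at -1", {
  x <- c(1, 5, 2, 8, 3, 9)
  m <- rbind(a = x, b = 3 * x + 2, c = max(x) + min(x) - x)
  r <- pearsonMatrix(m)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
})

test_that("zero-variance genes are excluded and reported", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5), c = c(4, 3, 2, 1))
  r <- pearsonMatrix(m)
  expect_equal(attr(r, "excluded"), "b")
  expect_false("b" %in% rownames(r))
})

test_that("the network uses a strict threshold and types edges", {
  r <- matrix(c(1, 0.90, 0.95, 0.90, 1, 0.2, 0.95, 0.2, 1), 3,
              dimnames = list(c("VQ1", "WRKY1", "WRKY2"),
                              c("VQ1", "WRKY1", "WRKY2")))
  labels <- c(VQ1 = "VQ", WRKY1 = "WRKY", WRKY2 = "WRKY")
  net <- buildNetwork(r, labels, threshold = 0.90)
  ## r exactly 0.90 does not create an edge
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$gene_a, "VQ1")
  expect_equal(net$edges$gene_b, "WRKY2")
  expect_equal(net$edges$edge_type, "VQ-WRKY")
  expect_equal(net$summary$vqWithOneWrky, 1L)
  expect_equal(net$summary$vqWithMultipleWrky, 0L)
  expect_equal(net$summary$wrkyCoexpressed, 1L)
  expect_error(buildNetwork(r, labels[1:2]), "labels missing")
})

test_that("the network is invariant under positive affine rescaling", {
  sim <- simCoexpression(seed = 10, nGenes = 12, blocks = list(1:4),
                         nSamples = 20, noiseSd = 0.05)
  labels <- setNames(rep(c("VQ", "WRKY"), 6), rownames(sim$matrix))
  n1 <- buildNetwork(pearsonMatrix(sim$matrix), labels)
  m2 <- sim$matrix
  m2[3, ] <- 2.5 * m2[3, ] + 7
  n2 <- buildNetwork(pearsonMatrix(m2), labels)
  expect_equal(n1$edges[, c("gene_a", "gene_b", "edge_type")],
               n2$edges[, c("gene_a", "gene_b", "edge_type")])
})

test_that("edge count is non-increasing in the threshold", {
  set.seed(83)
  m <- matrix(runif(200), 20, 10,
              dimnames = list(paste0("g", 1:20), NULL))
  labels <- setNames(rep("VQ", 20), rownames(m))
  r <- pearsonMatrix(m)
  counts <- vapply(c(0.2, 0.5, 0.8, 0.95), function(th)
    nrow(buildNetwork(r, labels, threshold = th)$edges), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("planted co-expression blocks are recovered with precision and recall 1", {
  sim <- simCoexpression(seed = 4, nGenes = 20, blocks = list(1:5),
                         nSamples = 12, noiseSd = 0.05)
  labels <- setNames(rep("VQ", 20), rownames(sim$matrix))
  net <- buildNetwork(pearsonMatrix(sim$matrix), labels, threshold = 0.90)
  inBlock <- sim$truth$gene_id[!is.na(sim$truth$block)]
  expected <- t(combn(sort(inBlock), 2))
  got <- as.matrix(net$edges[, c("gene_a", "gene_b")])
  expect_equal(nrow(got), nrow(expected))   # all 10 within-block pairs
  expect_setequal(paste(got[, 1], got[, 2]),
                  paste(expected[, 1], expected[, 2]))
})

test_that("independent genes produce no edges at r > 0.90", {
  sim <- simCoexpression(seed = 16, nGenes = 30, blocks = list(),
                         nSamples = 50, noiseSd = 0)
  labels <- setNames(rep("VQ", 30), rownames(sim$matrix))
  net <- buildNetwork(pearsonMatrix(sim$matrix), labels, threshold = 0.90)
  expect_equal(nrow(net$edges), 0L)
  expect_true(all(net$degree == 0L))
})

test_that("GraphML export round-trips nodes and edges", {
  sim <- simCoexpression(seed = 4, nGenes = 8, blocks = list(1:3),
                         nSamples = 12, noiseSd = 0.01)
  labels <- setNames(rep(c("VQ", "WRKY"), 4), rownames(sim$matrix))
  net <- buildNetwork(pearsonMatrix(sim$matrix), labels)
  f <- tempfile(fileext = ".graphml")
  writeNetworkGraphml(net, labels, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::gorder(g), 8)
  expect_equal(igraph::gsize(g), nrow(net$edges))
})
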