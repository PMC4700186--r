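droughtMeta <- function(replicates = 2) {
  meta <- expand.grid(replicate = seq_len(replicates),
                      condition = c("control", "treatment"),
                      timepoint = c("day3", "day6", "rewatered"),
                      stringsAsFactors = FALSE)
  meta$sample <- paste(meta$condition, meta$timepoint, meta$replicate,
                       sep = "_")
  meta[, c("sample", "condition", "timepoint", "replicate")]
}

test_that("all-zero genes land in the silent tissue group", {
  set.seed(61)
  m <- rbind(matrix(runif(40, 1, 100), 8, 5),
             matrix(0, 6, 5))
  rownames(m) <- paste0("g", 1:14)
  grp <- tissueGroups(m, k = 2)
  expect_equal(unname(grp[paste0("g", 9:14)]), rep("silent", 6))
  expect_false(any(grp[paste0("g", 1:8)] == "silent"))
  ## partition covers all genes exactly once
  expect_equal(sort(names(grp)), sort(rownames(m)))
  expect_false(anyNA(grp))
  expect_error(tissueGroups(m, k = 9), "exceeds")
})

test_that("planted tissue archetypes are recovered exactly at zero noise", {
  sim <- simTissueExpression(seed = 15, noiseSd = 0)
  grp <- tissueGroups(sim$matrix, k = 3)
  truth <- split(sim$truth$gene_id, sim$truth$archetype)
  expect_setequal(names(grp)[grp == "silent"], truth$silent)
  ## non-silent groups must match the planted partition up to labels
  found <- split(names(grp)[grp != "silent"], grp[grp != "silent"])
  found <- lapply(found, sort)
  planted <- lapply(truth[names(truth) != "silent"], sort)
  expect_setequal(unname(lapply(found, paste, collapse = ",")),
                  unname(lapply(planted, paste, collapse = ",")))
})

test_that("single gene per archetype yields one group each", {
  sim <- simTissueExpression(seed = 15, noiseSd = 0,
                             groupSizes = c(A = 1L, C = 1L, D = 1L))
  grp <- tissueGroups(sim$matrix, k = 3)
  expect_length(unique(grp), 3L)
})

test_that("relative expression is the log2 arm difference", {
  meta <- droughtMeta()
  m <- matrix(1, 2, nrow(meta), dimnames = list(c("g1", "g2"), meta$sample))
  expect_true(all(relativeExpression(m, meta) == 0))
  ## treatment 3 vs control 1 at one timepoint: log2(4) - log2(2) = 1
  m["g1", meta$condition == "treatment" & meta$timepoint == "day3"] <- 3
  prof <- relativeExpression(m, meta)
  expect_equal(prof["g1", "day3"], 1)
  expect_equal(prof["g1", "day6"], 0)
  ## arm swap negates the profile
  meta2 <- meta
  meta2$condition <- ifelse(meta$condition == "control", "treatment",
                            "control")
  expect_equal(relativeExpression(m, meta2), -prof)
  ## missing arm is an error naming the timepoint
  bad <- meta[!(meta$timepoint == "day6" & meta$condition == "control"), ]
  expect_error(relativeExpression(m[, bad$sample], bad), "day6")
})

test_that("drought classes follow the timepoint definitions", {
  prof <- rbind(zero = c(0, 0, 0),
                early = c(1.5, 0, 0),
                sustained = c(-1.2, 2, 0),
                late = c(0.2, -1.5, 2),
                rewater = c(0, 0, 1.1))
  colnames(prof) <- c("day3", "day6", "rewatered")
  cls <- classifyDroughtResponse(prof, threshold = 1)
  expect_equal(unname(cls),
               c("NON_RESPONSIVE", "EARLY", "SUSTAINED", "LATE",
                 "REWATER_ONLY"))
  expect_equal(droughtResponsiveCount(cls), 4L)
  expect_error(classifyDroughtResponse(prof[, 1:2, drop = FALSE]),
               "timepoint")
})

test_that("raising the threshold never makes a gene responsive", {
  set.seed(29)
  prof <- matrix(rnorm(60 * 3, 0, 1.5), 60,
                 dimnames = list(paste0("g", 1:60),
                                 c("day3", "day6", "rewatered")))
  lo <- classifyDroughtResponse(prof, threshold = 0.5)
  hi <- classifyDroughtResponse(prof, threshold = 1.5)
  was_nr <- lo == "NON_RESPONSIVE"
  expect_true(all(hi[was_nr] == "NON_RESPONSIVE"))
  expect_lte(droughtResponsiveCount(hi), droughtResponsiveCount(lo))
})

test_that("the synthetic drought cohort yields 41 of 61 responsive genes", {
  sim <- simDroughtExpression(seed = 8)
  prof <- relativeExpression(sim$matrix, sim$meta)
  cls <- classifyDroughtResponse(prof, threshold = 1)
  expect_equal(droughtResponsiveCount(cls), 41L)
  expect_equal(unname(cls), sim$truth$class)
})

test_that("ddct recovers closed-form folds and is reciprocal under swap", {
  tab <- expand.grid(replicate = 1:3, condition = c("control", "treatment"),
                     stringsAsFactors = FALSE)
  tab$gene <- "g1"; tab$timepoint <- "t1"
  tab$ct_reference <- 15
  ## treatment dCt is 2 cycles lower: ddCt = -2, fold = 4
  tab$ct_target <- ifelse(tab$condition == "treatment", 23, 25)
  res <- ddct(tab, calibrator = c(condition = "control", timepoint = "t1"))
  expect_equal(res$ddct, -2)
  expect_equal(res$fold, 4)
  ## identical arms give fold 1
  tab$ct_target <- 25
  res1 <- ddct(tab, calibrator = c(condition = "control", timepoint = "t1"))
  expect_equal(res1$fold, 1)
  expect_equal(res1$ddct, 0)
  ## sample/calibrator swap inverts the fold
  tab$ct_target <- ifelse(tab$condition == "treatment", 23, 25)
  swapped <- ddct(tab, calibrator = c(condition = "treatment",
                                      timepoint = "t1"))
  expect_equal(swapped$fold, 1 / res$fold)
})

test_that("rows without a reference Ct are rejected with a warning", {
  sim <- simQpcr(seed = 77, trueFolds = c(g1 = 2), replicates = 3)
  tab <- sim$table
  tab$ct_reference[1] <- NA
  expect_warning(
    res <- ddct(tab, calibrator = c(condition = "control",
                                    timepoint = "t1")),
    "rejected")
  expect_equal(nrow(res), 1L)
})

test_that("a planted 20-fold qPCR change is estimated and significant", {
  sim <- simQpcr(seed = 42, trueFolds = c(g1 = 20), replicates = 3,
                 ctNoiseSd = 0.1)
  res <- ddct(sim$table, calibrator = c(condition = "control",
                                        timepoint = "t1"))
  expect_gt(res$fold, 15)
  expect_lt(res$fold, 26)
  expect_true(res$significant)
  ## true fold 1 stays near 1 and non-significant
  null <- simQpcr(seed = 43, trueFolds = c(g1 = 1), replicates = 3,
                  ctNoiseSd = 0.05)
  rnull <- ddct(null$table, calibrator = c(condition = "control",
                                           timepoint = "t1"))
  expect_equal(rnull$fold, 1, tolerance = 0.2)
  expect_false(rnull$significant)
})
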