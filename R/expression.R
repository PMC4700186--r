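## Expression profiling: tissue grouping, drought relative-expression
## profiles and response classes, and qPCR 2^-ddCt quantification.
##
## Abundances are FPKM; all differencing is done on the log2(FPKM + 1)
## scale. Matrices are genes x samples; a SummarizedExperiment may be
## passed wherever a matrix is accepted (its first assay is used).

.asMatrix <- function(x) {
    if (is(x, "SummarizedExperiment")) {
        if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
            stop("SummarizedExperiment input requires that package")
        x <- SummarizedExperiment::assay(x)
    }
    stopifnot(is.matrix(x), is.numeric(x))
    if (any(x < 0))
        stop("expression values must be nonnegative")
    if (is.null(rownames(x)))
        rownames(x) <- paste0("gene", seq_len(nrow(x)))
    x
}

#' Group genes by tissue expression pattern
#'
#' Expression is transformed to log2(FPKM + 1) and z-scored per gene; genes
#' with zero variance across tissues (including silent, all-zero genes) are
#' assigned to a designated `"silent"` group. The remaining genes are
#' clustered by average-linkage hierarchical clustering on correlation
#' distance (1 - Pearson) and the tree is cut into `k` groups labelled
#' `G1..Gk` (deterministic given input order).
#'
#' @param matrix genes x tissues FPKM matrix (or SummarizedExperiment).
#' @param k number of expression groups for the non-silent genes.
#' @return Named character vector mapping each gene to its group label
#'   (`"G1"`..`"Gk"` or `"silent"`); a partition of the input genes.
#' @export
tissueGroups <- function(matrix, k) {
    m <- .asMatrix(matrix)
    lm2 <- log2(m + 1)
    v <- apply(lm2, 1, stats::var)
    silent <- v == 0 | is.na(v)
    labels <- stats::setNames(rep(NA_character_, nrow(m)), rownames(m))
    labels[silent] <- "silent"
    active <- lm2[!silent, , drop = FALSE]
    if (k > nrow(active))
        stop("k = ", k, " exceeds the ", nrow(active),
             " gene(s) with nonzero variance")
    if (nrow(active)) {
        z <- t(scale(t(active)))
        dc <- stats::as.dist(1 - stats::cor(t(z)))
        hc <- stats::hclust(dc, method = "average")
        cut <- stats::cutree(hc, k = k)
        labels[!silent] <- paste0("G", cut)
    }
    labels
}

.log2MeanArm <- function(m, cols) {
    rowMeans(log2(m[, cols, drop = FALSE] + 1))
}

#' Drought relative-expression profile
#'
#' For every gene and timepoint, the relative expression is
#' `Crelative = Ctreatment - Ccontrol`, where each arm's level is the mean
#' log2(FPKM + 1) over that arm's replicate samples at the timepoint.
#'
#' @param matrix genes x samples FPKM matrix (or SummarizedExperiment).
#' @param meta `data.frame` with one row per sample (in column order of the
#'   matrix or keyed by a `sample` column matching colnames): columns
#'   `condition` (`control`/`treatment`) and `timepoint`.
#' @return Genes x timepoints numeric matrix of Crelative values
#'   (log2 units); timepoints ordered as first seen in `meta`.
#' @export
relativeExpression <- function(matrix, meta) {
    m <- .asMatrix(matrix)
    stopifnot(is.data.frame(meta),
              all(c("condition", "timepoint") %in% colnames(meta)))
    if ("sample" %in% colnames(meta)) {
        stopifnot(!is.null(colnames(m)),
                  all(colnames(m) %in% meta$sample))
        meta <- meta[match(colnames(m), meta$sample), , drop = FALSE]
    } else {
        stopifnot(nrow(meta) == ncol(m))
    }
    stopifnot(all(meta$condition %in% c("control", "treatment")))
    tps <- unique(as.character(meta$timepoint))
    out <- matrix(NA_real_, nrow(m), length(tps),
                  dimnames = list(rownames(m), tps))
    for (tp in tps) {
        trt <- which(meta$timepoint == tp & meta$condition == "treatment")
        ctl <- which(meta$timepoint == tp & meta$condition == "control")
        if (!length(trt) || !length(ctl))
            stop("timepoint '", tp, "' lacks a ",
                 if (length(trt)) "control" else "treatment", " arm")
        out[, tp] <- .log2MeanArm(m, trt) - .log2MeanArm(m, ctl)
    }
    out
}

.DROUGHT_CLASSES <- c("EARLY", "SUSTAINED", "LATE", "REWATER_ONLY",
                      "NON_RESPONSIVE")

#' Classify drought-response profiles
#'
#' A gene is responsive at a timepoint when `|Crelative| >= threshold`.
#' Over the three-timepoint drought design (day 3 and day 6 of drought,
#' then re-watering): `SUSTAINED` = responsive at both day 3 and day 6;
#' `EARLY` = day 3 but not day 6; `LATE` = day 6 but not day 3;
#' `REWATER_ONLY` = responsive only after re-watering; otherwise
#' `NON_RESPONSIVE`. "Drought-responsive" means any class except
#' `NON_RESPONSIVE`.
#'
#' @param profile genes x timepoints Crelative matrix from
#'   [relativeExpression()].
#' @param threshold responsiveness threshold in log2 units (default 1).
#' @param timepoints names of the day-3, day-6 and re-watered columns, in
#'   that order (default the first three profile columns).
#' @return Named character vector of classes, one per gene.
#' @export
classifyDroughtResponse <- function(profile, threshold = 1,
                                    timepoints = colnames(profile)[1:3]) {
    stopifnot(is.matrix(profile), length(timepoints) == 3L)
    if (!all(timepoints %in% colnames(profile)))
        stop("profile lacks timepoint(s): ",
             paste(setdiff(timepoints, colnames(profile)), collapse = ", "))
    if (anyNA(profile[, timepoints]))
        stop("profile has missing Crelative values")
    r3 <- abs(profile[, timepoints[1]]) >= threshold
    r6 <- abs(profile[, timepoints[2]]) >= threshold
    rw <- abs(profile[, timepoints[3]]) >= threshold
    cls <- rep("NON_RESPONSIVE", nrow(profile))
    cls[rw & !r3 & !r6] <- "REWATER_ONLY"
    cls[r6 & !r3] <- "LATE"
    cls[r3 & !r6] <- "EARLY"
    cls[r3 & r6] <- "SUSTAINED"
    stats::setNames(cls, rownames(profile))
}

#' Count drought-responsive genes
#'
#' @param classes output of [classifyDroughtResponse()].
#' @return Number of genes in any class except `NON_RESPONSIVE`.
#' @export
droughtResponsiveCount <- function(classes) {
    stopifnot(all(classes %in% .DROUGHT_CLASSES))
    sum(classes != "NON_RESPONSIVE")
}

#' qPCR relative quantification by 2^-ddCt
#'
#' Per replicate, `dCt = Ct_target - Ct_reference`; per gene and sample
#' group, `ddCt = mean dCt(group) - mean dCt(calibrator)` and the fold
#' change is `2^-ddCt`. Groups are compared with the calibrator by a
#' two-sided Welch t-test on replicate dCt values and flagged significant
#' at `alpha`. Rows missing a reference Ct are rejected with a warning.
#'
#' @param table `data.frame` with columns `gene`, `condition`, `timepoint`,
#'   `replicate`, `ct_target`, `ct_reference`.
#' @param calibrator named character vector
#'   `c(condition = ..., timepoint = ...)` identifying the calibrator
#'   group of each gene.
#' @param alpha significance level (default 0.05).
#' @return A `data.frame` with one row per gene x non-calibrator group:
#'   `gene`, `condition`, `timepoint`, `ddct`, `fold`, `p_value`,
#'   `significant`.
#' @export
ddct <- function(table, calibrator = c(condition = "control",
                                       timepoint = "0"),
                 alpha = 0.05) {
    need <- c("gene", "condition", "timepoint", "replicate",
              "ct_target", "ct_reference")
    stopifnot(is.data.frame(table), all(need %in% colnames(table)))
    bad <- is.na(table$ct_reference)
    if (any(bad)) {
        warning(sum(bad), " row(s) rejected: missing reference Ct")
        table <- table[!bad, , drop = FALSE]
    }
    stopifnot(all(table$ct_target > 0), all(table$ct_reference > 0))
    table$dct <- table$ct_target - table$ct_reference
    table$timepoint <- as.character(table$timepoint)
    is_cal <- table$condition == calibrator[["condition"]] &
        table$timepoint == calibrator[["timepoint"]]
    if (!any(is_cal))
        stop("calibrator group not present in the table")
    out <- list()
    for (g in unique(table$gene)) {
        tg <- table[table$gene == g, , drop = FALSE]
        cal <- tg$dct[tg$condition == calibrator[["condition"]] &
                      tg$timepoint == calibrator[["timepoint"]]]
        if (!length(cal))
            stop("gene '", g, "' has no calibrator replicates")
        grp <- unique(tg[, c("condition", "timepoint")])
        for (r in seq_len(nrow(grp))) {
            if (grp$condition[r] == calibrator[["condition"]] &&
                grp$timepoint[r] == calibrator[["timepoint"]])
                next
            v <- tg$dct[tg$condition == grp$condition[r] &
                        tg$timepoint == grp$timepoint[r]]
            dd <- mean(v) - mean(cal)
            p <- if (length(v) >= 2L && length(cal) >= 2L)
                tryCatch(
                    stats::t.test(v, cal,
                                  alternative = "two.sided")$p.value,
                    error = function(e) NA_real_)  # constant replicates
            else NA_real_
            out[[length(out) + 1L]] <- data.frame(
                gene = g, condition = grp$condition[r],
                timepoint = grp$timepoint[r],
                ddct = dd, fold = 2^(-dd), p_value = p,
                significant = !is.na(p) & p < alpha,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}
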