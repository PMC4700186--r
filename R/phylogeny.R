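## Distance-based phylogeny: p-distance on aligned proteins, Saitou-Nei
## neighbor joining, and nonparametric bootstrap supports on internal
## splits. Trees are ape "phylo" objects throughout.

.GAP_CHARS <- c("-", ".")

.alignmentMatrix <- function(alignment) {
    if (is(alignment, "XStringSet"))
        alignment <- as.character(alignment)
    stopifnot(is.character(alignment))
    if (is.null(names(alignment)))
        names(alignment) <- paste0("seq", seq_along(alignment))
    if (anyDuplicated(names(alignment)))
        stop("alignment ids must be unique")
    if (length(unique(nchar(alignment))) != 1L)
        stop("aligned sequences must all have the same length")
    if (length(alignment) < 3L)
        stop("at least 3 aligned sequences are required")
    m <- do.call(rbind, strsplit(alignment, ""))
    rownames(m) <- names(alignment)
    m
}

#' Pairwise p-distance with pairwise gap deletion
#'
#' For each pair of aligned sequences, the fraction of mismatched sites over
#' the columns where neither sequence has a gap (`-` or `.`).
#'
#' @param alignment an aligned [Biostrings::AAStringSet] or named character
#'   vector (all sequences the same length, at least 3 sequences).
#' @return A symmetric numeric matrix with a zero diagonal, dimnames = ids.
#' @examples
#' pDistance(c(a = "AAAA", b = "AAAT", c = "AA-A"))
#' @export
pDistance <- function(alignment) {
    m <- .alignmentMatrix(alignment)
    n <- nrow(m)
    notgap <- !(m %in% .GAP_CHARS)
    dim(notgap) <- dim(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1L)) {
        for (j in seq((i + 1L), n)) {
            comp <- notgap[i, ] & notgap[j, ]
            if (!any(comp))
                stop("no comparable (gap-free) columns between '",
                     rownames(m)[i], "' and '", rownames(m)[j], "'")
            d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / sum(comp)
        }
    }
    d
}

.checkDistanceMatrix <- function(d) {
    stopifnot(is.matrix(d), nrow(d) == ncol(d),
              isTRUE(all.equal(d, t(d))), all(diag(d) == 0), all(d >= 0))
    if (is.null(rownames(d)))
        rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
    d
}

.fmtLen <- function(x) sprintf("%.17g", max(x, 0))

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration: repeatedly join the pair minimising the
#' Q-criterion `Q(i,j) = (r-2) d(i,j) - R(i) - R(j)` (ties broken towards
#' the lowest index pair, for determinism), with the standard branch-length
#' and distance-update formulas. Negative branch lengths are clamped to
#' zero. On an additive distance matrix the generating topology and path
#' lengths are recovered exactly.
#'
#' @param d a symmetric distance matrix with zero diagonal and at least 3
#'   taxa (dimnames = taxon labels).
#' @return An unrooted [ape] `phylo` tree over the input taxa.
#' @examples
#' d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' njTree(d)$edge.length  # 0.5, 1.5, 2.5
#' @export
njTree <- function(d) {
    d <- .checkDistanceMatrix(d)
    n <- nrow(d)
    if (n < 3L)
        stop("neighbor joining requires at least 3 taxa")
    ## each active node carries its Newick subtree string
    labels <- rownames(d)
    node <- as.list(labels)
    while (length(node) > 3L) {
        r <- nrow(d)
        R <- rowSums(d)
        best <- c(NA_integer_, NA_integer_)
        best_q <- Inf
        for (i in seq_len(r - 1L)) {
            for (j in seq((i + 1L), r)) {
                q <- (r - 2) * d[i, j] - R[i] - R[j]
                if (q < best_q) {            # strict: ties keep lowest (i,j)
                    best_q <- q
                    best <- c(i, j)
                }
            }
        }
        i <- best[1]; j <- best[2]
        li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
        lj <- d[i, j] - li
        dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
        merged <- paste0("(", node[[i]], ":", .fmtLen(li), ",",
                         node[[j]], ":", .fmtLen(lj), ")")
        keep <- setdiff(seq_len(r), c(i, j))
        d <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                   c(dnew[keep], 0))
        node <- c(node[keep], merged)
    }
    ## final trifurcation
    la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    newick <- paste0("(", node[[1]], ":", .fmtLen(la), ",",
                     node[[2]], ":", .fmtLen(lb), ",",
                     node[[3]], ":", .fmtLen(lc), ");")
    ape::read.tree(text = newick)
}

#' Nontrivial splits of an unrooted tree
#'
#' Each internal edge bipartitions the taxa; a split is represented
#' canonically as the sorted comma-separated labels on the side containing
#' the alphabetically first taxon.
#'
#' @param tree a `phylo` object.
#' @return Character vector of canonical split keys (possibly empty).
#' @export
treeSplits <- function(tree) {
    stopifnot(inherits(tree, "phylo"))
    tips <- sort(tree$tip.label)
    ref <- tips[1]
    n <- length(tips)
    internal <- setdiff(unique(tree$edge[, 2]), seq_len(n))
    keys <- character(0)
    for (nd in internal) {
        clade <- ape::extract.clade(tree, nd)$tip.label
        if (length(clade) <= 1L || length(clade) >= n - 1L)
            next                           # trivial split
        side <- if (ref %in% clade) clade else setdiff(tips, clade)
        keys <- c(keys, paste(sort(side), collapse = ","))
    }
    unique(keys)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the full-data p-distance NJ tree, then resamples alignment
#' columns with replacement `replicates` times, rebuilding the tree per
#' replicate. The support of each internal split of the full-data tree is
#' the fraction of successfully built replicate trees containing it.
#' Replicates whose resampled columns leave some pair with no comparable
#' site are skipped (with a warning) and excluded from the denominator.
#'
#' @param alignment as in [pDistance()].
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed making the resampling reproducible.
#' @return A list with `tree` (the full-data `phylo`, with `node.label`
#'   carrying supports on internal nodes), `supports` (named numeric in
#'   \[0, 1\], keyed by canonical split), and `skipped` (replicates
#'   discarded as degenerate).
#' @export
bootstrapSupport <- function(alignment, replicates = 1000L, seed = 1L) {
    stopifnot(replicates >= 1L)
    m <- .alignmentMatrix(alignment)
    aln <- stats::setNames(apply(m, 1, paste, collapse = ""), rownames(m))
    full <- njTree(pDistance(aln))
    splits <- treeSplits(full)
    counts <- stats::setNames(numeric(length(splits)), splits)
    used <- 0L
    skipped <- 0L
    set.seed(as.integer(seed))
    for (b in seq_len(replicates)) {
        cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
        mb <- m[, cols, drop = FALSE]
        alnb <- stats::setNames(apply(mb, 1, paste, collapse = ""),
                                rownames(m))
        db <- tryCatch(pDistance(alnb), error = function(e) NULL)
        if (is.null(db)) {
            skipped <- skipped + 1L
            next
        }
        used <- used + 1L
        bs <- treeSplits(njTree(db))
        hit <- splits %in% bs
        counts[hit] <- counts[hit] + 1
    }
    if (skipped > 0L)
        warning(skipped, " degenerate bootstrap replicate(s) skipped")
    supports <- if (used > 0L) counts / used else counts * NA_real_
    ## attach supports as node labels on the full-data tree
    tips <- sort(full$tip.label)
    ref <- tips[1]
    ntip <- length(tips)
    node_ids <- (ntip + 1L):(ntip + full$Nnode)
    lab <- character(full$Nnode)
    for (k in seq_along(node_ids)) {
        clade <- ape::extract.clade(full, node_ids[k])$tip.label
        if (length(clade) <= 1L || length(clade) >= ntip - 1L) {
            lab[k] <- ""
            next
        }
        side <- if (ref %in% clade) clade else setdiff(tips, clade)
        key <- paste(sort(side), collapse = ",")
        lab[k] <- ifelse(key %in% names(supports),
                         format(supports[[key]], digits = 3), "")
    }
    full$node.label <- lab
    list(tree = full, supports = supports, skipped = skipped)
}

#' Poisson-corrected distance
#'
#' Optional correction `-log(1 - p)` applied to a p-distance matrix.
#'
#' @param d a p-distance matrix with entries in \[0, 1).
#' @return The corrected distance matrix.
#' @export
poissonCorrect <- function(d) {
    d <- .checkDistanceMatrix(d)
    stopifnot(all(d < 1))
    -log(1 - d)
}

#' Write a tree with supports to a Newick file
#'
#' @param tree a `phylo` object (e.g. `bootstrapSupport()$tree`).
#' @param file output path.
#' @return Invisibly, the file path.
#' @export
writeTreeNewick <- function(tree, file) {
    ape::write.tree(tree, file = file)
    invisible(file)
}
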