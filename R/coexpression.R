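## VQ-WRKY co-expression: Pearson correlation over drought samples and a
## strict-threshold network with family-typed edges.

#' Pearson correlation matrix over samples
#'
#' @param matrix genes x samples FPKM matrix (or SummarizedExperiment);
#'   at least 3 samples.
#' @param genes optional character vector restricting to a gene subset.
#' @return Symmetric correlation matrix with unit diagonal. Genes with zero
#'   variance across samples are excluded; their ids are recorded in the
#'   `"excluded"` attribute.
#' @export
pearsonMatrix <- function(matrix, genes = NULL) {
    m <- .asMatrix(matrix)
    if (!is.null(genes)) {
        stopifnot(all(genes %in% rownames(m)))
        m <- m[genes, , drop = FALSE]
    }
    if (ncol(m) < 3L)
        stop("Pearson correlation requires at least 3 samples")
    v <- apply(m, 1, stats::var)
    excluded <- rownames(m)[v == 0 | is.na(v)]
    m <- m[!(rownames(m) %in% excluded), , drop = FALSE]
    r <- stats::cor(t(m))
    diag(r) <- 1
    attr(r, "excluded") <- excluded
    r
}

#' Build a thresholded co-expression network
#'
#' Edges connect gene pairs whose Pearson correlation strictly exceeds
#' `threshold` (negative correlations never create edges). Each edge is
#' typed from the two genes' family labels (e.g. `VQ-VQ`, `VQ-WRKY`,
#' `WRKY-WRKY`); within an edge, `gene_a < gene_b` lexicographically.
#'
#' @param corr symmetric correlation matrix (e.g. from [pearsonMatrix()]).
#' @param labels named character vector of family labels (`"VQ"` or
#'   `"WRKY"`) covering every gene in `corr`.
#' @param threshold strict lower bound on r (default 0.90).
#' @return A list with `edges` (`data.frame`: `gene_a`, `gene_b`, `r`,
#'   `edge_type`), `degree` (named integer over all genes) and `summary`
#'   (per-VQ-gene WRKY partner counts, plus the number of VQ genes with
#'   exactly one and with more than one WRKY partner).
#' @export
buildNetwork <- function(corr, labels, threshold = 0.90) {
    stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
    ids <- rownames(corr)
    if (!all(ids %in% names(labels)))
        stop("family labels missing for: ",
             paste(setdiff(ids, names(labels)), collapse = ", "))
    labels <- labels[ids]
    n <- length(ids)
    ga <- gb <- character(0)
    rv <- numeric(0)
    if (n >= 2L) {
        idx <- which(upper.tri(corr) & corr > threshold, arr.ind = TRUE)
        if (nrow(idx)) {
            a <- ids[idx[, 1]]
            b <- ids[idx[, 2]]
            swap <- a > b
            ga <- ifelse(swap, b, a)
            gb <- ifelse(swap, a, b)
            rv <- corr[idx]
        }
    }
    edge_type <- if (length(ga))
        mapply(function(x, y) paste(sort(c(x, y)), collapse = "-"),
               unname(labels[ga]), unname(labels[gb]), USE.NAMES = FALSE)
    else character(0)
    edges <- data.frame(gene_a = ga, gene_b = gb, r = rv,
                        edge_type = edge_type, stringsAsFactors = FALSE)
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
    degree <- stats::setNames(integer(n), ids)
    if (nrow(edges)) {
        tab <- table(c(edges$gene_a, edges$gene_b))
        degree[names(tab)] <- as.integer(tab)
    }
    vq <- ids[labels == "VQ"]
    wrky_partners <- stats::setNames(integer(length(vq)), vq)
    for (i in seq_len(nrow(edges))) {
        a <- edges$gene_a[i]; b <- edges$gene_b[i]
        if (labels[a] == "VQ" && labels[b] == "WRKY")
            wrky_partners[a] <- wrky_partners[a] + 1L
        if (labels[b] == "VQ" && labels[a] == "WRKY")
            wrky_partners[b] <- wrky_partners[b] + 1L
    }
    vw <- edges[edges$edge_type == "VQ-WRKY", , drop = FALSE]
    wrky_in_vw <- unique(c(vw$gene_a, vw$gene_b))
    wrky_in_vw <- wrky_in_vw[labels[wrky_in_vw] == "WRKY"]
    list(edges = edges,
         degree = degree,
         summary = list(
             wrkyPartnersPerVQ = wrky_partners,
             vqWithWrky = sum(wrky_partners >= 1L),
             vqWithOneWrky = sum(wrky_partners == 1L),
             vqWithMultipleWrky = sum(wrky_partners > 1L),
             wrkyCoexpressed = length(wrky_in_vw)))
}

#' Export a network as GraphML
#'
#' Writes the edge list as a GraphML file (importable by common network
#' viewers), with `family` and `degree` node attributes and `r` and
#' `edge_type` edge attributes.
#'
#' @param network output of [buildNetwork()].
#' @param labels the family labels used to build it.
#' @param file output path.
#' @return Invisibly, the file path.
#' @export
writeNetworkGraphml <- function(network, labels, file) {
    g <- igraph::graph_from_data_frame(
        network$edges, directed = FALSE,
        vertices = data.frame(name = names(network$degree),
                              family = unname(labels[names(network$degree)]),
                              degree = unname(network$degree)))
    igraph::write_graph(g, file, format = "graphml")
    invisible(file)
}
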