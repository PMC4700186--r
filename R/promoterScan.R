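## Promoter extraction and degenerate cis-element scanning.
##
## Elements are short DNA consensus patterns written with literal bases and
## bracket classes, e.g. "TTGAC[CT]". Promoters are the 2000 bp immediately
## upstream of a gene's start codon, read 5'->3' towards the gene.

.IUPAC_FROM_SET <- c(A = "A", C = "C", G = "G", T = "T",
                     AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y",
                     GT = "K", ACG = "V", ACT = "H", AGT = "D", CGT = "B",
                     ACGT = "N")

#' The seven stress-related cis-elements
#'
#' Default element set for promoter scanning: W-box (WRKY binding,
#' `TTGAC[CT]`), DRE (drought-response element, `[AG]CCGAC`), CG-box
#' (calmodulin-binding transcription activator, `[ACG]CGCG[CGT]`), MBS
#' (MYB binding site, `CAACTG`), ABRE (ABA-responsive element,
#' `[CT]ACGTG[GT]`), SARE (salicylic-acid responsive, `TGACG`) and G-box
#' (light/environmental stimuli, `CACGTG`).
#'
#' @return A `data.frame` with columns `name` and `pattern`.
#' @export
cisElements <- function() {
    data.frame(
        name = c("W-box", "DRE", "CG-box", "MBS", "ABRE", "SARE", "G-box"),
        pattern = c("TTGAC[CT]", "[AG]CCGAC", "[ACG]CGCG[CGT]", "CAACTG",
                    "[CT]ACGTG[GT]", "TGACG", "CACGTG"),
        stringsAsFactors = FALSE)
}

## "TTGAC[CT]" -> "TTGACY" (IUPAC string usable by matchPattern)
.compilePattern <- function(pattern) {
    stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
    out <- character(0)
    i <- 1L
    n <- nchar(pattern)
    while (i <= n) {
        ch <- substr(pattern, i, i)
        if (ch == "[") {
            close <- regexpr("]", substr(pattern, i, n), fixed = TRUE)
            if (close < 0L)
                stop("unclosed bracket class in pattern: ", pattern)
            cls <- substr(pattern, i + 1L, i + close - 2L)
            bases <- sort(unique(strsplit(gsub("/", "", cls), "")[[1]]))
            if (!all(bases %in% c("A", "C", "G", "T")))
                stop("bracket classes may only contain A, C, G, T: ", pattern)
            out <- c(out, .IUPAC_FROM_SET[[paste(bases, collapse = "")]])
            i <- i + close
        } else {
            if (!ch %in% c("A", "C", "G", "T"))
                stop("invalid literal base '", ch, "' in pattern: ", pattern)
            out <- c(out, ch)
            i <- i + 1L
        }
    }
    paste(out, collapse = "")
}

#' Extract promoters upstream of gene start codons
#'
#' For a plus-strand gene the promoter is the `length` bases immediately 5'
#' of the gene start, in genomic orientation; for a minus-strand gene it is
#' the `length` bases immediately 3' of the gene end, reverse-complemented
#' so that the returned sequence reads 5'->3' towards the gene. Promoters
#' running off the chromosome edge are truncated and flagged.
#'
#' @param genome a [Biostrings::DNAStringSet], names = chromosome ids.
#' @param genes a [GenomicRanges::GRanges] with one range per gene
#'   (names = gene ids, strand `+` or `-`), or a `GRangesList` of exons
#'   from which the gene span is taken.
#' @param length promoter length in bp (default 2000).
#' @return A [Biostrings::DNAStringSet] of promoters (names = gene ids)
#'   whose `mcols()` carry a logical `truncated` flag; truncation also emits
#'   a warning.
#' @export
extractPromoters <- function(genome, genes, length = 2000L) {
    stopifnot(is(genome, "DNAStringSet"), length >= 1L)
    if (is(genes, "GRangesList"))
        genes <- unlist(range(genes))
    stopifnot(is(genes, "GRanges"))
    ids <- names(genes)
    if (is.null(ids))
        ids <- paste0("gene", seq_along(genes))
    out <- vector("list", length(genes))
    truncated <- logical(length(genes))
    for (i in seq_along(genes)) {
        chr <- as.character(GenomicRanges::seqnames(genes)[i])
        if (!chr %in% names(genome))
            stop("chromosome '", chr, "' not present in the genome")
        chrlen <- length(genome[[chr]])
        strand <- as.character(GenomicRanges::strand(genes)[i])
        if (strand == "+") {
            to <- GenomicRanges::start(genes)[i] - 1L
            from <- max(1L, to - length + 1L)
            if (to < 1L)
                stop("gene '", ids[i], "' starts at the chromosome edge; ",
                     "no upstream sequence")
            seq <- Biostrings::subseq(genome[[chr]], from, to)
        } else if (strand == "-") {
            from <- GenomicRanges::end(genes)[i] + 1L
            to <- min(chrlen, from + length - 1L)
            if (from > chrlen)
                stop("gene '", ids[i], "' ends at the chromosome edge; ",
                     "no upstream sequence")
            seq <- Biostrings::reverseComplement(
                Biostrings::subseq(genome[[chr]], from, to))
        } else {
            stop("gene '", ids[i], "' has no strand")
        }
        truncated[i] <- length(seq) < length
        out[[i]] <- seq
    }
    if (any(truncated))
        warning("truncated promoter(s): ",
                paste(ids[truncated], collapse = ", "))
    prom <- Biostrings::DNAStringSet(out)
    names(prom) <- ids
    S4Vectors::mcols(prom)$truncated <- truncated
    prom
}

#' Scan promoters for cis-elements
#'
#' Reports every occurrence of every element, overlapping occurrences
#' included. Minus-strand hits are found by matching the reverse complement
#' of the pattern against the promoter; their `start` is still given in
#' forward promoter coordinates (1-based from the promoter's 5' end) and
#' `match` holds the element-oriented (reverse-complemented) sequence.
#' `N` bases never match.
#'
#' @param promoters a [Biostrings::DNAStringSet] (names = gene ids) or
#'   named character vector over `{A,C,G,T,N}`.
#' @param elements a `data.frame` with `name` and `pattern` columns;
#'   defaults to [cisElements()].
#' @param bothStrands scan the reverse strand too (default `TRUE`)?
#' @return A `data.frame` with columns `gene_id`, `element`, `start`,
#'   `end`, `strand`, `match`, sorted by (gene, element, start, strand).
#' @examples
#' scanElements(c(g1 = "TTGACC"))
#' @export
scanElements <- function(promoters, elements = cisElements(),
                         bothStrands = TRUE) {
    if (is.character(promoters))
        promoters <- Biostrings::DNAStringSet(promoters)
    stopifnot(is(promoters, "DNAStringSet"))
    ids <- names(promoters)
    if (is.null(ids))
        ids <- paste0("gene", seq_along(promoters))
    rows <- list()
    for (e in seq_len(nrow(elements))) {
        pat <- Biostrings::DNAString(.compilePattern(elements$pattern[e]))
        strands <- if (bothStrands) c("+", "-") else "+"
        for (strand in strands) {
            qpat <- if (strand == "+") pat else
                Biostrings::reverseComplement(pat)
            hits <- Biostrings::vmatchPattern(
                qpat, promoters, fixed = "subject")
            for (i in seq_along(promoters)) {
                rg <- hits[[i]]
                if (!length(rg))
                    next
                matched <- as.character(Biostrings::extractAt(
                    promoters[[i]], rg))
                if (strand == "-")
                    matched <- as.character(Biostrings::reverseComplement(
                        Biostrings::DNAStringSet(matched)))
                rows[[length(rows) + 1L]] <- data.frame(
                    gene_id = ids[i],
                    element = elements$name[e],
                    start = IRanges::start(rg),
                    end = IRanges::end(rg),
                    strand = strand,
                    match = matched,
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(rows)) {
        out <- data.frame(gene_id = character(), element = character(),
                          start = integer(), end = integer(),
                          strand = character(), match = character(),
                          stringsAsFactors = FALSE)
        return(out)
    }
    out <- do.call(rbind, rows)
    out <- out[order(match(out$gene_id, ids), out$element, out$start,
                     out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Summarise cis-element hits per gene
#'
#' @param hits output of [scanElements()].
#' @param promoters the promoter set the hits came from (so genes with zero
#'   hits are included).
#' @param elements element definitions (default [cisElements()]).
#' @param k threshold for the "more than k distinct element types" set
#'   (default 4).
#' @param wbox name of the W-box element (default `"W-box"`).
#' @param collapsePalindromes if `TRUE`, plus/minus hits of the same element
#'   at the same site (same gene, start) are counted once; default `FALSE`
#'   (both reported, relevant for palindromic elements such as the G-box).
#' @return A list with `counts` (genes x elements integer matrix),
#'   `wboxFraction` (fraction of genes with at least one W-box) and
#'   `genesOverK` (ids of genes with more than `k` distinct element types).
#' @export
summarizeElements <- function(hits, promoters, elements = cisElements(),
                              k = 4L, wbox = "W-box",
                              collapsePalindromes = FALSE) {
    ids <- names(promoters)
    if (is.null(ids))
        ids <- paste0("gene", seq_along(promoters))
    if (collapsePalindromes && nrow(hits))
        hits <- hits[!duplicated(hits[, c("gene_id", "element", "start")]), ,
                     drop = FALSE]
    counts <- matrix(0L, length(ids), nrow(elements),
                     dimnames = list(ids, elements$name))
    if (nrow(hits)) {
        tab <- table(factor(hits$gene_id, levels = ids),
                     factor(hits$element, levels = elements$name))
        counts[] <- as.integer(tab)
    }
    stopifnot(sum(counts) == nrow(hits))
    wfrac <- if (length(ids)) mean(counts[, wbox] >= 1L) else 0
    distinct <- rowSums(counts > 0L)
    list(counts = counts,
         wboxFraction = wfrac,
         genesOverK = ids[distinct > k])
}
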