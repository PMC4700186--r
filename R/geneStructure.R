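## Gene-structure statistics: intron counts, intronless partition,
## copy-number groups. Gene models are exon sets held as a GRangesList
## (one element per gene, names = gene ids); coordinates are 1-based
## inclusive, matching GFF3.

#' The curated ZmVQ family table
#'
#' The 61-member maize VQ family, one row per gene: `gene_id`
#' (ZmVQ1..ZmVQ61, numbered by chromosomal position), `accession`,
#' `chromosome`, `start`/`end` (1-based bp), `copy_number`,
#' `intron_number`, `amino_acids`, `pI`, `MW_kDa` and the conserved
#' 10-residue VQ `decamer`. Values are fixture data reproduced as published
#' (including the implausible ZmVQ10 molecular weight, kept verbatim and
#' excluded from any computation).
#'
#' @return A `data.frame` with 61 rows.
#' @examples
#' tab <- zmvqFamilyTable()
#' table(classifyDecamer(tab$decamer))
#' @export
zmvqFamilyTable <- function() {
    path <- system.file("extdata", "zmvq_family_table.tsv",
                        package = "VQFamily", mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(nrow(tab) == 61L, !anyDuplicated(tab$gene_id),
              all(tab$start < tab$end))
    tab
}

.checkGeneModel <- function(exons, id) {
    if (length(exons) < 1L)
        stop("gene '", id, "' has no exons")
    s <- GenomicRanges::start(exons)
    e <- GenomicRanges::end(exons)
    o <- order(s)
    if (any(e[o][-length(o)] >= s[o][-1L]))
        stop("gene '", id, "' has overlapping exons")
    if (length(unique(as.character(GenomicRanges::strand(exons)))) > 1L)
        stop("gene '", id, "' mixes strands")
    invisible(TRUE)
}

#' Count introns of gene models
#'
#' An intron count is simply (number of exons) - 1, and is invariant under
#' strand flips.
#'
#' @param models a [GenomicRanges::GRangesList] of exons (one element per
#'   gene, names = gene ids) or a single [GenomicRanges::GRanges] holding the
#'   exons of one gene.
#' @return Named integer vector of intron counts.
#' @export
countIntrons <- function(models) {
    if (is(models, "GRanges"))
        models <- GenomicRanges::GRangesList(gene = models)
    stopifnot(is(models, "GRangesList"))
    ids <- names(models)
    if (is.null(ids))
        ids <- paste0("gene", seq_along(models))
    for (i in seq_along(models))
        .checkGeneModel(models[[i]], ids[i])
    stats::setNames(lengths(models) - 1L, ids)
}

#' Partition genes into intronless and introned
#'
#' @param x either a named integer vector of intron counts (e.g. from
#'   [countIntrons()]), a `GRangesList` of gene models, or a `data.frame`
#'   with columns `gene_id` and `intron_number` (such as
#'   [zmvqFamilyTable()]).
#' @return A list with `intronlessCount`, `intronlessIds` and `intronedIds`;
#'   the two id sets partition the input.
#' @examples
#' intronlessSummary(zmvqFamilyTable())$intronlessCount  # 54
#' @export
intronlessSummary <- function(x) {
    if (is(x, "GRangesList"))
        x <- countIntrons(x)
    if (is.data.frame(x))
        x <- stats::setNames(x$intron_number, x$gene_id)
    stopifnot(is.numeric(x))
    if (anyNA(x))
        stop("missing intron counts for: ",
             paste(names(x)[is.na(x)], collapse = ", "))
    list(intronlessCount = sum(x == 0L),
         intronlessIds = names(x)[x == 0L],
         intronedIds = names(x)[x > 0L])
}

#' Global pairwise percent identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps) via
#' [Biostrings::pairwiseAlignment()]; identity is computed over the full
#' alignment length (PID1), so it is 1 exactly when the sequences are
#' identical.
#'
#' @param a,b amino-acid sequences (character scalars).
#' @return Identity fraction in \[0, 1\].
#' @export
pairwiseIdentity <- function(a, b) {
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b),
        substitutionMatrix = "BLOSUM62",
        gapOpening = 10, gapExtension = 0.5, type = "global")
    Biostrings::pid(aln, type = "PID1") / 100
}

#' Group proteins into copy-number groups
#'
#' Single-linkage grouping of proteins whose global pairwise identity is at
#' least `identityThreshold`; a gene's copy number is the size of its group.
#' The default threshold 1.0 groups exact duplicates only.
#'
#' @param proteins an [Biostrings::AAStringSet] or named character vector.
#' @param identityThreshold identity fraction in (0, 1\].
#' @return A list with `groups` (list of id vectors, a partition of the
#'   input) and `copyNumber` (named integer per gene).
#' @examples
#' copyNumberGroups(c(a = "MKV", b = "MKV", c = "MIV"))$copyNumber
#' @export
copyNumberGroups <- function(proteins, identityThreshold = 1.0) {
    stopifnot(identityThreshold > 0, identityThreshold <= 1)
    if (is(proteins, "XStringSet"))
        proteins <- as.character(proteins)
    n <- length(proteins)
    if (n == 0L)
        return(list(groups = list(), copyNumber = integer()))
    if (is.null(names(proteins)))
        names(proteins) <- paste0("protein", seq_len(n))
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1L)) {
        for (j in seq((i + 1L), n)) {
            ident <- if (proteins[[i]] == proteins[[j]]) 1.0 else
                pairwiseIdentity(proteins[[i]], proteins[[j]])
            if (ident >= identityThreshold) {
                ri <- find(i); rj <- find(j)
                if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
            }
        }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    groups <- unname(split(names(proteins), roots))
    copy_number <- stats::setNames(integer(n), names(proteins))
    for (g in groups) copy_number[g] <- length(g)
    list(groups = groups, copyNumber = copy_number)
}

#' Count single-copy genes in a family table
#'
#' @param table a `data.frame` with a `copy_number` column, e.g.
#'   [zmvqFamilyTable()].
#' @return Number of rows with copy number 1.
#' @examples
#' singleCopyCount(zmvqFamilyTable())  # 57
#' @export
singleCopyCount <- function(table) {
    stopifnot("copy_number" %in% colnames(table),
              !anyNA(table$copy_number))
    sum(table$copy_number == 1L)
}

#' Read gene models from a GFF3 file
#'
#' Imports exon features and groups them by their `Parent` attribute (or
#' `ID`/`gene_id` fallback) into a `GRangesList`, one element per gene.
#'
#' @param file path to a GFF3 file.
#' @return A [GenomicRanges::GRangesList] of exons, names = gene ids.
#' @export
readGeneModelsGff3 <- function(file) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
        stop("reading GFF3 requires the rtracklayer package")
    gr <- rtracklayer::import(file, format = "gff3")
    gr <- gr[tolower(as.character(gr$type)) == "exon"]
    parent <- as.character(S4Vectors::mcols(gr)$Parent)
    if (!length(parent) || all(is.na(parent)) || !nzchar(parent[1]))
        stop("exon features must carry a Parent attribute")
    GenomicRanges::split(gr, parent)
}
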