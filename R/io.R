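## Light I/O wrappers over Biostrings for the formats the pipeline consumes.

#' Read proteins from a FASTA file
#'
#' Sequence ids are the first whitespace-delimited token of each
#' description line.
#'
#' @param file path to a (multi-record) protein FASTA file.
#' @return An [Biostrings::AAStringSet] with unique ids.
#' @export
readProteinFasta <- function(file) {
    aa <- Biostrings::readAAStringSet(file)
    names(aa) <- sub("\\s.*$", "", names(aa))
    if (anyDuplicated(names(aa)))
        stop("duplicate protein ids in ", file)
    aa
}

#' Read an aligned protein FASTA file
#'
#' @param file path to an aligned FASTA (residues plus `-`/`.` gaps, all
#'   records the same length).
#' @return Named character vector of aligned sequences.
#' @export
readAlignedFasta <- function(file) {
    aa <- Biostrings::readAAStringSet(file)
    names(aa) <- sub("\\s.*$", "", names(aa))
    out <- as.character(aa)
    if (length(unique(nchar(out))) > 1L)
        stop("aligned records differ in length in ", file)
    out
}

#' Read a genome FASTA file
#'
#' @param file path to a DNA FASTA file; ids are the first token of each
#'   description line.
#' @return A [Biostrings::DNAStringSet].
#' @export
readGenomeFasta <- function(file) {
    dna <- Biostrings::readDNAStringSet(file)
    names(dna) <- sub("\\s.*$", "", names(dna))
    dna
}

#' Read an expression matrix and sample metadata
#'
#' @param matrixFile TSV of genes x samples (first column = gene ids).
#' @param metaFile optional TSV of sample metadata with a `sample` column.
#' @return A list with `matrix` (numeric matrix) and `meta` (`data.frame`
#'   or `NULL`).
#' @export
readExpressionTsv <- function(matrixFile, metaFile = NULL) {
    tab <- utils::read.delim(matrixFile, stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    meta <- if (!is.null(metaFile))
        utils::read.delim(metaFile, stringsAsFactors = FALSE)
    list(matrix = m, meta = meta)
}
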