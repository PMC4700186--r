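## VQ decamer location and classification.
##
## The family is defined by a ten-residue window (the "decamer") whose
## loosest printed consensus is FxxxVxxxTx; the working master pattern
## tightens it to F-x(3)-V-[QH]-x(2)-T-x (positions 1, 5 and 9 fixed as
## F, V, T; position 6 restricted to Q or H). Every decamer of the curated
## ZmVQ family satisfies this pattern, and the tightening keeps random
## sequence from flooding the scan with spurious windows.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.MASTER_RE <- "F[A-Z]{3}V[QH][A-Z]{2}T[A-Z]"

#' Test decamers against the master VQ pattern
#'
#' The master pattern is `F-x(3)-V-[QH]-x(2)-T-x`: position 1 is F,
#' position 5 is V, position 6 is Q or H, position 9 is T; all positions are
#' 1-based within the decamer.
#'
#' @param decamer character vector of candidate 10-residue windows.
#' @return Logical vector: does each string satisfy the master pattern
#'   (including having length exactly 10)?
#' @examples
#' isMasterDecamer(c("FRALVQELTG", "AAAAAAAAAA"))
#' @export
isMasterDecamer <- function(decamer) {
    stopifnot(is.character(decamer))
    nchar(decamer) == 10L &
        grepl(paste0("^", .MASTER_RE, "$"), decamer)
}

#' Classify a VQ decamer
#'
#' Assigns each master-pattern decamer to exactly one class, by precedence:
#' `CANONICAL` if positions (1,5,6,8,9,10) are (F,V,Q,L,T,G) — the
#' FxxxVQxLTG consensus; else `VH_VARIANT` if the core (position 6) is H;
#' else `TG_VARIANT` if positions 9–10 are TG (FxxxVQxxTG); else
#' `LTX_VARIANT` if positions 8–9 are LT (FxxxVQxLTx); else `OTHER`.
#' `VH_VARIANT` outranks `TG_VARIANT` so that VH-core decamers ending in TG
#' are not absorbed into the TG class.
#'
#' @param decamer character vector of decamers; every element must satisfy
#'   the master pattern (see [isMasterDecamer()]), otherwise an error is
#'   signalled (precondition violation, distinct from any class label).
#' @return Character vector of motif classes (see [motifClasses()]).
#' @examples
#' classifyDecamer("FRALVQELTG")   # CANONICAL
#' classifyDecamer("FRRMVHQATG")   # VH_VARIANT
#' classifyDecamer("FRAMVQRVTG")   # TG_VARIANT
#' classifyDecamer("FRDIVQQLTA")   # LTX_VARIANT
#' @export
classifyDecamer <- function(decamer) {
    stopifnot(is.character(decamer))
    if (!length(decamer))
        return(character())
    ok <- isMasterDecamer(decamer)
    if (!all(ok))
        stop("decamer(s) violating the master pattern F-x(3)-V-[QH]-x(2)-T-x: ",
             paste(unique(decamer[!ok]), collapse = ", "))
    p6 <- substr(decamer, 6L, 6L)
    p8 <- substr(decamer, 8L, 8L)
    p10 <- substr(decamer, 10L, 10L)
    cls <- rep("OTHER", length(decamer))
    cls[p8 == "L"] <- "LTX_VARIANT"          # ...LTx (position 9 is T)
    cls[p10 == "G"] <- "TG_VARIANT"          # ...xTG
    cls[p6 == "H"] <- "VH_VARIANT"
    cls[p6 == "Q" & p8 == "L" & p10 == "G"] <- "CANONICAL"
    cls
}

.checkResidues <- function(seqs) {
    bad_re <- paste0("[^", paste(.AA20, collapse = ""), "]")
    for (i in seq_along(seqs)) {
        m <- regexpr(bad_re, seqs[[i]])
        if (m > 0L)
            stop("invalid residue '", substr(seqs[[i]], m, m),
                 "' at position ", m, " of protein '",
                 names(seqs)[i], "'")
    }
    invisible(TRUE)
}

#' Scan proteins for VQ decamer motifs
#'
#' Slides a 10-residue window over each protein and reports every window
#' satisfying the master pattern (overlapping windows included), classified
#' by [classifyDecamer()]. Hits are returned in input protein order, then
#' ascending start position.
#'
#' @param proteins an [Biostrings::AAStringSet] or a named character vector
#'   of protein sequences over the 20-letter amino-acid alphabet (no gaps).
#'   Unnamed single sequences are labelled `protein1`, ...
#' @return A [VQHits] object (zero rows when nothing matches).
#' @examples
#' scanProteins(c(p1 = "AAAFRALVQELTGAAA"))
#' @export
scanProteins <- function(proteins) {
    if (is(proteins, "XStringSet"))
        proteins <- as.character(proteins)
    stopifnot(is.character(proteins))
    if (is.null(names(proteins)))
        names(proteins) <- paste0("protein", seq_along(proteins))
    if (anyDuplicated(names(proteins)))
        stop("protein ids must be unique")
    if (any(nchar(proteins) < 1L))
        stop("empty protein sequence")
    .checkResidues(proteins)
    ids <- starts <- decs <- vector("list", length(proteins))
    for (i in seq_along(proteins)) {
        ## lookahead so overlapping windows are all reported
        m <- gregexpr(paste0("(?=", .MASTER_RE, ")"), proteins[[i]],
                      perl = TRUE)[[1]]
        pos <- as.integer(m[m > 0L])
        ids[[i]] <- rep(names(proteins)[i], length(pos))
        starts[[i]] <- pos
        decs[[i]] <- if (length(pos))
            substring(proteins[[i]], pos, pos + 9L) else character(0)
    }
    VQHits(unlist(ids, use.names = FALSE),
           unlist(starts, use.names = FALSE),
           unlist(decs, use.names = FALSE))
}

#' Summarise family motif composition
#'
#' Computes class counts, the anchor-residue (decamer position 8) histogram
#' and the VH-core count over one decamer per protein. When a protein has
#' several hits the one with the lowest start position is selected
#' (`select = "first"`); with `select = "none"` the hits are taken as given
#' and duplicated protein ids are an error.
#'
#' @param hits a [VQHits] object, e.g. from [scanProteins()].
#' @param select `"first"` (default) or `"none"`.
#' @return A [FamilySummary].
#' @examples
#' summarizeFamily(scanProteins(c(a = "FRALVQELTGAA", b = "AFRAMVQRVTG")))
#' @export
summarizeFamily <- function(hits, select = c("first", "none")) {
    stopifnot(is(hits, "VQHits"))
    select <- match.arg(select)
    if (select == "first" && nrow(hits)) {
        o <- order(match(hits$protein_id, unique(hits$protein_id)),
                   hits$start)
        hits <- hits[o, , drop = FALSE]
        hits <- hits[!duplicated(hits$protein_id), , drop = FALSE]
    }
    if (anyDuplicated(hits$protein_id))
        stop("duplicate protein ids among selected hits: ",
             paste(unique(hits$protein_id[duplicated(hits$protein_id)]),
                   collapse = ", "))
    per_class <- vapply(.MOTIF_CLASSES,
                        function(cl) sum(hits$motif_class == cl), integer(1))
    anchors <- table(hits$anchor_residue)
    anchor_hist <- stats::setNames(as.integer(anchors), names(anchors))
    new("FamilySummary",
        total = nrow(hits),
        perClass = per_class,
        anchorHistogram = anchor_hist,
        coreVHCount = sum(hits$core_residue == "H"))
}

#' Build a VQHits object from per-protein decamers
#'
#' Convenience for summarising families where only the conserved decamer of
#' each protein is recorded (as in the curated ZmVQ table): each decamer is
#' treated as a single hit at position 1.
#'
#' @param ids character vector of protein/gene ids.
#' @param decamers character vector of the same length.
#' @return A [VQHits] object.
#' @examples
#' tab <- zmvqFamilyTable()
#' summarizeFamily(decamersAsHits(tab$gene_id, tab$decamer))
#' @export
decamersAsHits <- function(ids, decamers) {
    stopifnot(length(ids) == length(decamers))
    VQHits(ids, rep(1L, length(decamers)), decamers)
}

#' Write motif hits to a TSV file
#'
#' @param hits a [VQHits] object.
#' @param file output path.
#' @return Invisibly, the file path.
#' @export
writeHitsTsv <- function(hits, file) {
    utils::write.table(as.data.frame(hits), file = file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(file)
}
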