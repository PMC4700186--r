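#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## Recognised motif classes, in classification precedence order.
.MOTIF_CLASSES <- c("CANONICAL", "VH_VARIANT", "TG_VARIANT", "LTX_VARIANT",
                    "OTHER")

#' VQHits: located VQ decamer motifs
#'
#' A [S4Vectors::DataFrame]-derived container holding one row per located VQ
#' decamer. Columns are `protein_id`, `start` (1-based position of the
#' decamer within the protein), `decamer` (the 10-residue window),
#' `motif_class` (one of `CANONICAL`, `VH_VARIANT`, `TG_VARIANT`,
#' `LTX_VARIANT`, `OTHER`), `core_residue` (decamer position 6, Q or H) and
#' `anchor_residue` (decamer position 8, the residue next to the TG
#' di-peptide).
#'
#' @seealso [scanProteins()], [summarizeFamily()]
#' @exportClass VQHits
setClass("VQHits", contains = "DFrame")

.validVQHits <- function(object) {
    msgs <- character()
    need <- c("protein_id", "start", "decamer", "motif_class",
              "core_residue", "anchor_residue")
    if (!all(need %in% colnames(object)))
        return(paste("missing columns:",
                     paste(setdiff(need, colnames(object)), collapse = ", ")))
    if (nrow(object) == 0L)
        return(TRUE)
    if (any(nchar(object$decamer) != 10L))
        msgs <- c(msgs, "all decamers must have length 10")
    if (!all(object$motif_class %in% .MOTIF_CLASSES))
        msgs <- c(msgs, "unknown motif class")
    if (!all(object$core_residue == substr(object$decamer, 6L, 6L)))
        msgs <- c(msgs, "core_residue must be decamer position 6")
    if (!all(object$anchor_residue == substr(object$decamer, 8L, 8L)))
        msgs <- c(msgs, "anchor_residue must be decamer position 8")
    if (any(object$start < 1L))
        msgs <- c(msgs, "start positions are 1-based (>= 1)")
    if (length(msgs)) msgs else TRUE
}

setValidity("VQHits", .validVQHits)

#' Construct a VQHits object
#'
#' @param protein_id character vector of protein identifiers.
#' @param start integer vector, 1-based start of each decamer.
#' @param decamer character vector of 10-residue windows matching the master
#'   pattern `F-x(3)-V-[QH]-x(2)-T-x`.
#' @return A [VQHits] object with classes assigned by [classifyDecamer()].
#' @examples
#' VQHits("p1", 4L, "FRALVQELTG")
#' @export
VQHits <- function(protein_id = character(), start = integer(),
                   decamer = character()) {
    new("VQHits", DataFrame(
        protein_id = as.character(protein_id),
        start = as.integer(start),
        decamer = as.character(decamer),
        motif_class = classifyDecamer(as.character(decamer)),
        core_residue = substr(decamer, 6L, 6L),
        anchor_residue = substr(decamer, 8L, 8L)))
}

setMethod("show", "VQHits", function(object) {
    cat("VQHits with", nrow(object), "hit(s) in",
        length(unique(object$protein_id)), "protein(s)\n")
    callNextMethod()
})

#' FamilySummary: family-level motif composition
#'
#' Counts of motif classes, anchor residues and VH cores over one selected
#' decamer per protein.
#'
#' @slot total integer, number of proteins summarised.
#' @slot perClass named integer, hits per motif class (sums to `total`).
#' @slot anchorHistogram named integer, counts of the residue at decamer
#'   position 8 (sums to `total`).
#' @slot coreVHCount integer, proteins whose core (position 6) is H.
#' @exportClass FamilySummary
setClass("FamilySummary", representation(
    total = "integer",
    perClass = "integer",
    anchorHistogram = "integer",
    coreVHCount = "integer"))

setValidity("FamilySummary", function(object) {
    msgs <- character()
    if (!identical(sort(names(object@perClass)), sort(.MOTIF_CLASSES)))
        msgs <- c(msgs, "perClass must be keyed by the five motif classes")
    if (sum(object@perClass) != object@total)
        msgs <- c(msgs, "perClass must sum to total")
    if (length(object@anchorHistogram) && sum(object@anchorHistogram) != object@total)
        msgs <- c(msgs, "anchorHistogram must sum to total")
    if (object@coreVHCount > object@total)
        msgs <- c(msgs, "coreVHCount cannot exceed total")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "FamilySummary", function(object) {
    cat("FamilySummary of", object@total, "protein(s)\n")
    cat("  classes: ",
        paste(names(object@perClass), object@perClass,
              sep = "=", collapse = ", "), "\n", sep = "")
    cat("  anchors: ",
        paste(names(object@anchorHistogram), object@anchorHistogram,
              sep = "=", collapse = ", "), "\n", sep = "")
    cat("  VH cores:", object@coreVHCount, "\n")
})

#' @describeIn FamilySummary total number of summarised proteins
#' @param object a `FamilySummary`
#' @export
familyTotal <- function(object) object@total

#' @describeIn FamilySummary named per-class counts
#' @export
perClass <- function(object) object@perClass

#' @describeIn FamilySummary named anchor-residue counts
#' @export
anchorHistogram <- function(object) object@anchorHistogram

#' @describeIn FamilySummary number of proteins with an H core
#' @export
coreVHCount <- function(object) object@coreVHCount

#' Recognised VQ motif classes
#'
#' @return Character vector of the five motif classes in classification
#'   precedence order.
#' @export
motifClasses <- function() .MOTIF_CLASSES
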