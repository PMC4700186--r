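## Physicochemical protein properties: average molecular weight and
## isoelectric point (pI) via Henderson-Hasselbalch net charge.

## Average (isotope-averaged) residue masses in daltons; a residue is the
## amino acid minus one water. Free-protein mass = sum(residues) + water.
.RESIDUE_MASS <- c(
    A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.01524

## pKa tables for the two supported scales. Positive groups: N-terminus,
## H, K, R; negative: C-terminus, D, E, C (reduced), Y.
.PKA_TABLES <- list(
    EMBOSS = c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
               H = 6.5, K = 10.8, R = 12.5, Y = 10.1),
    Bjellqvist = c(Nterm = 7.5, Cterm = 3.55, C = 9.0, D = 4.05, E = 4.45,
                   H = 5.98, K = 10.0, R = 12.0, Y = 10.0))

.splitResidues <- function(sequence) {
    stopifnot(is.character(sequence), length(sequence) == 1L,
              nchar(sequence) >= 1L)
    res <- strsplit(sequence, "")[[1]]
    bad <- which(!(res %in% names(.RESIDUE_MASS)))
    if (length(bad))
        stop("unknown residue '", res[bad[1]], "' at position ", bad[1])
    res
}

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water mass.
#'
#' @param sequence amino-acid string (or vector of strings) over the
#'   20-letter alphabet.
#' @return Mass in daltons.
#' @examples
#' molecularWeight("G")  # free glycine, 75.07 Da
#' @export
molecularWeight <- function(sequence) {
    if (length(sequence) > 1L)
        return(vapply(sequence, molecularWeight, numeric(1)))
    res <- .splitResidues(sequence)
    sum(.RESIDUE_MASS[res]) + .WATER_MASS
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, C-terminus and the
#' ionizable side chains (D, E, C, Y, H, K, R). Cysteines are treated as
#' reduced (ionizable). The charge is strictly decreasing in pH.
#'
#' @param sequence amino-acid string.
#' @param pH numeric vector of pH values in (0, 14).
#' @param pKaSet `"EMBOSS"` (default) or `"Bjellqvist"`.
#' @return Net charge in elementary-charge units, one value per `pH`.
#' @export
netCharge <- function(sequence, pH, pKaSet = c("EMBOSS", "Bjellqvist")) {
    pKaSet <- match.arg(pKaSet)
    stopifnot(all(pH > 0), all(pH < 14))
    pka <- .PKA_TABLES[[pKaSet]]
    res <- .splitResidues(sequence)
    counts <- c(Nterm = 1, Cterm = 1,
                vapply(c("C", "D", "E", "H", "K", "R", "Y"),
                       function(a) sum(res == a), numeric(1)))
    pos_groups <- c("Nterm", "H", "K", "R")
    neg_groups <- c("Cterm", "C", "D", "E", "Y")
    charge <- numeric(length(pH))
    for (g in pos_groups)
        charge <- charge + counts[[g]] / (1 + 10^(pH - pka[[g]]))
    for (g in neg_groups)
        charge <- charge - counts[[g]] / (1 + 10^(pka[[g]] - pH))
    charge
}

#' Isoelectric point by bisection
#'
#' The pI is the unique pH in (0, 14) where [netCharge()] crosses zero;
#' it is found by bisection until the bracketing interval is narrower than
#' `tol` pH units.
#'
#' @inheritParams netCharge
#' @param tol bisection interval tolerance in pH units.
#' @return The pI, in pH units.
#' @examples
#' isoelectricPoint("AAAAA")
#' @export
isoelectricPoint <- function(sequence, pKaSet = c("EMBOSS", "Bjellqvist"),
                             tol = 1e-4) {
    pKaSet <- match.arg(pKaSet)
    lo <- 1e-6
    hi <- 14 - 1e-6
    f_lo <- netCharge(sequence, lo, pKaSet)
    f_hi <- netCharge(sequence, hi, pKaSet)
    stopifnot(f_lo > 0, f_hi < 0)
    while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (netCharge(sequence, mid, pKaSet) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
}

#' Tabulate protein properties
#'
#' @param proteins an [Biostrings::AAStringSet] or named character vector.
#' @param pKaSet passed to [isoelectricPoint()].
#' @return A `data.frame` with columns `id`, `length`, `mw_da` and `pI`.
#' @export
proteinProperties <- function(proteins, pKaSet = "EMBOSS") {
    if (is(proteins, "XStringSet"))
        proteins <- as.character(proteins)
    if (is.null(names(proteins)))
        names(proteins) <- paste0("protein", seq_along(proteins))
    data.frame(
        id = names(proteins),
        length = nchar(proteins),
        mw_da = vapply(proteins, molecularWeight, numeric(1)),
        pI = vapply(proteins, isoelectricPoint, numeric(1),
                    pKaSet = pKaSet),
        row.names = NULL)
}
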