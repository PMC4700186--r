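## Seeded synthetic-data generators with recorded ground truth.
##
## One global integer seed drives independent per-generator streams: each
## generator seeds its own stream as seed + a fixed generator offset, so
## adding a generator never shifts another's draws. Defaults emulate the
## maize ZmVQ study design: 61 family members, the Table-derived motif-class
## mix (42 canonical / 15 TG / 1 LTx / 3 VH), 54 intronless genes, 2000-bp
## promoters, a 3-timepoint drought design with 2 RNA-seq replicates per
## arm, and triplicate qPCR.

.GEN_OFFSETS <- c(proteins = 101L, genome = 211L, promoters = 307L,
                  tissue = 401L, drought = 503L, coexpr = 601L,
                  qpcr = 701L)

.genSeed <- function(seed, generator) {
    s <- as.integer(seed) + .GEN_OFFSETS[[generator]]
    stopifnot(s < .Machine$integer.max)
    set.seed(s)
}

.randAA <- function(n) paste(sample(.AA20, n, replace = TRUE), collapse = "")

## draw one decamer of the requested class (verified by classifyDecamer)
.randDecamer <- function(class) {
    x <- function(k) sample(.AA20, k, replace = TRUE)
    repeat {
        d <- switch(class,
            CANONICAL = c("F", x(3), "V", "Q", x(1), "L", "T", "G"),
            VH_VARIANT = c("F", x(3), "V", "H", x(2), "T", x(1)),
            TG_VARIANT = c("F", x(3), "V", "Q", x(1),
                           sample(setdiff(.AA20, "L"), 1), "T", "G"),
            LTX_VARIANT = c("F", x(3), "V", "Q", x(1), "L", "T",
                            sample(setdiff(.AA20, "G"), 1)),
            OTHER = c("F", x(3), "V", "Q", x(1),
                      sample(setdiff(.AA20, "L"), 1), "T",
                      sample(setdiff(.AA20, "G"), 1)),
            stop("unknown motif class: ", class))
        d <- paste(d, collapse = "")
        if (identical(classifyDecamer(d), class))
            return(d)
    }
}

## motif-free random background of the given length
.motifFreeAA <- function(len, maxAttempts = 1000L) {
    for (a in seq_len(maxAttempts)) {
        s <- .randAA(len)
        if (!grepl(.MASTER_RE, s))
            return(s)
    }
    stop("could not draw a motif-free background after ", maxAttempts,
         " attempts")
}

#' Generate proteins with planted VQ decamers
#'
#' Background residues are i.i.d. uniform over the 20 amino acids; each
#' positive protein carries exactly one decamer of its assigned class,
#' planted at a recorded position (backgrounds are rejection-sampled so the
#' planted window is the only master-pattern match); decoys are guaranteed
#' motif-free.
#'
#' @param seed global integer seed.
#' @param classCounts named integer vector of proteins per motif class;
#'   default mirrors the maize family (42 CANONICAL, 15 TG_VARIANT,
#'   1 LTX_VARIANT, 3 VH_VARIANT).
#' @param nDecoys number of motif-free decoy proteins (default 0).
#' @param lengthRange protein length range, sampled uniformly.
#' @return A list with `proteins` (named character vector, usable as an
#'   `AAStringSet` via [Biostrings::AAStringSet()]) and `truth`
#'   (`data.frame`: `id`, `class` (`NA` for decoys), `position`).
#' @export
simProteins <- function(seed = 1L,
                        classCounts = c(CANONICAL = 42L, TG_VARIANT = 15L,
                                        LTX_VARIANT = 1L, VH_VARIANT = 3L),
                        nDecoys = 0L,
                        lengthRange = c(80L, 300L)) {
    stopifnot(all(names(classCounts) %in% .MOTIF_CLASSES),
              all(classCounts >= 0L), nDecoys >= 0L,
              lengthRange[1] >= 20L)
    .genSeed(seed, "proteins")
    classes <- rep(names(classCounts), classCounts)
    n <- length(classes)
    ids <- c(if (n) paste0("VQP", seq_len(n)),
             if (nDecoys) paste0("DECOY", seq_len(nDecoys)))
    seqs <- character(n + nDecoys)
    pos <- rep(NA_integer_, n + nDecoys)
    for (i in seq_len(n)) {
        len <- sample(seq(lengthRange[1], lengthRange[2]), 1L)
        repeat {
            bg <- .motifFreeAA(len - 10L)
            p <- sample(seq_len(len - 9L), 1L)
            s <- paste0(substr(bg, 1L, p - 1L), .randDecamer(classes[i]),
                        substr(bg, p, len - 10L))
            ## planting may create extra master windows at the junctions
            m <- gregexpr(paste0("(?=", .MASTER_RE, ")"), s,
                          perl = TRUE)[[1]]
            if (identical(as.integer(m[m > 0L]), as.integer(p))) {
                seqs[i] <- s
                pos[i] <- p
                break
            }
        }
    }
    for (i in seq_len(nDecoys)) {
        len <- sample(seq(lengthRange[1], lengthRange[2]), 1L)
        seqs[n + i] <- .motifFreeAA(len)
    }
    names(seqs) <- ids
    list(proteins = seqs,
         truth = data.frame(id = ids,
                            class = c(classes,
                                      rep(NA_character_, nDecoys)),
                            position = pos, stringsAsFactors = FALSE))
}

#' Generate a synthetic genome with gene models
#'
#' Genes are placed non-overlapping on both strands of a random chromosome;
#' each gene's exon count is drawn from `intronCounts` + 1 (the default
#' mirrors the maize family: 54 intronless genes and seven genes with one
#' or two introns). Duplicate protein groups of the requested sizes are
#' planted for copy-number tests.
#'
#' @param seed global integer seed.
#' @param intronCounts integer vector, one intron count per gene; default
#'   `c(rep(0, 54), 1, 2, 1, 1, 1, 1, 1)`.
#' @param duplicateGroups integer vector of duplicate-group sizes to plant
#'   among the generated proteins (default none).
#' @param proteinLength length of the generated protein sequences.
#' @return A list with `genome` ([Biostrings::DNAStringSet]), `models`
#'   ([GenomicRanges::GRangesList] of exons), `proteins` (named character),
#'   and `truth` (`data.frame`: `gene_id`, `strand`, `introns`,
#'   `copy_group`).
#' @export
simGenomeGff <- function(seed = 1L,
                         intronCounts = c(rep(0L, 54L), 1L, 2L, 1L, 1L,
                                          1L, 1L, 1L),
                         duplicateGroups = integer(),
                         proteinLength = 120L) {
    stopifnot(all(intronCounts >= 0L), all(duplicateGroups >= 2L))
    .genSeed(seed, "genome")
    n <- length(intronCounts)
    ids <- paste0("SVQ", seq_len(n))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    exon_len <- 200L
    intron_len <- 150L
    gap <- 500L
    cursor <- 1000L
    grl <- vector("list", n)
    for (i in seq_len(n)) {
        k <- intronCounts[i] + 1L
        starts <- cursor + (seq_len(k) - 1L) * (exon_len + intron_len)
        ends <- starts + exon_len - 1L
        grl[[i]] <- GenomicRanges::GRanges(
            "chrS1", IRanges::IRanges(starts, ends), strand = strands[i])
        cursor <- ends[k] + gap
    }
    names(grl) <- ids
    chrlen <- cursor + 2500L
    genome <- Biostrings::DNAStringSet(
        paste(sample(c("A", "C", "G", "T"), chrlen, replace = TRUE),
              collapse = ""))
    names(genome) <- "chrS1"
    ## proteins: motif-free backgrounds; duplicates planted as exact copies
    copy_group <- seq_len(n)
    gi <- 1L
    for (gsize in duplicateGroups) {
        members <- seq(gi, gi + gsize - 1L)
        stopifnot(max(members) <= n)
        copy_group[members] <- gi
        gi <- gi + gsize
    }
    proteins <- character(n)
    for (i in seq_len(n)) {
        proteins[i] <- if (copy_group[i] == i)
            .motifFreeAA(proteinLength)
        else proteins[copy_group[i]]
    }
    names(proteins) <- ids
    list(genome = genome,
         models = GenomicRanges::GRangesList(grl),
         proteins = proteins,
         truth = data.frame(gene_id = ids, strand = strands,
                            introns = intronCounts,
                            copy_group = copy_group,
                            stringsAsFactors = FALSE))
}

.scanCount <- function(prom, elements) {
    nrow(scanElements(prom, elements, bothStrands = TRUE))
}

#' Generate promoters with planted cis-elements
#'
#' Backgrounds are sampled and then locally resampled until no element of
#' the set occurs on either strand; the requested occurrences are then
#' planted at recorded non-overlapping positions and strands, and the
#' result is re-checked so the planted occurrences are exactly the ones a
#' scan reports.
#'
#' @param seed global integer seed.
#' @param plantCounts genes x elements integer matrix of occurrences to
#'   plant (rownames = gene ids; colnames must match `elements$name`).
#' @param length promoter length in bp (default 2000).
#' @param elements element set (default [cisElements()]).
#' @param maxAttempts bound on resampling rounds before giving up.
#' @return A list with `promoters` ([Biostrings::DNAStringSet]) and `truth`
#'   (`data.frame`: `gene_id`, `element`, `start`, `strand`).
#' @export
simPromoters <- function(seed = 1L, plantCounts, length = 2000L,
                         elements = cisElements(), maxAttempts = 200L) {
    stopifnot(is.matrix(plantCounts),
              identical(colnames(plantCounts), elements$name))
    .genSeed(seed, "promoters")
    ngene <- nrow(plantCounts)
    ids <- rownames(plantCounts)
    if (is.null(ids))
        ids <- paste0("PROM", seq_len(ngene))
    iupac <- vapply(elements$pattern, .compilePattern, character(1))
    widths <- nchar(iupac)
    proms <- character(ngene)
    truth <- list()
    for (g in seq_len(ngene)) {
        for (attempt in seq_len(maxAttempts)) {
            s <- paste(sample(c("A", "C", "G", "T"), length,
                              replace = TRUE), collapse = "")
            ## locally resample matched windows until background is clean
            for (round in seq_len(maxAttempts)) {
                hits <- scanElements(stats::setNames(s, "bg"), elements)
                if (!nrow(hits))
                    break
                for (h in seq_len(nrow(hits))) {
                    w <- hits$end[h] - hits$start[h] + 1L
                    substr(s, hits$start[h], hits$end[h]) <-
                        paste(sample(c("A", "C", "G", "T"), w,
                                     replace = TRUE), collapse = "")
                }
            }
            if (nrow(scanElements(stats::setNames(s, "bg"), elements)))
                next                       # background never came clean
            ## choose non-overlapping planting slots (with margins so
            ## planting cannot create junction artefacts to check later)
            counts <- plantCounts[g, ]
            total <- sum(counts)
            if (total == 0L) {
                placed <- data.frame(gene_id = character(),
                                     element = character(),
                                     start = integer(),
                                     strand = character())
                proms[g] <- s
                truth[[g]] <- placed
                break
            }
            maxw <- max(widths)
            slots <- seq(1L, length - maxw + 1L)
            starts <- sort(sample(slots, total))
            ok_slots <- all(diff(starts) > maxw + 2L)
            if (!ok_slots)
                next
            el_of <- rep(elements$name, counts)
            strands <- sample(c("+", "-"), total, replace = TRUE)
            s2 <- s
            for (t in seq_len(total)) {
                e <- match(el_of[t], elements$name)
                inst <- .instantiateIupac(iupac[e])
                if (strands[t] == "-")
                    inst <- as.character(Biostrings::reverseComplement(
                        Biostrings::DNAString(inst)))
                substr(s2, starts[t], starts[t] + widths[e] - 1L) <- inst
            }
            ## accept only if the scan recovers exactly the planted sites.
            ## comparison is on distinct (element, start) keys: palindromic
            ## or self-complementary patterns legitimately hit both strands
            ## at one planted site, which is one key, not two.
            sc <- scanElements(stats::setNames(s2, "x"), elements)
            sc_key <- sort(unique(paste(sc$element, sc$start)))
            planted_key <- sort(paste(el_of, starts))
            if (identical(sc_key, planted_key)) {
                proms[g] <- s2
                truth[[g]] <- data.frame(
                    gene_id = ids[g], element = el_of, start = starts,
                    strand = strands, stringsAsFactors = FALSE)
                break
            }
        }
        if (!nzchar(proms[g]))
            stop("could not plant elements in promoter '", ids[g],
                 "'; try a longer promoter or fewer occurrences")
    }
    promoters <- Biostrings::DNAStringSet(proms)
    names(promoters) <- ids
    list(promoters = promoters,
         truth = do.call(rbind, truth))
}

.IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                    M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
                    S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
                    V = c("A", "C", "G"), H = c("A", "C", "T"),
                    D = c("A", "G", "T"), B = c("C", "G", "T"),
                    N = c("A", "C", "G", "T"))

.instantiateIupac <- function(iupac) {
    paste(vapply(strsplit(iupac, "")[[1]],
                 function(ch) sample(.IUPAC_SETS[[ch]], 1L), character(1)),
          collapse = "")
}

#' Generate a tissue expression matrix with planted archetypes
#'
#' Each non-silent gene's log2 profile is its archetype's mean profile plus
#' Gaussian noise, back-transformed to FPKM; silent genes are all-zero.
#' The default design mirrors the maize tissue panel: 61 genes over 78
#' tissues in four groups of sizes 6 (reproductive-high), 6 (silent),
#' 6 (reproductive-high, second pattern) and 43 (vegetative-high).
#'
#' @param seed global integer seed.
#' @param nTissues number of tissue columns (default 78).
#' @param groupSizes named integer vector of genes per archetype; the
#'   archetype named `"silent"` is all-zero.
#' @param noiseSd Gaussian noise standard deviation on the log2 scale
#'   (default 0.25).
#' @return A list with `matrix` (genes x tissues FPKM) and `truth`
#'   (`data.frame`: `gene_id`, `archetype`).
#' @export
simTissueExpression <- function(seed = 1L, nTissues = 78L,
                                groupSizes = c(A = 6L, silent = 6L,
                                               C = 6L, D = 43L),
                                noiseSd = 0.25) {
    stopifnot(all(groupSizes >= 0L), noiseSd >= 0, nTissues >= 2L)
    .genSeed(seed, "tissue")
    arch <- names(groupSizes)
    ## distinct archetype mean log2 profiles (recorded stream, fixed shape)
    profiles <- lapply(arch, function(a) {
        if (a == "silent") rep(0, nTissues)
        else stats::runif(nTissues, 0, 8)
    })
    names(profiles) <- arch
    assignment <- rep(arch, groupSizes)
    n <- length(assignment)
    ids <- paste0("SVQ", seq_len(n))
    m <- matrix(0, n, nTissues,
                dimnames = list(ids, paste0("tissue", seq_len(nTissues))))
    for (i in seq_len(n)) {
        a <- assignment[i]
        if (a == "silent")
            next
        lg <- profiles[[a]] + stats::rnorm(nTissues, 0, noiseSd)
        m[i, ] <- pmax(2^lg - 1, 0)
    }
    list(matrix = m,
         truth = data.frame(gene_id = ids, archetype = assignment,
                            stringsAsFactors = FALSE))
}

#' Generate a drought-design expression matrix
#'
#' Control log2 levels are gene-specific baselines; treatment arms carry a
#' planted Crelative effect per response class (`EARLY` at day 3,
#' `SUSTAINED` at days 3 and 6, `LATE` at day 6, `REWATER_ONLY` after
#' re-watering, `NON_RESPONSIVE` nowhere), with Gaussian noise on the log2
#' scale. The default class sizes mirror the maize drought cohort: 6
#' early, 10 sustained, 11 late, 14 re-watering-only and 20 non-responsive
#' genes (41 of 61 responsive).
#'
#' @param seed global integer seed.
#' @param classSizes named integer vector of genes per response class.
#' @param effectSize planted |Crelative| in log2 units (default 2; effect
#'   signs are drawn at random per gene).
#' @param noiseSd per-sample log2 noise sd (default 0.1).
#' @param replicates samples per arm and timepoint (default 2, as in the
#'   drought RNA-seq design).
#' @return A list with `matrix` (genes x samples FPKM), `meta`
#'   (`data.frame`: `sample`, `condition`, `timepoint`, `replicate`) and
#'   `truth` (`data.frame`: `gene_id`, `class`).
#' @export
simDroughtExpression <- function(seed = 1L,
                                 classSizes = c(EARLY = 6L, SUSTAINED = 10L,
                                                LATE = 11L,
                                                REWATER_ONLY = 14L,
                                                NON_RESPONSIVE = 20L),
                                 effectSize = 2, noiseSd = 0.1,
                                 replicates = 2L) {
    stopifnot(all(names(classSizes) %in% .DROUGHT_CLASSES),
              effectSize >= 0, noiseSd >= 0, replicates >= 1L)
    .genSeed(seed, "drought")
    tps <- c("day3", "day6", "rewatered")
    classes <- rep(names(classSizes), classSizes)
    n <- length(classes)
    ids <- paste0("SVQ", seq_len(n))
    meta <- expand.grid(replicate = seq_len(replicates),
                        condition = c("control", "treatment"),
                        timepoint = tps, stringsAsFactors = FALSE)
    meta$sample <- paste(meta$condition, meta$timepoint, meta$replicate,
                         sep = "_")
    meta <- meta[, c("sample", "condition", "timepoint", "replicate")]
    effect_at <- function(class, tp) {
        switch(class,
               EARLY = (tp == "day3"),
               SUSTAINED = (tp %in% c("day3", "day6")),
               LATE = (tp == "day6"),
               REWATER_ONLY = (tp == "rewatered"),
               NON_RESPONSIVE = FALSE)
    }
    base <- stats::runif(n, 3, 7)
    sign <- sample(c(-1, 1), n, replace = TRUE)
    m <- matrix(0, n, nrow(meta),
                dimnames = list(ids, meta$sample))
    for (i in seq_len(n)) {
        for (s in seq_len(nrow(meta))) {
            lg <- base[i]
            if (meta$condition[s] == "treatment" &&
                effect_at(classes[i], meta$timepoint[s]))
                lg <- lg + sign[i] * effectSize
            lg <- lg + stats::rnorm(1, 0, noiseSd)
            m[i, s] <- max(2^lg - 1, 0)
        }
    }
    list(matrix = m, meta = meta,
         truth = data.frame(gene_id = ids, class = classes,
                            stringsAsFactors = FALSE))
}

#' Generate a co-expression matrix with planted gene blocks
#'
#' Genes within a block share a latent factor: each block gene's profile is
#' a positive multiple of the block factor plus an offset and Gaussian
#' noise; background genes are independent noise.
#'
#' @param seed global integer seed.
#' @param nGenes total number of genes.
#' @param blocks list of integer vectors, each the gene indices of one
#'   block (disjoint).
#' @param nSamples number of sample columns (default 12, the drought
#'   design's 3 timepoints x 2 arms x 2 replicates).
#' @param noiseSd within-block noise sd (default 0.05).
#' @param labels optional named family labels to attach to the truth.
#' @return A list with `matrix` (genes x samples, nonnegative), `truth`
#'   (`data.frame`: `gene_id`, `block` (`NA` for background)).
#' @export
simCoexpression <- function(seed = 1L, nGenes = 20L,
                            blocks = list(1:5), nSamples = 12L,
                            noiseSd = 0.05) {
    stopifnot(nSamples >= 3L, noiseSd >= 0)
    idx <- unlist(blocks)
    stopifnot(!anyDuplicated(idx), all(idx >= 1L), all(idx <= nGenes))
    .genSeed(seed, "coexpr")
    ids <- paste0("SG", seq_len(nGenes))
    m <- matrix(stats::rnorm(nGenes * nSamples, 5, 1), nGenes, nSamples,
                dimnames = list(ids, paste0("s", seq_len(nSamples))))
    block_of <- rep(NA_integer_, nGenes)
    for (b in seq_along(blocks)) {
        factor <- stats::rnorm(nSamples, 0, 1)
        for (i in blocks[[b]]) {
            a <- stats::runif(1, 0.5, 2)     # positive loading
            m[i, ] <- 5 + a * factor + stats::rnorm(nSamples, 0, noiseSd)
            block_of[i] <- b
        }
    }
    m <- pmax(m, 0)
    list(matrix = m,
         truth = data.frame(gene_id = ids, block = block_of,
                            stringsAsFactors = FALSE))
}

#' Generate a replicated qPCR Ct table
#'
#' Per gene: treatment target Ct = baseline - log2(true fold) + noise,
#' control target Ct = baseline + noise; the reference-gene Ct is constant.
#' The control group is the calibrator.
#'
#' @param seed global integer seed.
#' @param trueFolds named numeric vector of true treatment/control fold
#'   changes, one per gene.
#' @param replicates replicates per gene and condition (default 3, as in
#'   triplicate qPCR).
#' @param ctNoiseSd Ct measurement noise sd in cycles (default 0.1).
#' @param baselineCt control-condition target Ct (default 25).
#' @param referenceCt constant reference-gene Ct (default 15).
#' @return A list with `table` (a `ddct()`-ready `data.frame`) and `truth`
#'   (`data.frame`: `gene`, `fold`).
#' @export
simQpcr <- function(seed = 1L, trueFolds = c(SVQ1 = 20), replicates = 3L,
                    ctNoiseSd = 0.1, baselineCt = 25, referenceCt = 15) {
    stopifnot(replicates >= 2L, all(trueFolds > 0), ctNoiseSd >= 0)
    .genSeed(seed, "qpcr")
    genes <- names(trueFolds)
    if (is.null(genes))
        genes <- paste0("SVQ", seq_along(trueFolds))
    rows <- list()
    for (i in seq_along(trueFolds)) {
        for (cond in c("control", "treatment")) {
            mu <- baselineCt -
                (cond == "treatment") * log2(trueFolds[[i]])
            rows[[length(rows) + 1L]] <- data.frame(
                gene = genes[i], condition = cond, timepoint = "t1",
                replicate = seq_len(replicates),
                ct_target = mu + stats::rnorm(replicates, 0, ctNoiseSd),
                ct_reference = referenceCt,
                stringsAsFactors = FALSE)
        }
    }
    list(table = do.call(rbind, rows),
         truth = data.frame(gene = genes, fold = unname(trueFolds),
                            stringsAsFactors = FALSE))
}
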