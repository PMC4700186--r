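## Independent brute-force oracles used across the suite. These deliberately
## avoid the package's own code paths (regex scanning, IUPAC matching,
## bisection, the NJ agglomeration) so they can stand as references.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomProtein <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

## -- motif scan oracle: test every length-10 window position by position --
bruteMasterWindow <- function(w) {
  ch <- strsplit(w, "")[[1]]
  length(ch) == 10 && ch[1] == "F" && ch[5] == "V" &&
    (ch[6] == "Q" || ch[6] == "H") && ch[9] == "T"
}

bruteScanStarts <- function(seq) {
  n <- nchar(seq)
  if (n < 10) return(integer(0))
  starts <- integer(0)
  for (p in 1:(n - 9)) {
    if (bruteMasterWindow(substr(seq, p, p + 9)))
      starts <- c(starts, p)
  }
  starts
}

## -- cis-element scan oracle: per-position base-set window testing --
## pattern strings use literal bases and bracket classes, e.g. "TTGAC[CT]"
patternSets <- function(pattern) {
  sets <- list()
  i <- 1
  while (i <= nchar(pattern)) {
    ch <- substr(pattern, i, i)
    if (ch == "[") {
      j <- i
      while (substr(pattern, j, j) != "]") j <- j + 1
      sets[[length(sets) + 1]] <-
        strsplit(gsub("/", "", substr(pattern, i + 1, j - 1)), "")[[1]]
      i <- j + 1
    } else {
      sets[[length(sets) + 1]] <- ch
      i <- i + 1
    }
  }
  sets
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revComp <- function(s) {
  paste(rev(unname(COMPLEMENT[strsplit(s, "")[[1]]])), collapse = "")
}

windowMatchesSets <- function(ch, sets) {
  for (k in seq_along(sets)) {
    if (!(ch[k] %in% sets[[k]])) return(FALSE)
  }
  TRUE
}

bruteScanElements <- function(promoters, elements, bothStrands = TRUE) {
  rows <- list()
  for (g in seq_along(promoters)) {
    seq <- promoters[[g]]
    chars <- strsplit(seq, "")[[1]]
    gid <- names(promoters)[g]
    for (e in seq_len(nrow(elements))) {
      sets <- patternSets(elements$pattern[e])
      w <- length(sets)
      if (length(chars) < w) next
      for (p in 1:(length(chars) - w + 1)) {
        win <- chars[p:(p + w - 1)]
        if (windowMatchesSets(win, sets))
          rows[[length(rows) + 1]] <- data.frame(
            gene_id = gid, element = elements$name[e], start = p,
            end = p + w - 1, strand = "+",
            match = paste(win, collapse = ""),
            stringsAsFactors = FALSE)
        if (bothStrands) {
          rc <- rev(unname(COMPLEMENT[win]))
          if (windowMatchesSets(rc, sets))
            rows[[length(rows) + 1]] <- data.frame(
              gene_id = gid, element = elements$name[e], start = p,
              end = p + w - 1, strand = "-",
              match = paste(rc, collapse = ""),
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), element = character(),
                      start = integer(), end = integer(),
                      strand = character(), match = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(match(out$gene_id, names(promoters)), out$element,
                   out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## -- pI grid-search oracle at step 1e-4 over (0, 14) --
gridPI <- function(sequence, pKaSet = "EMBOSS", step = 1e-4) {
  grid <- seq(step, 14 - step, by = step)
  charge <- netCharge(sequence, grid, pKaSet)
  grid[which.min(abs(charge))]
}

## -- exhaustive unrooted-topology enumeration and least-squares scoring --
## leaves are 1..n; internal nodes n+1, n+2, ... in creation order.
enumTopologies <- function(n) {
  stopifnot(n >= 3)
  trees <- list(rbind(c(n + 1, 1), c(n + 1, 2), c(n + 1, 3)))
  if (n == 3) return(trees)
  for (k in 4:n) {
    v <- n + k - 2
    nxt <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr))) {
        t2 <- rbind(tr[-e, , drop = FALSE],
                    c(tr[e, 1], v), c(v, tr[e, 2]), c(v, k))
        nxt[[length(nxt) + 1]] <- t2
      }
    }
    trees <- nxt
  }
  trees
}

## edge-indicator matrix of leaf-pair paths (pairs in row order i<j)
pathMatrix <- function(edges, n) {
  nodes <- max(edges)
  adj <- vector("list", nodes)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, e))
    adj[[b]] <- rbind(adj[[b]], c(a, e))
  }
  findPath <- function(from, to) {
    ## iterative DFS recording edge used to reach each node
    prev_edge <- rep(NA_integer_, nodes)
    prev_node <- rep(NA_integer_, nodes)
    visited <- rep(FALSE, nodes)
    stack <- from
    visited[from] <- TRUE
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (cur == to) break
      nb <- adj[[cur]]
      for (r in seq_len(nrow(nb))) {
        if (!visited[nb[r, 1]]) {
          visited[nb[r, 1]] <- TRUE
          prev_edge[nb[r, 1]] <- nb[r, 2]
          prev_node[nb[r, 1]] <- cur
          stack <- c(stack, nb[r, 1])
        }
      }
    }
    path <- integer(0)
    cur <- to
    while (cur != from) {
      path <- c(path, prev_edge[cur])
      cur <- prev_node[cur]
    }
    path
  }
  pairs <- utils::combn(n, 2)
  A <- matrix(0, ncol(pairs), nrow(edges))
  for (p in seq_len(ncol(pairs))) {
    A[p, findPath(pairs[1, p], pairs[2, p])] <- 1
  }
  A
}

## canonical split keys of a topology over taxa labels t1..tn
splitsFromEdges <- function(edges, n, labels = paste0("t", seq_len(n))) {
  keys <- character(0)
  internal <- edges[, 1] > n & edges[, 2] > n
  for (e in which(internal)) {
    rest <- edges[-e, , drop = FALSE]
    ## leaves reachable from edges[e, 1] without crossing edge e
    reach <- edges[e, 1]
    repeat {
      touch <- rest[, 1] %in% reach | rest[, 2] %in% reach
      new <- setdiff(unique(as.vector(rest[touch, , drop = FALSE])), reach)
      if (!length(new)) break
      reach <- c(reach, new)
    }
    side <- sort(labels[intersect(reach, seq_len(n))])
    if (!(labels[1] %in% side))
      side <- sort(setdiff(labels, side))
    keys <- c(keys, paste(side, collapse = ","))
  }
  unique(keys)
}

## per-size cache of topologies, their projection matrices and split keys
.topoCache <- new.env(parent = emptyenv())

topologiesWithProjections <- function(n) {
  key <- as.character(n)
  if (!is.null(.topoCache[[key]])) return(.topoCache[[key]])
  topos <- enumTopologies(n)
  out <- lapply(topos, function(edges) {
    A <- pathMatrix(edges, n)
    P <- A %*% solve(crossprod(A), t(A))
    list(edges = edges, A = A, P = P,
         splits = splitsFromEdges(edges, n))
  })
  .topoCache[[key]] <- out
  out
}

## additive distance matrix from a random topology with random lengths
randomAdditiveMatrix <- function(n) {
  topos <- topologiesWithProjections(n)
  t <- topos[[sample(length(topos), 1)]]
  len <- stats::runif(ncol(t$A), 0.1, 2)
  dvec <- as.vector(t$A %*% len)
  d <- matrix(0, n, n, dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
  d[lower.tri(d)] <- NA  # fill from pair order i<j
  pairs <- utils::combn(n, 2)
  for (p in seq_len(ncol(pairs)))
    d[pairs[1, p], pairs[2, p]] <- d[pairs[2, p], pairs[1, p]] <- dvec[p]
  list(d = d, splits = t$splits)
}

## least-squares-best topology splits for a distance matrix
lsBestSplits <- function(d) {
  n <- nrow(d)
  pairs <- utils::combn(n, 2)
  dvec <- vapply(seq_len(ncol(pairs)),
                 function(p) d[pairs[1, p], pairs[2, p]], numeric(1))
  topos <- topologiesWithProjections(n)
  scores <- vapply(topos, function(t) sum((dvec - t$P %*% dvec)^2),
                   numeric(1))
  topos[[which.min(scores)]]$splits
}
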