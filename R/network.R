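#' Read a labelled similarity matrix from delimited text
#'
#' The file must contain a square numeric matrix whose first row and first
#' column carry the node identifiers. Blank and non-numeric cells are
#' rejected; values must lie in \[0, 1\] and the matrix must be symmetric
#' within 1e-9.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator (default tab).
#' @return A numeric matrix with identical row and column names.
#' @export
readSimilarityMatrix <- function(path, sep = "\t") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path,
        sep = sep, row.names = 1, check.names = FALSE,
        stringsAsFactors = FALSE, colClasses = NA
    )
    x <- as.matrix(df)
    if (!is.numeric(x)) {
        stop("non-numeric cell in similarity file: ", path)
    }
    if (anyNA(x)) {
        stop("NaN or blank cell in similarity file: ", path)
    }
    mode(x) <- "double"
    msg <- .checkSimMatrix(x, sprintf("'%s'", basename(path)))
    if (!is.null(msg)) stop(msg)
    x
}

# Header detection: a first row made of common column labels rather than ids.
.interactionHeaderNames <- c(
    "drug", "target", "drug_id", "target_id", "drugid", "targetid"
)

#' Read a drug-target interaction edge list
#'
#' Two-column delimited file (drug identifier, target identifier), one known
#' interaction per line, optional header. Identifiers absent from the
#' supplied vocabularies are an error, never silently dropped.
#'
#' @param path Path to the edge-list file.
#' @param drugIds,targetIds Character vectors of valid identifiers, in the
#'   order that defines the rows/columns of the returned matrix.
#' @param sep Field separator (default tab).
#' @return An m x n binary matrix with the given dimnames.
#' @export
readInteractions <- function(path, drugIds, targetIds, sep = "\t") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path,
        sep = sep, header = FALSE, stringsAsFactors = FALSE,
        colClasses = "character", blank.lines.skip = TRUE
    )
    if (ncol(df) != 2) {
        stop("interaction file must have exactly two columns, got ", ncol(df))
    }
    if (nrow(df) > 0 &&
        all(tolower(trimws(unlist(df[1, ]))) %in% .interactionHeaderNames)) {
        df <- df[-1, , drop = FALSE]
    }
    Y <- matrix(0, length(drugIds), length(targetIds),
        dimnames = list(drugIds, targetIds)
    )
    if (nrow(df) == 0) {
        return(Y)
    }
    d <- trimws(df[[1]])
    t <- trimws(df[[2]])
    if (any(d == "" | t == "")) stop("blank identifier in interaction file")
    bad <- unique(c(setdiff(d, drugIds), setdiff(t, targetIds)))
    if (length(bad)) {
        stop(
            "unknown identifier(s) in interaction file: ",
            paste(bad, collapse = ", ")
        )
    }
    Y[cbind(match(d, drugIds), match(t, targetIds))] <- 1
    Y
}

#' Load and validate a heterogeneous drug-target network from files
#'
#' @param drugSimPath,targetSimPath Paths to the two labelled similarity
#'   matrices (see [readSimilarityMatrix()]).
#' @param interactionsPath Path to the two-column interaction edge list.
#' @param sep Field separator used in all three files.
#' @return A validated [DrugTargetNetwork-class].
#' @export
readNetwork <- function(drugSimPath, targetSimPath, interactionsPath,
                        sep = "\t") {
    sd <- readSimilarityMatrix(drugSimPath, sep = sep)
    st <- readSimilarityMatrix(targetSimPath, sep = sep)
    y <- readInteractions(interactionsPath, rownames(sd), rownames(st),
        sep = sep
    )
    DrugTargetNetwork(sd, st, y)
}

#' Write a network to the package's file formats
#'
#' Writes `drug_sim.tsv`, `target_sim.tsv` and `interactions.tsv` (edge
#' list with header) into `dir`, in the formats accepted by
#' [readNetwork()].
#'
#' @param net A [DrugTargetNetwork-class].
#' @param dir Output directory (created if missing).
#' @param sep Field separator.
#' @return Invisibly, a named character vector of the three file paths.
#' @export
writeNetworkFiles <- function(net, dir, sep = "\t") {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(
        drug_sim = file.path(dir, "drug_sim.tsv"),
        target_sim = file.path(dir, "target_sim.tsv"),
        interactions = file.path(dir, "interactions.tsv")
    )
    .writeLabelled <- function(x, path) {
        utils::write.table(
            data.frame(id = rownames(x), x, check.names = FALSE),
            path,
            sep = sep, quote = FALSE, row.names = FALSE
        )
    }
    .writeLabelled(drugSimilarity(net), paths["drug_sim"])
    .writeLabelled(targetSimilarity(net), paths["target_sim"])
    Y <- interactions(net)
    idx <- which(Y == 1, arr.ind = TRUE)
    edges <- data.frame(
        drug = rownames(Y)[idx[, 1]],
        target = colnames(Y)[idx[, 2]]
    )
    edges <- edges[order(edges$drug, edges$target), , drop = FALSE]
    utils::write.table(edges, paths["interactions"],
        sep = sep, quote = FALSE, row.names = FALSE
    )
    invisible(paths)
}

#' Row-normalize a similarity matrix into a transition matrix
#'
#' Converts similarities into transition probabilities
#' `N[i, j] = S[i, j] / sum_j' S[i, j']`. Self-similarity is excluded: the
#' diagonal is zeroed before normalization, so a walker never steps onto
#' the node it currently occupies. A node whose off-diagonal similarities
#' are all zero becomes self-absorbing (`N[i, i] = 1`) so the result is
#' always row-stochastic.
#'
#' @param sim Square similarity matrix with values in \[0, 1\].
#' @return A row-stochastic matrix of the same shape and dimnames.
#' @export
rowNormalize <- function(sim) {
    if (nrow(sim) != ncol(sim)) stop("similarity matrix must be square")
    if (any(!is.finite(sim)) || any(sim < 0 | sim > 1)) {
        stop("similarity values must be finite and in [0, 1]")
    }
    S <- sim
    diag(S) <- 0
    rs <- rowSums(S)
    zero <- rs == 0
    N <- S / ifelse(rs > 0, rs, 1)
    if (any(zero)) {
        N[zero, ] <- 0
        diag(N)[zero] <- 1
    }
    N
}

#' Random walk with restart on a similarity network
#'
#' Iterates `W <- (1 - restart) * N %*% W + restart * W0` from the identity
#' start `W0 = I` until the entrywise L1 norm of successive iterates drops
#' below `tol`. The converged `W[i, j]` is the stationary probability that
#' a walker restarting at node i with probability `restart` is found at
#' node j, and is used as a topology-aware similarity between i and j. The
#' fixed point equals the closed form
#' `restart * solve(I - (1 - restart) * N)`.
#'
#' @param N Row-stochastic transition matrix (see [rowNormalize()]).
#' @param restart Restart probability in (0, 1\]; default 0.4.
#' @param tol Convergence threshold on the L1 norm of the update; default
#'   1e-6.
#' @param maxIter Iteration cap; exceeding it is an error reporting the
#'   last norm.
#' @return The converged matrix, with the number of update steps attached
#'   as attribute `"iterations"`.
#' @examples
#' N <- matrix(c(0, 1, 1, 0), 2, 2)
#' randomWalkWithRestart(N, restart = 0.4) # rows (0.625, 0.375)
#' @export
randomWalkWithRestart <- function(N, restart = 0.4, tol = 1e-6,
                                  maxIter = 1000L) {
    if (nrow(N) != ncol(N)) stop("transition matrix must be square")
    if (any(N < 0) || max(abs(rowSums(N) - 1)) > 1e-9) {
        stop("transition matrix must be row-stochastic")
    }
    if (!is.numeric(restart) || restart <= 0 || restart > 1) {
        stop("restart probability must lie in (0, 1]")
    }
    m <- nrow(N)
    W <- diag(m)
    iter <- 0L
    repeat {
        Wnew <- (1 - restart) * (N %*% W)
        diag(Wnew) <- diag(Wnew) + restart
        iter <- iter + 1L
        delta <- sum(abs(Wnew - W))
        W <- Wnew
        if (delta < tol) break
        if (iter >= maxIter) {
            stop(sprintf(
                "random walk did not converge in %d iterations (last L1 norm %.3g)",
                maxIter, delta
            ))
        }
    }
    dimnames(W) <- dimnames(N)
    attr(W, "iterations") <- iter
    W
}

# Undirected edge weight between two like-type nodes: the mean of the two
# directed walk probabilities, with the (restart-inflated) diagonal removed.
.symmetrize <- function(W) {
    S <- (W + t(W)) / 2
    diag(S) <- 0
    attr(S, "iterations") <- NULL
    S
}

#' Select the k most similar neighbours of every node
#'
#' Scores are the symmetrized diffused similarities
#' `(W[i, j] + W[j, i]) / 2`; a node is never its own neighbour (the
#' diagonal of `W` is inflated by the restart term and is ignored). Ties
#' are broken by ascending node index so the table is deterministic.
#'
#' @param W Square (diffused) similarity matrix.
#' @param k Number of neighbours per node, at least 1. If `k` is not
#'   smaller than the node count it degrades to all other nodes with a
#'   warning.
#' @return An integer matrix with one row per node and `min(k, m - 1)`
#'   columns of node indices, most similar first; row names carry the node
#'   identifiers when `W` has dimnames.
#' @export
selectKNeighbors <- function(W, k) {
    m <- nrow(W)
    if (m != ncol(W)) stop("similarity matrix must be square")
    if (!is.numeric(k) || k < 1) stop("k must be at least 1")
    k <- as.integer(k)
    if (k > m - 1L) {
        warning(sprintf(
            "k = %d >= node count %d; using all %d other nodes", k, m, m - 1L
        ))
        k <- m - 1L
    }
    S <- .symmetrize(W)
    out <- matrix(0L, m, k)
    for (i in seq_len(m)) {
        # order() is stable, so equal scores resolve to the lower index
        ord <- order(S[i, ], decreasing = TRUE)
        ord <- ord[ord != i]
        out[i, ] <- ord[seq_len(k)]
    }
    rownames(out) <- rownames(W)
    out
}
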