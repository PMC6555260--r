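#' DrugTargetNetwork: a heterogeneous drug-target network
#'
#' Container for the three layers of the heterogeneous network used
#' throughout the package: a drug-drug similarity matrix (e.g. Tanimoto
#' coefficients on chemical structures), a target-target similarity matrix
#' (e.g. normalised Smith-Waterman scores on protein sequences), and a
#' binary drug-target interaction matrix. Similarity values are unitless
#' scores in \[0, 1\]; a positive off-diagonal entry is an edge weighted by
#' that similarity. A known interaction is an edge of weight exactly 1.
#'
#' Row/column identifiers of the similarity matrices define the node sets;
#' the interaction matrix must carry the same identifiers in the same order.
#'
#' @slot drugSim m x m symmetric numeric matrix of drug similarities with
#'   identical row and column names (the drug identifiers).
#' @slot targetSim n x n symmetric numeric matrix of target similarities
#'   with identical row and column names (the target identifiers).
#' @slot interactions m x n binary matrix; `interactions[i, j] == 1` iff
#'   drug i is known to interact with target j.
#'
#' @seealso [readNetwork()], [workedExampleFixture()], [generateNetwork()]
#' @name DrugTargetNetwork-class
#' @aliases DrugTargetNetwork-class
#' @exportClass DrugTargetNetwork
setClass("DrugTargetNetwork",
    slots = c(
        drugSim = "matrix",
        targetSim = "matrix",
        interactions = "matrix"
    )
)

.checkSimMatrix <- function(x, what, tol = 1e-9) {
    if (!is.numeric(x)) {
        return(sprintf("%s similarity matrix must be numeric", what))
    }
    if (nrow(x) != ncol(x)) {
        return(sprintf(
            "%s similarity matrix must be square (got %d x %d)",
            what, nrow(x), ncol(x)
        ))
    }
    if (is.null(rownames(x)) || is.null(colnames(x)) ||
        !identical(rownames(x), colnames(x))) {
        return(sprintf(
            "%s similarity matrix must have identical row and column names",
            what
        ))
    }
    if (anyDuplicated(rownames(x))) {
        return(sprintf("duplicated %s identifiers", what))
    }
    if (any(!is.finite(x))) {
        return(sprintf("%s similarity matrix contains non-finite values", what))
    }
    if (any(x < 0 | x > 1)) {
        return(sprintf(
            "%s similarity values out of range [0, 1]", what
        ))
    }
    if (max(abs(x - t(x))) > tol) {
        return(sprintf(
            "%s similarity matrix is asymmetric beyond tolerance %g", what, tol
        ))
    }
    NULL
}

setValidity("DrugTargetNetwork", function(object) {
    msgs <- c(
        .checkSimMatrix(object@drugSim, "drug"),
        .checkSimMatrix(object@targetSim, "target")
    )
    Y <- object@interactions
    if (!is.numeric(Y)) {
        msgs <- c(msgs, "interaction matrix must be numeric")
    } else {
        if (nrow(Y) != nrow(object@drugSim) || ncol(Y) != nrow(object@targetSim)) {
            msgs <- c(msgs, sprintf(
                "interaction matrix dimension mismatch: %d x %d vs %d drugs, %d targets",
                nrow(Y), ncol(Y), nrow(object@drugSim), nrow(object@targetSim)
            ))
        }
        if (!all(Y %in% c(0, 1))) {
            msgs <- c(msgs, "interaction matrix entries must be 0 or 1")
        }
        if (!identical(rownames(Y), rownames(object@drugSim)) ||
            !identical(colnames(Y), rownames(object@targetSim))) {
            msgs <- c(msgs, "interaction matrix identifiers do not match the similarity matrices")
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a DrugTargetNetwork
#'
#' @param drugSim m x m symmetric drug similarity matrix in \[0, 1\] with
#'   drug identifiers as dimnames.
#' @param targetSim n x n symmetric target similarity matrix in \[0, 1\]
#'   with target identifiers as dimnames.
#' @param interactions m x n binary interaction matrix with matching
#'   dimnames.
#' @return A validated [DrugTargetNetwork-class] object.
#' @examples
#' sd <- diag(3); dimnames(sd) <- list(paste0("d", 1:3), paste0("d", 1:3))
#' st <- diag(2); dimnames(st) <- list(paste0("t", 1:2), paste0("t", 1:2))
#' y <- matrix(0, 3, 2, dimnames = list(rownames(sd), rownames(st)))
#' y["d1", "t1"] <- 1
#' DrugTargetNetwork(sd, st, y)
#' @export
DrugTargetNetwork <- function(drugSim, targetSim, interactions) {
    mode(drugSim) <- "double"
    mode(targetSim) <- "double"
    mode(interactions) <- "double"
    methods::new("DrugTargetNetwork",
        drugSim = drugSim, targetSim = targetSim,
        interactions = interactions
    )
}

#' @describeIn DrugTargetNetwork-class drug similarity matrix
#' @param object,x A `DrugTargetNetwork`.
#' @export
setGeneric("drugSimilarity", function(object) standardGeneric("drugSimilarity"))

#' @rdname DrugTargetNetwork-class
#' @export
setMethod("drugSimilarity", "DrugTargetNetwork", function(object) object@drugSim)

#' @describeIn DrugTargetNetwork-class target similarity matrix
#' @export
setGeneric("targetSimilarity", function(object) standardGeneric("targetSimilarity"))

#' @rdname DrugTargetNetwork-class
#' @export
setMethod("targetSimilarity", "DrugTargetNetwork", function(object) object@targetSim)

#' @describeIn DrugTargetNetwork-class binary interaction matrix
#' @export
setGeneric("interactions", function(object) standardGeneric("interactions"))

#' @rdname DrugTargetNetwork-class
#' @export
setMethod("interactions", "DrugTargetNetwork", function(object) object@interactions)

#' @describeIn DrugTargetNetwork-class drug identifiers
#' @export
setGeneric("drugIds", function(object) standardGeneric("drugIds"))

#' @rdname DrugTargetNetwork-class
#' @export
setMethod("drugIds", "DrugTargetNetwork", function(object) rownames(object@drugSim))

#' @describeIn DrugTargetNetwork-class target identifiers
#' @export
setGeneric("targetIds", function(object) standardGeneric("targetIds"))

#' @rdname DrugTargetNetwork-class
#' @export
setMethod("targetIds", "DrugTargetNetwork", function(object) rownames(object@targetSim))

#' @describeIn DrugTargetNetwork-class number of drugs
#' @export
setGeneric("numDrugs", function(object) standardGeneric("numDrugs"))

#' @rdname DrugTargetNetwork-class
#' @export
setMethod("numDrugs", "DrugTargetNetwork", function(object) nrow(object@drugSim))

#' @describeIn DrugTargetNetwork-class number of targets
#' @export
setGeneric("numTargets", function(object) standardGeneric("numTargets"))

#' @rdname DrugTargetNetwork-class
#' @export
setMethod("numTargets", "DrugTargetNetwork", function(object) nrow(object@targetSim))

#' @rdname DrugTargetNetwork-class
#' @export
setMethod("show", "DrugTargetNetwork", function(object) {
    m <- numDrugs(object)
    n <- numTargets(object)
    npos <- sum(object@interactions)
    cat("DrugTargetNetwork\n")
    cat(sprintf("  drugs:   %d (drug-drug edges: %d)\n", m,
        sum(object@drugSim[upper.tri(object@drugSim)] > 0)))
    cat(sprintf("  targets: %d (target-target edges: %d)\n", n,
        sum(object@targetSim[upper.tri(object@targetSim)] > 0)))
    cat(sprintf(
        "  known interactions: %d of %d pairs (%.2f%%)\n",
        npos, m * n, 100 * npos / (m * n)
    ))
    invisible(NULL)
})
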