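## Diffusion embedding of a voxelized connectome.
##
## The connectivity profile of a voxel is its outgoing row concatenated
## with its incoming column. Profiles are sum-normalized, their inner
## products give the similarity matrix S, and the symmetric
## Fokker-Planck normalization W = D^-1/2 S D^-1/2 (the alpha = 0.5
## anisotropy normalization of diffusion maps) yields the operator whose
## eigenvectors, scaled by their eigenvalues, are the embedding
## coordinates.

#' Build connectivity profiles
#'
#' Row \code{i} of the returned \code{n x 2n} matrix is the outgoing row
#' \code{C[i, ]} concatenated with the incoming column \code{C[, i]}.
#'
#' @param conn a [VoxelizedConnectome-class] or a square nonnegative
#'   matrix.
#' @return numeric matrix, \code{n x 2n}.
#' @export
buildProfiles <- function(conn) {
    C <- if (is(conn, "VoxelizedConnectome")) conn@connectivity else as.matrix(conn)
    if (nrow(C) != ncol(C))
        stop("connectivity matrix must be square")
    cbind(C, t(C))
}

#' Sum-normalize profile rows
#'
#' Divides each row by its sum so rows are probability vectors. Rows
#' summing to zero (fully disconnected voxels) are not allowed here;
#' \code{\link{diffusionEmbed}} removes such voxels with a warning
#' before calling this.
#'
#' @param P profile matrix.
#' @return matrix of the same shape with unit row sums.
#' @export
normalizeProfiles <- function(P) {
    rs <- rowSums(P)
    if (any(rs == 0))
        stop("profile rows with zero sum; remove disconnected voxels first")
    P / rs
}

#' Profile similarity matrix
#'
#' \code{S = P' P'^T}, the matrix of inner products of sum-normalized
#' connectivity profiles.
#'
#' @param Pn sum-normalized profile matrix.
#' @return symmetric nonnegative matrix.
#' @export
similarityMatrix <- function(Pn) {
    tcrossprod(Pn)
}

#' Fokker-Planck normalization
#'
#' \code{W = D^-1/2 S D^-1/2} with \code{D} the diagonal of row sums of
#' \code{S}; the symmetric form of the alpha = 0.5 diffusion-map
#' normalization, approximating Fokker-Planck diffusion.
#'
#' @param S symmetric nonnegative similarity matrix.
#' @return symmetric matrix W.
#' @export
fokkerPlanck <- function(S) {
    d <- rowSums(S)
    if (any(d == 0))
        stop("similarity matrix has zero row sums; remove disconnected voxels first")
    s <- 1 / sqrt(d)
    W <- S * tcrossprod(s)
    (W + t(W)) / 2
}

## deterministic sign convention: largest-magnitude entry positive
fixSigns <- function(V) {
    for (j in seq_len(ncol(V))) {
        i <- which.max(abs(V[, j]))
        if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    V
}

#' Diffusion embedding
#'
#' Embeds the voxels of a connectome in the \code{k} strongest
#' nontrivial diffusion components. The transition operator is built via
#' \code{\link{buildProfiles}}, \code{\link{normalizeProfiles}},
#' \code{\link{similarityMatrix}} and \code{\link{fokkerPlanck}}; since W
#' is symmetric positive semidefinite, a dense symmetric
#' eigendecomposition is used. The strongest (stationary) eigenvector is
#' discarded, remaining eigenvectors are sorted by eigenvalue, scaled by
#' \code{lambda^t}, and their signs fixed deterministically (the sign of
#' a component is arbitrary).
#'
#' Voxels whose profile row sums to zero (disconnected) are removed with
#' a warning before embedding; the result records which voxels were
#' embedded.
#'
#' @param conn a [VoxelizedConnectome-class] or square nonnegative matrix.
#' @param k number of components to retain (default 20).
#' @param t diffusion time (default 1).
#' @param alpha anisotropy normalization parameter, recorded for
#'   provenance; 0.5 is embodied in the symmetric normalization.
#' @param voxelIds voxel ids when \code{conn} is a bare matrix.
#' @return an [EmbeddingResult-class].
#' @export
diffusionEmbed <- function(conn, k = 20L, t = 1, alpha = 0.5,
                           voxelIds = NULL) {
    if (is(conn, "VoxelizedConnectome")) {
        C <- conn@connectivity
        ids <- conn@voxelIds
    } else {
        C <- as.matrix(conn)
        ids <- if (is.null(voxelIds)) seq_len(nrow(C)) else voxelIds
    }
    P <- buildProfiles(C)
    rs <- rowSums(P)
    if (any(rs == 0)) {
        drop <- which(rs == 0)
        warning(sprintf("removing %d disconnected voxel(s) before embedding",
                        length(drop)))
        C <- C[-drop, -drop, drop = FALSE]
        ids <- ids[-drop]
        P <- buildProfiles(C)
    }
    n <- nrow(P)
    if (n < k + 2L)
        stop(sprintf("need at least k + 2 = %d voxels after cleanup, got %d",
                     k + 2L, n))
    W <- fokkerPlanck(similarityMatrix(normalizeProfiles(P)))
    eig <- tryCatch(eigen(W, symmetric = TRUE),
                    error = function(e) stop("eigendecomposition failed: ",
                                             conditionMessage(e)))
    ## drop the trivial stationary component (largest eigenvalue), keep k
    keep <- seq.int(2L, k + 1L)
    lam <- pmax(eig$values[keep], 0)
    V <- fixSigns(eig$vectors[, keep, drop = FALSE])
    coords <- sweep(V, 2L, lam^t, `*`)
    colnames(coords) <- paste0("comp_", seq_len(k))
    new("EmbeddingResult",
        coordinates = coords,
        strengths = lam^t,
        voxelIds = as.integer(ids),
        t = t, alpha = alpha)
}

#' Component weights relative to the strongest
#'
#' The per-component strengths normalized so the strongest retained
#' component has weight 1; used as the weights of the cosine-distance
#' splitter.
#'
#' @param emb an [EmbeddingResult-class].
#' @return numeric vector of weights.
#' @export
componentWeights <- function(emb) {
    s <- emb@strengths
    if (s[1L] == 0) rep(0, length(s)) else s / s[1L]
}
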