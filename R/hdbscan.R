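## HDBSCAN on a precomputed distance matrix.
##
## Hierarchical density-based clustering: core distances -> mutual
## reachability distances -> single-linkage hierarchy -> condensed tree
## (clusters persist only while they hold at least minClusterSize
## points) -> excess-of-mass cluster selection. Points that fall out of
## the hierarchy above every selected cluster are labeled 0 (noise).
## Written here because the installed R stack provides no HDBSCAN;
## behaviour follows the reference formulation of Campello et al. as
## implemented in the scikit-learn ecosystem (the root cluster is never
## selected, so the result is either >= 2 clusters or all noise).

#' HDBSCAN clustering of a precomputed distance matrix
#'
#' @param D symmetric nonnegative distance matrix.
#' @param minClusterSize smallest cluster size considered real.
#' @param minSamples neighborhood size for core distances (defaults to
#'   \code{minClusterSize}).
#' @param selection cluster selection: \code{"leaf"} (default) takes the
#'   leaves of the condensed tree (finest stable granularity),
#'   \code{"eom"} the excess-of-mass optimum, which tends to return the
#'   coarsest split of a nested hierarchy.
#' @return integer vector of labels; 0 marks noise/outlier points.
#' @export
hdbscan <- function(D, minClusterSize = 5L, minSamples = minClusterSize,
                    selection = c("leaf", "eom")) {
    selection <- match.arg(selection)
    n <- nrow(D)
    m <- as.integer(minClusterSize)
    if (n < 2L * m) return(rep(0L, n))
    maxd <- max(D)
    ## numerically identical points: nothing to split
    if (maxd <= 1e-9) return(rep(0L, n))
    eps <- maxd * 1e-12

    ## core distance: m-th smallest entry of the row, self included
    core <- apply(D, 1L, function(r) sort(r)[minSamples])
    MR <- pmax(D, outer(core, core, pmax))
    diag(MR) <- 0

    hc <- hclust(as.dist(MR), method = "single")
    merge <- hc$merge
    height <- hc$height
    nm <- nrow(merge)

    ## subtree sizes of dendrogram nodes
    size <- integer(nm)
    for (k in seq_len(nm)) {
        s <- 0L
        for (c in merge[k, ]) s <- s + if (c < 0L) 1L else size[c]
        size[k] <- s
    }

    ## condensed tree ---------------------------------------------------
    ## clusters: id, parent, birth lambda; edges: point fall-outs and
    ## cluster births recorded for stability
    clParent <- c(NA_integer_)      # root = cluster 1
    clBirth <- c(0)
    clSize <- c(n)
    pointCluster <- integer(n)      # cluster each point falls out of
    pointLambda <- numeric(n)
    childEdges <- list()            # per cluster: cluster children ids

    leavesUnder <- function(node) {
        ## node: dendrogram node index (>0) or negated point (<0)
        if (node < 0L) return(-node)
        out <- integer(0)
        stack <- node
        while (length(stack)) {
            k <- stack[length(stack)]; stack <- stack[-length(stack)]
            for (c in merge[k, ]) {
                if (c < 0L) out <- c(out, -c) else stack <- c(stack, c)
            }
        }
        out
    }
    nodeSize <- function(node) if (node < 0L) 1L else size[node]

    ## iterative top-down traversal: (dendrogram node, cluster id)
    stack <- list(list(node = nm, cluster = 1L))
    while (length(stack)) {
        item <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        node <- item$node
        cl <- item$cluster
        if (node < 0L) {  # singleton reached directly: falls out at birth
            p <- -node
            pointCluster[p] <- cl
            pointLambda[p] <- clBirth[cl]
            next
        }
        lam <- 1 / max(height[node], eps)
        ch <- merge[node, ]
        s1 <- nodeSize(ch[1L]); s2 <- nodeSize(ch[2L])
        if (s1 >= m && s2 >= m) {
            for (i in 1:2) {
                newId <- length(clParent) + 1L
                clParent[newId] <- cl
                clBirth[newId] <- lam
                clSize[newId] <- nodeSize(ch[i])
                childEdges[[length(childEdges) + 1L]] <-
                    c(parent = cl, child = newId, lambda = lam)
                stack[[length(stack) + 1L]] <- list(node = ch[i],
                                                    cluster = newId)
            }
        } else if (s1 < m && s2 < m) {
            for (p in c(leavesUnder(ch[1L]), leavesUnder(ch[2L]))) {
                pointCluster[p] <- cl
                pointLambda[p] <- lam
            }
        } else {
            keep <- if (s1 >= m) ch[1L] else ch[2L]
            runt <- if (s1 >= m) ch[2L] else ch[1L]
            for (p in leavesUnder(runt)) {
                pointCluster[p] <- cl
                pointLambda[p] <- lam
            }
            stack[[length(stack) + 1L]] <- list(node = keep, cluster = cl)
        }
    }

    nc <- length(clParent)
    if (nc == 1L) return(rep(0L, n))

    ## stability ---------------------------------------------------------
    stability <- numeric(nc)
    for (p in seq_len(n)) {
        cl <- pointCluster[p]
        stability[cl] <- stability[cl] + (pointLambda[p] - clBirth[cl])
    }
    for (e in childEdges) {
        stability[e["parent"]] <- stability[e["parent"]] +
            clSize[e["child"]] * (e["lambda"] - clBirth[e["parent"]])
    }

    ## cluster selection (root excluded) ----------------------------------
    kids <- vector("list", nc)
    for (e in childEdges)
        kids[[e["parent"]]] <- c(kids[[e["parent"]]], e["child"])
    selected <- rep(FALSE, nc)
    if (selection == "leaf") {
        for (cl in seq.int(2L, nc))
            selected[cl] <- is.null(kids[[cl]])
    } else {
        subtreeStab <- stability
        for (cl in seq.int(nc, 2L)) {
            if (is.null(kids[[cl]])) {
                selected[cl] <- TRUE
            } else {
                childStab <- sum(subtreeStab[kids[[cl]]])
                if (stability[cl] >= childStab) {
                    selected[cl] <- TRUE
                    ## deselect the whole subtree below
                    st <- kids[[cl]]
                    while (length(st)) {
                        c2 <- st[length(st)]; st <- st[-length(st)]
                        selected[c2] <- FALSE
                        st <- c(st, kids[[c2]])
                    }
                } else {
                    subtreeStab[cl] <- childStab
                }
            }
        }
    }

    ## labeling ----------------------------------------------------------
    labelOf <- rep(0L, nc)
    nextLab <- 0L
    for (cl in seq_len(nc)) {
        if (selected[cl]) {
            nextLab <- nextLab + 1L
            labelOf[cl] <- nextLab
        }
    }
    labels <- integer(n)
    for (p in seq_len(n)) {
        cl <- pointCluster[p]
        lab <- 0L
        while (!is.na(cl)) {
            if (selected[cl]) { lab <- labelOf[cl]; break }
            cl <- clParent[cl]
        }
        labels[p] <- lab
    }
    labels
}
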