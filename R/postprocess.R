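## Post-processing of an initial split: extrapolate unlabeled pixels
## with an SVM on pixel coordinates, split spatially noncontiguous
## labels into connected components, merge undersized regions into the
## neighbor sharing the longest boundary, and unflatten to voxels.

#' Extrapolate labels to unlabeled pixels
#'
#' Trains a support vector machine (radial kernel, standardized
#' coordinates) on the labeled pixels' (x, y) positions and assigns each
#' unlabeled valid pixel the predicted class. Labeled pixels keep their
#' labels. With a single labeled class, all unlabeled pixels join it.
#'
#' @param labels integer matrix; 0 = unlabeled, NA = outside region.
#' @param cost,gamma SVM hyperparameters; \code{gamma = NULL} uses the
#'   e1071 default (1/2 for two standardized features).
#' @return integer label matrix with every region pixel labeled.
#' @export
extrapolateLabels <- function(labels, cost = 1, gamma = NULL) {
    unl <- which(!is.na(labels) & labels == 0L)
    if (length(unl) == 0L) return(labels)
    lab <- which(!is.na(labels) & labels > 0L)
    if (length(lab) == 0L)
        stop("cannot extrapolate: no labeled pixels")
    classes <- unique(labels[lab])
    if (length(classes) == 1L) {
        labels[unl] <- classes
        return(labels)
    }
    labxy <- which(!is.na(labels) & labels > 0L, arr.ind = TRUE)
    unlxy <- which(!is.na(labels) & labels == 0L, arr.ind = TRUE)
    train <- data.frame(x = labxy[, 1L], y = labxy[, 2L],
                        cls = factor(labels[lab]))
    args <- list(cls ~ x + y, data = train, kernel = "radial",
                 cost = cost, scale = TRUE)
    if (!is.null(gamma)) args$gamma <- gamma
    fit <- do.call(e1071::svm, args)
    pred <- predict(fit, newdata = data.frame(x = unlxy[, 1L],
                                              y = unlxy[, 2L]))
    labels[unl] <- as.integer(as.character(pred))
    labels
}

## 8-neighborhood connected components of a logical matrix (flood fill)
connectedComponents <- function(mask) {
    d <- dim(mask)
    comp <- matrix(0L, d[1L], d[2L])
    cur <- 0L
    offs <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                  c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
    todo <- which(mask & comp == 0L)
    for (start in todo) {
        if (comp[start] != 0L) next
        cur <- cur + 1L
        queue <- start
        comp[start] <- cur
        while (length(queue)) {
            p <- queue[length(queue)]; queue <- queue[-length(queue)]
            px <- (p - 1L) %% d[1L] + 1L
            py <- (p - 1L) %/% d[1L] + 1L
            nx <- px + offs[, 1L]
            ny <- py + offs[, 2L]
            ok <- nx >= 1L & nx <= d[1L] & ny >= 1L & ny <= d[2L]
            nidx <- nx[ok] + (ny[ok] - 1L) * d[1L]
            nidx <- nidx[mask[nidx] & comp[nidx] == 0L]
            comp[nidx] <- cur
            queue <- c(queue, nidx)
        }
    }
    comp
}

#' Enforce spatial contiguity of labeled regions
#'
#' Splits every label into its 8-neighborhood connected components
#' (equivalent to single-linkage clustering of same-label pixels with
#' Euclidean cutoff sqrt(2)) and assigns new unique labels.
#'
#' @param labels fully labeled integer matrix (NA outside region).
#' @return integer label matrix with contiguous regions, labels 1..m.
#' @export
enforceContinuity <- function(labels) {
    out <- matrix(NA_integer_, nrow(labels), ncol(labels))
    nxt <- 0L
    for (l in sort(unique(labels[!is.na(labels)]))) {
        comp <- connectedComponents(!is.na(labels) & labels == l)
        k <- max(comp)
        sel <- comp > 0L
        out[sel] <- comp[sel] + nxt
        nxt <- nxt + k
    }
    out
}

## boundary length between two labels: number of 8-adjacent pixel pairs
adjacencyCounts <- function(labels) {
    mask <- !is.na(labels)
    cells <- which(mask)
    edges <- gridEdges(mask)
    if (!nrow(edges))
        return(data.frame(a = integer(0), b = integer(0), n = integer(0)))
    la <- labels[cells[edges[, 1L]]]
    lb <- labels[cells[edges[, 2L]]]
    keep <- la != lb
    if (!any(keep))
        return(data.frame(a = integer(0), b = integer(0), n = integer(0)))
    a <- pmin(la[keep], lb[keep])
    b <- pmax(la[keep], lb[keep])
    tab <- table(paste(a, b))
    parts <- do.call(rbind, strsplit(names(tab), " "))
    data.frame(a = as.integer(parts[, 1L]), b = as.integer(parts[, 2L]),
               n = as.integer(tab), row.names = NULL)
}

#' Merge undersized regions
#'
#' Iteratively merges regions below \code{minSize} (smallest first, ties
#' towards the lower label) into the adjacent region sharing the longest
#' boundary (\code{mode = "boundary"}) or with the nearest centroid
#' (\code{mode = "centroid"}). Pixel count is conserved; a region with
#' no neighbor survives regardless of size.
#'
#' @param labels contiguous integer label matrix.
#' @param minSize minimum region size in pixels (default 10).
#' @param mode neighbor-closeness criterion.
#' @return integer label matrix, relabeled 1..m.
#' @export
mergeSmall <- function(labels, minSize = 10L, mode = c("boundary", "centroid")) {
    mode <- match.arg(mode)
    repeat {
        sizes <- table(labels[!is.na(labels)])
        small <- as.integer(names(sizes)[sizes < minSize])
        if (!length(small)) break
        small <- small[order(sizes[as.character(small)], small)]
        target <- small[1L]
        adj <- adjacencyCounts(labels)
        nb <- adj[adj$a == target | adj$b == target, , drop = FALSE]
        if (!nrow(nb)) {
            ## no neighbor at all: drop from consideration by keeping it
            if (length(small) == 1L) break
            ## try the next smallest instead
            found <- FALSE
            for (t2 in small[-1L]) {
                nb2 <- adj[adj$a == t2 | adj$b == t2, , drop = FALSE]
                if (nrow(nb2)) { target <- t2; nb <- nb2; found <- TRUE; break }
            }
            if (!found) break
        }
        others <- ifelse(nb$a == target, nb$b, nb$a)
        if (mode == "boundary") {
            best <- others[order(-nb$n, others)][1L]
        } else {
            cen <- function(l) {
                xy <- which(!is.na(labels) & labels == l, arr.ind = TRUE)
                colMeans(xy)
            }
            ct <- cen(target)
            dists <- vapply(others, function(o) sum((cen(o) - ct)^2), numeric(1))
            best <- others[order(dists, others)][1L]
        }
        labels[!is.na(labels) & labels == target] <- best
    }
    relabelSequential(labels)
}

## relabel positive labels to 1..m preserving order of first appearance
## by label value; 0 and NA pass through
relabelSequential <- function(labels) {
    pos <- sort(unique(labels[!is.na(labels) & labels > 0L]))
    map <- seq_along(pos)
    out <- labels
    out[!is.na(labels) & labels > 0L] <-
        map[match(labels[!is.na(labels) & labels > 0L], pos)]
    out
}

#' Post-process an initial split
#'
#' Applies \code{\link{extrapolateLabels}}, \code{\link{enforceContinuity}}
#' and \code{\link{mergeSmall}} in order, returning a clean labeling with
#' contiguous regions of at least \code{minSize} pixels (labels 1..m).
#'
#' @param labels initial integer label matrix (0 = unlabeled, NA =
#'   outside region).
#' @param minSize minimum region size.
#' @param mergeMode see \code{\link{mergeSmall}}.
#' @return integer label matrix.
#' @export
postProcess <- function(labels, minSize = 10L, mergeMode = "boundary") {
    full <- extrapolateLabels(labels)
    cont <- enforceContinuity(full)
    mergeSmall(cont, minSize = minSize, mode = mergeMode)
}
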