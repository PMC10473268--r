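## Recursive parcellation driver.
##
## A schedule is an ordered list of (method, max applications). Each
## application visits every current leaf region, re-embeds it using only
## within-region connectivity (gradients are context-dependent), applies
## the splitter, post-processes, and accepts the split only if it yields
## at least two regions of at least minSize pixels. Leaves that cannot
## be split are marked atomic for the current method; a method block
## ends early when an application adds no new region. Per-region seeds
## are derived from the master seed and the region's hierarchy path so
## results are deterministic and locally stable.

#' Construct a split schedule
#'
#' @param methods character vector of splitter names, each
#'   \code{"reversal"} or \code{"cosine"}, in application order.
#' @param applications integer vector, maximum applications per method
#'   block.
#' @param minSize minimum region size in pixels (post-processing merge
#'   threshold and split-acceptance bound).
#' @param minVoxels smallest region (in voxels) still embedded; smaller
#'   leaves are final. The default, three voxels per requested
#'   component, keeps the spectral decomposition well determined.
#' @param k number of diffusion components per embedding (capped at
#'   region size - 2).
#' @param kernelWidth,threshold,kernelShape border-map parameters of the
#'   reversal splitter.
#' @param smoothWidth FWHM (pixels) of the Gaussian pre-smoothing applied
#'   to flattened components before gradients are taken.
#' @param gdThreshold,riThreshold acceptance thresholds stored with the
#'   result for flagging non-atomic leaves (no effect on splitting).
#' @param seed master seed.
#' @return list of class \code{"SplitSchedule"}.
#' @export
splitSchedule <- function(methods = c("reversal", "cosine"),
                          applications = c(4L, 3L),
                          minSize = 10L, minVoxels = 3L * k, k = 20L,
                          kernelWidth = 5, threshold = 0.97,
                          kernelShape = "gaussian", smoothWidth = 5,
                          gdThreshold = 30, riThreshold = 0.4,
                          seed = 1L) {
    stopifnot(length(methods) == length(applications), length(methods) >= 1L,
              all(methods %in% c("reversal", "cosine")),
              minSize > 0, all(applications >= 1L))
    structure(list(methods = methods, applications = as.integer(applications),
                   minSize = as.integer(minSize),
                   minVoxels = as.integer(minVoxels), k = as.integer(k),
                   kernelWidth = kernelWidth, threshold = threshold,
                   kernelShape = kernelShape, smoothWidth = smoothWidth,
                   gdThreshold = gdThreshold, riThreshold = riThreshold,
                   seed = as.integer(seed)),
              class = "SplitSchedule")
}

## deterministic per-region seed from master seed and hierarchy path
deriveSeed <- function(seed, path) {
    s <- as.double(seed)
    for (p in path) s <- (s * 31 + p + 7) %% 2147483647
    as.integer(s) + 1L
}

## embed a region; returns NULL when too small / embedding impossible
embedRegion <- function(conn, proj, region, k, minVoxels) {
    sub <- subsetRegion(conn, proj, region)
    n <- nVoxels(sub$conn)
    if (n < minVoxels) return(NULL)
    kk <- min(k, n - 2L)
    if (kk < 1L) return(NULL)
    emb <- tryCatch(
        withCallingHandlers(
            diffusionEmbed(sub$conn, k = kk),
            warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) NULL)
    if (is.null(emb)) return(NULL)
    keep <- match(emb@voxelIds, voxelIds(sub$proj))
    list(emb = emb, proj = subsetProjectionVoxels(sub$proj, keep))
}

## attempt one split of one region; returns NULL or relabeled matrix
trySplit <- function(conn, proj, region, method, schedule) {
    er <- embedRegion(conn, proj, region, schedule$k, schedule$minVoxels)
    if (is.null(er)) return(NULL)
    res <- if (method == "reversal") {
        reversalSplit(er$emb, er$proj, region = region,
                      kernelWidth = schedule$kernelWidth,
                      threshold = schedule$threshold,
                      shape = schedule$kernelShape,
                      minSize = schedule$minSize,
                      smoothWidth = schedule$smoothWidth)
    } else {
        cosineSplit(er$emb, er$proj, region = region,
                    smoothWidth = schedule$smoothWidth)
    }
    if (res$atomic || is.null(res$labels)) return(NULL)
    post <- tryCatch(postProcess(res$labels, minSize = schedule$minSize),
                     error = function(e) NULL)
    if (is.null(post)) return(NULL)
    sizes <- table(post[!is.na(post)])
    if (length(sizes) < 2L || sum(sizes >= schedule$minSize) < 2L)
        return(NULL)
    list(labels = post, component = res$component)
}

#' Run the recursive parcellation pipeline
#'
#' Applies the schedule's splitters recursively to the flat view of a
#' connectome, building a [Parcellation-class] with its region
#' hierarchy. Per-node gd and ri are evaluated on each region in
#' isolation (within-region re-embedding of the two strongest
#' components).
#'
#' @param conn a [VoxelizedConnectome-class].
#' @param proj a [FlatProjection-class] for its voxels.
#' @param schedule a \code{\link{splitSchedule}}.
#' @param verbose logical; log per-split decisions.
#' @return a [Parcellation-class]; the hierarchy carries per-node
#'   \code{gd}, \code{ri}, \code{nPixels}, the splitter used and the
#'   selected component.
#' @export
parcellate <- function(conn, proj, schedule = splitSchedule(),
                       verbose = FALSE) {
    stopifnot(is(conn, "VoxelizedConnectome"), is(proj, "FlatProjection"))
    valid <- validPixelMask(proj)
    labels <- matrix(NA_integer_, proj@dims[1L], proj@dims[2L])
    labels[valid] <- 1L

    nodes <- data.frame(id = 1L, parent = NA_integer_, level = 0L,
                        application = 0L, nPixels = sum(valid),
                        gd = NA_real_, ri = NA_real_,
                        leaf = TRUE, atomic = FALSE, method = NA_character_,
                        component = NA_integer_)
    q <- regionQuality(conn, proj, valid, smoothWidth = schedule$smoothWidth)
    nodes$gd[1L] <- q$gd; nodes$ri[1L] <- q$ri
    paths <- list(`1` = integer(0))
    nextId <- 2L
    ## per-leaf record of methods already tried without success
    exhausted <- list(`1` = character(0))

    appCounter <- 0L
    for (b in seq_along(schedule$methods)) {
        method <- schedule$methods[b]
        for (app in seq_len(schedule$applications[b])) {
            appCounter <- appCounter + 1L
            leaves <- nodes$id[nodes$leaf]
            newRegions <- 0L
            for (lf in leaves) {
                key <- as.character(lf)
                if (method %in% exhausted[[key]]) next
                region <- !is.na(labels) & labels == lf
                if (!any(region)) next
                seedHere <- deriveSeed(schedule$seed, c(paths[[key]], b, app))
                set.seed(seedHere)
                sp <- trySplit(conn, proj, region, method, schedule)
                if (is.null(sp)) {
                    exhausted[[key]] <- c(exhausted[[key]], method)
                    nodes$atomic[nodes$id == lf] <- TRUE
                    next
                }
                subLabs <- sort(unique(sp$labels[!is.na(sp$labels)]))
                if (verbose)
                    message(sprintf("region %d -> %d subregions (%s%s)",
                                    lf, length(subLabs), method,
                                    if (!is.na(sp$component))
                                        paste0(", component ", sp$component)
                                    else ""))
                nodes$leaf[nodes$id == lf] <- FALSE
                nodes$atomic[nodes$id == lf] <- FALSE
                lvl <- nodes$level[nodes$id == lf] + 1L
                for (si in seq_along(subLabs)) {
                    sub <- region & !is.na(sp$labels) & sp$labels == subLabs[si]
                    id <- nextId; nextId <- nextId + 1L
                    labels[sub] <- id
                    qq <- regionQuality(conn, proj, sub,
                                        smoothWidth = schedule$smoothWidth)
                    nodes <- rbind(nodes, data.frame(
                        id = id, parent = lf, level = lvl,
                        application = appCounter,
                        nPixels = sum(sub), gd = qq$gd, ri = qq$ri,
                        leaf = TRUE, atomic = FALSE, method = method,
                        component = if (is.na(sp$component)) NA_integer_
                                    else as.integer(sp$component)))
                    paths[[as.character(id)]] <- c(paths[[key]], si)
                    exhausted[[as.character(id)]] <- character(0)
                }
                newRegions <- newRegions + length(subLabs) - 1L
            }
            if (newRegions == 0L) break  # method resolves no more granularity
        }
    }

    ## diagnostic acceptance flag (Fig-6D-style tree coloring): a leaf
    ## whose quality metrics fall under the thresholds counts as atomic
    nodes$accepted <- nodes$leaf & !is.na(nodes$gd) & !is.na(nodes$ri) &
        nodes$gd <= schedule$gdThreshold & nodes$ri <= schedule$riThreshold

    ## compact leaf labels to 1..m, keep hierarchy ids as region ids
    leafIds <- nodes$id[nodes$leaf]
    final <- matrix(NA_integer_, nrow(labels), ncol(labels))
    for (i in seq_along(leafIds))
        final[!is.na(labels) & labels == leafIds[i]] <- i
    nodes$label <- ifelse(nodes$leaf, match(nodes$id, leafIds), NA_integer_)
    vox <- unflattenLabels(final, proj)
    new("Parcellation", labels = final, voxelLabels = vox,
        voxelIds = voxelIds(proj), hierarchy = nodes)
}

#' Leaf-region quality summary
#'
#' @param parc a [Parcellation-class] produced by \code{\link{parcellate}}.
#' @return data.frame of leaf regions with \code{label}, \code{nPixels},
#'   \code{gd}, \code{ri}.
#' @export
leafMetrics <- function(parc) {
    h <- parc@hierarchy
    h <- h[h$leaf, c("label", "nPixels", "gd", "ri")]
    h[order(h$label), , drop = FALSE]
}

#' Quality metrics of the current leaves after each application
#'
#' Reconstructs, for every splitter application, the set of regions that
#' were leaves at that point of the recursion and summarizes their gd
#' and ri (the after-each-split trend of the region-quality metrics).
#'
#' @param parc a [Parcellation-class] produced by \code{\link{parcellate}}.
#' @return data.frame with one row per application: \code{application},
#'   \code{nLeaves}, \code{medianGd}, \code{medianRi}, \code{meanGd},
#'   \code{meanRi}.
#' @export
applicationTrend <- function(parc) {
    h <- parc@hierarchy
    apps <- sort(unique(h$application))
    apps <- apps[apps > 0]
    out <- NULL
    for (a in apps) {
        nodes <- h[h$application <= a, ]
        isLeafNow <- vapply(nodes$id, function(id) {
            kids <- h$id[!is.na(h$parent) & h$parent == id]
            length(kids) == 0L || all(h$application[match(kids, h$id)] > a)
        }, logical(1))
        cur <- nodes[isLeafNow, ]
        out <- rbind(out, data.frame(
            application = a, nLeaves = nrow(cur),
            medianGd = median(cur$gd, na.rm = TRUE),
            medianRi = median(cur$ri, na.rm = TRUE),
            meanGd = mean(cur$gd, na.rm = TRUE),
            meanRi = mean(cur$ri, na.rm = TRUE)))
    }
    out
}
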