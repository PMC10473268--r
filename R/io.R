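## File formats: connectome as Matrix Market + coordinate CSV, flat-map
## lookup as CSV or NRRD, label volumes as NRRD (integer, 0 =
## unassigned), hierarchy as nested JSON, embeddings and metrics as CSV.

#' Write a voxelized connectome
#'
#' Writes the connection matrix in Matrix Market coordinate format and
#' the voxel coordinates as a CSV \code{voxel_id,i,j,k}.
#'
#' @param conn a [VoxelizedConnectome-class].
#' @param mtxFile path of the .mtx file.
#' @param coordsFile path of the coordinates CSV.
#' @export
writeConnectome <- function(conn, mtxFile, coordsFile) {
    Matrix::writeMM(methods::as(methods::as(conn@connectivity, "CsparseMatrix"),
                                "generalMatrix"), mtxFile)
    df <- data.frame(voxel_id = conn@voxelIds,
                     i = conn@coords[, 1L], j = conn@coords[, 2L],
                     k = conn@coords[, 3L])
    write.csv(df, coordsFile, row.names = FALSE, quote = FALSE)
    invisible(NULL)
}

#' Read a voxelized connectome
#'
#' @param mtxFile Matrix Market file of the connection matrix.
#' @param coordsFile CSV \code{voxel_id,i,j,k} of voxel grid positions.
#' @return a [VoxelizedConnectome-class].
#' @export
readConnectome <- function(mtxFile, coordsFile) {
    M <- as.matrix(Matrix::readMM(mtxFile))
    df <- read.csv(coordsFile)
    need <- c("voxel_id", "i", "j", "k")
    if (!all(need %in% names(df)))
        stop("coordinates CSV must have columns voxel_id,i,j,k")
    if (nrow(df) != nrow(M))
        stop(sprintf("coordinate table has %d voxels but matrix is %d x %d",
                     nrow(df), nrow(M), ncol(M)))
    VoxelizedConnectome(M, as.matrix(df[, c("i", "j", "k")]),
                        voxelIds = df$voxel_id)
}

#' Write / read a flat-map lookup as CSV
#'
#' Columns \code{voxel_id,x,y}: the 0-based pixel of each voxel.
#'
#' @param proj a [FlatProjection-class].
#' @param file path.
#' @export
writeFlatMap <- function(proj, file) {
    write.csv(data.frame(voxel_id = proj@voxelIds,
                         x = proj@pixelX, y = proj@pixelY),
              file, row.names = FALSE, quote = FALSE)
    invisible(NULL)
}

#' @rdname writeFlatMap
#' @param dims optional grid extent; defaults to the bounding box.
#' @return \code{readFlatMap}: a [FlatProjection-class].
#' @export
readFlatMap <- function(file, dims = NULL) {
    df <- read.csv(file)
    if (!all(c("voxel_id", "x", "y") %in% names(df)))
        stop("flat-map CSV must have columns voxel_id,x,y")
    if (is.null(dims)) dims <- c(max(df$x) + 1L, max(df$y) + 1L)
    if (any(df$x < 0L | df$y < 0L | df$x >= dims[1L] | df$y >= dims[2L]))
        stop("flat-map pixels fall outside the declared grid extent")
    FlatProjection(df$voxel_id, df$x, df$y, dims = dims)
}

## ---- minimal NRRD (ascii + raw little-endian) ------------------------------
## Written here because the installed stack has no NRRD reader; covers
## the detached-header-free, single-file NRRD subset this package emits.

nrrdTypeMap <- c("int" = "integer", "signed int" = "integer",
                 "int32" = "integer", "int32_t" = "integer",
                 "double" = "double", "float" = "double",
                 "short" = "integer", "uchar" = "integer",
                 "unsigned char" = "integer")

#' Write an array as NRRD
#'
#' Minimal NRRD writer (ascii or raw little-endian encoding). Integer
#' arrays are written as \code{int}, doubles as \code{double}. Label
#' volumes use 0 for unassigned/outside.
#'
#' @param x numeric/integer array (any dimension); \code{NA} is written
#'   as 0 for integer data.
#' @param file output path.
#' @param encoding \code{"ascii"} (default; text, diff-friendly) or
#'   \code{"raw"}.
#' @export
writeNrrd <- function(x, file, encoding = c("ascii", "raw")) {
    encoding <- match.arg(encoding)
    dims <- dim(x)
    if (is.null(dims)) dims <- length(x)
    isInt <- is.integer(x) || all(is.na(x) | x == round(x))
    v <- as.vector(x)
    if (isInt) {
        v[is.na(v)] <- 0L
        v <- as.integer(v)
        type <- "int"
    } else {
        type <- "double"
    }
    con <- file(file, "wb")
    on.exit(close(con))
    hdr <- c("NRRD0004",
             paste0("type: ", type),
             paste0("dimension: ", length(dims)),
             paste0("sizes: ", paste(dims, collapse = " ")),
             paste0("encoding: ", encoding))
    if (encoding == "raw")
        hdr <- c(hdr, "endian: little")
    writeLines(c(hdr, ""), con)
    if (encoding == "ascii") {
        writeLines(paste(format(v, scientific = TRUE, digits = 17,
                                trim = TRUE), collapse = " "), con)
    } else {
        size <- if (isInt) 4L else 8L
        writeBin(v, con, size = size, endian = "little")
    }
    invisible(NULL)
}

#' Read a NRRD file
#'
#' Reads the subset written by \code{\link{writeNrrd}} (attached header,
#' ascii or raw little-endian encoding, int/double types).
#'
#' @param file path.
#' @return array with the declared dimensions.
#' @export
readNrrd <- function(file) {
    con <- file(file, "rb")
    on.exit(close(con))
    magic <- readLines(con, n = 1L)
    if (!startsWith(magic, "NRRD"))
        stop("not a NRRD file (bad magic)")
    fields <- list()
    repeat {
        ln <- readLines(con, n = 1L)
        if (length(ln) == 0L) stop("malformed NRRD header: no blank line")
        if (ln == "") break
        if (startsWith(ln, "#")) next
        kv <- regmatches(ln, regexpr(": ", ln), invert = TRUE)[[1L]]
        if (length(kv) != 2L) stop("malformed NRRD header line: ", ln)
        fields[[trimws(kv[1L])]] <- trimws(kv[2L])
    }
    need <- c("type", "dimension", "sizes", "encoding")
    if (!all(need %in% names(fields)))
        stop("NRRD header missing required fields: ",
             paste(setdiff(need, names(fields)), collapse = ", "))
    sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1L]])
    if (length(sizes) != as.integer(fields$dimension))
        stop("NRRD sizes do not match declared dimension")
    rmode <- nrrdTypeMap[fields$type]
    if (is.na(rmode)) stop("unsupported NRRD type: ", fields$type)
    n <- prod(sizes)
    if (fields$encoding == "ascii") {
        txt <- readLines(con)
        toks <- strsplit(paste(txt, collapse = " "), "\\s+")[[1L]]
        v <- suppressWarnings(as.numeric(toks[nzchar(toks)]))
    } else if (fields$encoding == "raw") {
        endian <- if (!is.null(fields$endian)) fields$endian else "little"
        size <- switch(fields$type, "double" = 8L, "float" = 4L,
                       "short" = 2L, "uchar" = , "unsigned char" = 1L, 4L)
        what <- if (rmode == "double") numeric() else integer()
        v <- readBin(con, what, n = n, size = size, endian = endian)
    } else {
        stop("unsupported NRRD encoding: ", fields$encoding)
    }
    if (length(v) != n)
        stop(sprintf("NRRD data length %d does not match sizes (%d values)",
                     length(v), n))
    if (rmode == "integer") v <- as.integer(v)
    array(v, dim = sizes)
}

#' Write / read a label volume as NRRD
#'
#' Per-voxel labels are placed in a dense integer volume at the voxel
#' grid positions; 0 marks unassigned grid cells.
#'
#' @param labels integer per-voxel labels.
#' @param coords n x 3 integer voxel grid positions (0-based).
#' @param file path.
#' @param dims optional volume extent; defaults to the coordinate
#'   bounding box.
#' @param encoding see \code{\link{writeNrrd}}.
#' @export
writeLabelVolume <- function(labels, coords, file,
                             dims = apply(coords, 2L, max) + 1L,
                             encoding = "ascii") {
    vol <- array(0L, dim = dims)
    vol[coords + 1L] <- as.integer(labels)
    writeNrrd(vol, file, encoding = encoding)
}

#' @rdname writeLabelVolume
#' @return \code{readLabelVolume}: integer labels at the given
#'   coordinates.
#' @export
readLabelVolume <- function(file, coords) {
    vol <- readNrrd(file)
    if (any(coords < 0L) || any(sweep(coords + 1L, 2L, dim(vol), `>`)))
        stop("voxel coordinates fall outside the label volume")
    as.integer(vol[coords + 1L])
}

## ---- hierarchy JSON ---------------------------------------------------------

hierarchyToNested <- function(h, id) {
    node <- h[h$id == id, , drop = FALSE]
    children <- h$id[!is.na(h$parent) & h$parent == id]
    out <- list(id = node$id,
                acronym = if (!is.null(node$acronym)) node$acronym
                          else paste0("R", node$id))
    for (fld in c("nPixels", "gd", "ri", "level"))
        if (fld %in% names(node)) out[[fld]] <- node[[fld]]
    out$children <- lapply(children, function(c2) hierarchyToNested(h, c2))
    out
}

nestedToHierarchy <- function(node, parent = NA_integer_) {
    row <- data.frame(id = as.integer(node$id),
                      parent = parent,
                      acronym = if (!is.null(node$acronym)) node$acronym
                                else NA_character_,
                      nPixels = if (!is.null(node$nPixels))
                          as.integer(node$nPixels) else NA_integer_,
                      gd = if (!is.null(node$gd)) as.numeric(node$gd)
                           else NA_real_,
                      ri = if (!is.null(node$ri)) as.numeric(node$ri)
                           else NA_real_,
                      level = if (!is.null(node$level))
                          as.integer(node$level) else NA_integer_)
    kids <- node$children
    if (length(kids))
        row <- rbind(row, do.call(rbind, lapply(kids, nestedToHierarchy,
                                                parent = as.integer(node$id))))
    row
}

#' Write / read a region hierarchy as nested JSON
#'
#' Nodes carry \code{id}, \code{acronym}, optional \code{nPixels},
#' \code{gd}, \code{ri}, \code{level}, and a \code{children} array,
#' mirroring atlas structure-graph nesting.
#'
#' @param h hierarchy data.frame (columns \code{id}, \code{parent}, and
#'   optionally the metadata above).
#' @param file path.
#' @export
writeHierarchyJson <- function(h, file) {
    root <- h$id[is.na(h$parent)]
    if (length(root) != 1L) stop("hierarchy must have exactly one root")
    jsonlite::write_json(hierarchyToNested(h, root), file,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(NULL)
}

#' @rdname writeHierarchyJson
#' @return \code{readHierarchyJson}: a hierarchy data.frame.
#' @export
readHierarchyJson <- function(file) {
    nested <- jsonlite::read_json(file)
    out <- nestedToHierarchy(nested)
    out <- out[order(out$id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write an embedding as CSV
#'
#' Coordinates as \code{voxel_id,comp_1..comp_k} plus a strengths CSV
#' \code{component,strength}.
#'
#' @param emb an [EmbeddingResult-class].
#' @param coordsFile,strengthsFile paths.
#' @export
writeEmbedding <- function(emb, coordsFile, strengthsFile) {
    df <- data.frame(voxel_id = emb@voxelIds, emb@coordinates)
    write.csv(df, coordsFile, row.names = FALSE, quote = FALSE)
    write.csv(data.frame(component = seq_along(emb@strengths),
                         strength = emb@strengths),
              strengthsFile, row.names = FALSE, quote = FALSE)
    invisible(NULL)
}

#' Write per-region metrics as CSV
#'
#' @param parc a [Parcellation-class] from \code{\link{parcellate}}.
#' @param file path; columns \code{region,gd,ri,n_pixels}.
#' @export
writeRegionMetrics <- function(parc, file) {
    lm <- leafMetrics(parc)
    write.csv(data.frame(region = lm$label, gd = lm$gd, ri = lm$ri,
                         n_pixels = lm$nPixels),
              file, row.names = FALSE, quote = FALSE)
    invisible(NULL)
}
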