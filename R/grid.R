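#' Construct a GridStack from a list of layer matrices
#'
#' @param layers named list of matrices (all the same dimension), or a 3-D
#'   array with a named third dimension.
#' @param kind character vector (`"continuous"`/`"categorical"`), recycled.
#' @param priority numeric priority ranks (1 = most important); defaults to
#'   layer order.
#' @param cellsize cell edge length in metres.
#' @param origin numeric length-2 lower-left corner.
#' @return a [GridStack-class]
#' @examples
#' s <- gridStack(list(a = matrix(rnorm(64), 8), b = matrix(rnorm(64), 8)))
#' layerNames(s)
#' @export
gridStack <- function(layers, kind = "continuous", priority = NULL,
                      cellsize = 1000, origin = c(0, 0)) {
  if (is.list(layers)) {
    stopifnot(length(layers) >= 1L, !is.null(names(layers)))
    d <- dim(layers[[1L]])
    arr <- array(NA_real_, c(d, length(layers)),
                 dimnames = list(NULL, NULL, names(layers)))
    for (i in seq_along(layers)) arr[, , i] <- layers[[i]]
  } else arr <- layers
  nl <- dim(arr)[3L]
  kind <- rep_len(kind, nl)
  if (is.null(priority)) priority <- seq_len(nl)
  new("GridStack", layers = arr, kind = kind, priority = as.numeric(priority),
      cellsize = cellsize, origin = as.numeric(origin))
}

#' @rdname GridStack-accessors
#' @name GridStack-accessors
#' @aliases layerNames,GridStack-method
setMethod("layerNames", "GridStack", function(x) dimnames(x@layers)[[3L]])

#' @rdname GridStack-accessors
setMethod("nLayers", "GridStack", function(x) dim(x@layers)[3L])

#' @rdname GridStack-accessors
setMethod("getLayer", "GridStack", function(x, name) {
  if (!name %in% layerNames(x))
    stop("no layer named '", name, "'")
  x@layers[, , name]
})

#' @rdname GridStack-accessors
setMethod("layerKind", "GridStack", function(x)
  stats::setNames(x@kind, layerNames(x)))

#' @rdname GridStack-accessors
setMethod("layerPriority", "GridStack", function(x)
  stats::setNames(x@priority, layerNames(x)))

#' @rdname GridStack-accessors
setMethod("gridDim", "GridStack", function(x) dim(x@layers)[1:2])

#' @rdname GridStack-accessors
setMethod("cellSize", "GridStack", function(x) x@cellsize)

#' @rdname GridStack-accessors
setMethod("gridOrigin", "GridStack", function(x) x@origin)

#' Subset a GridStack by layer name
#'
#' @param x a [GridStack-class]
#' @param names layers to keep, in the given order
#' @return a [GridStack-class]
#' @export
subsetLayers <- function(x, names) {
  stopifnot(all(names %in% layerNames(x)))
  idx <- match(names, layerNames(x))
  gridStack(
    x@layers[, , idx, drop = FALSE],
    kind = x@kind[idx], priority = x@priority[idx],
    cellsize = x@cellsize, origin = x@origin
  )
}

setMethod("show", "GridStack", function(object) {
  d <- gridDim(object)
  cat("GridStack:", d[1], "x", d[2], "cells,", nLayers(object), "layers\n")
  cat("  cellsize:", object@cellsize, "m; origin: (",
      object@origin[1], ",", object@origin[2], ")\n")
  cat("  layers:", paste0(layerNames(object), " [", object@kind, "]",
                          collapse = ", "), "\n")
})

#' Construct a SpeciesMap
#'
#' @param species species name
#' @param values matrix of cell values
#' @param what `"occupancy"` or `"abundance"`
#' @param cellsize,origin grid geometry
#' @return a [SpeciesMap-class]
#' @export
speciesMap <- function(species, values, what = c("occupancy", "abundance"),
                       cellsize = 1000, origin = c(0, 0)) {
  new("SpeciesMap", species = species, values = values,
      what = match.arg(what), cellsize = cellsize, origin = as.numeric(origin))
}

#' @rdname SpeciesMap-accessors
#' @name SpeciesMap-accessors
setMethod("mapValues", "SpeciesMap", function(x) x@values)

#' @rdname SpeciesMap-accessors
setMethod("gridDim", "SpeciesMap", function(x) dim(x@values))

#' @rdname SpeciesMap-accessors
setMethod("cellSize", "SpeciesMap", function(x) x@cellsize)

#' @rdname SpeciesMap-accessors
setMethod("gridOrigin", "SpeciesMap", function(x) x@origin)

setMethod("show", "SpeciesMap", function(object) {
  d <- dim(object@values)
  rng <- range(object@values, na.rm = TRUE)
  cat("SpeciesMap (", object@what, "): ", object@species, ", ",
      d[1], " x ", d[2], " cells, range [",
      signif(rng[1], 3), ", ", signif(rng[2], 3), "]\n", sep = "")
})

## ---- cell lookup -----------------------------------------------------------

#' Map point coordinates to grid cell indices
#'
#' Uses the half-open cell convention: cell `i` along an axis covers
#' `[origin + (i-1)*cellsize, origin + i*cellsize)`, so a point on a shared
#' edge belongs to the higher cell.
#'
#' @param x,y point coordinates
#' @param cellsize cell edge length
#' @param origin length-2 lower-left corner
#' @param dim grid dimension (nx, ny); indices outside give `NA`
#' @return a two-column integer matrix (ix, iy)
#' @export
cellIndex <- function(x, y, cellsize, origin, dim) {
  ix <- floor((x - origin[1]) / cellsize) + 1L
  iy <- floor((y - origin[2]) / cellsize) + 1L
  bad <- ix < 1L | ix > dim[1] | iy < 1L | iy > dim[2]
  ix[bad] <- NA_integer_
  iy[bad] <- NA_integer_
  cbind(ix = as.integer(ix), iy = as.integer(iy))
}

#' Extract covariate values at site coordinates
#'
#' Looks up the grid cell containing each site (half-open convention) and
#' returns one row per site. Continuous layers come back numeric;
#' categorical layers come back as factors of their integer category codes.
#'
#' @param stack a [GridStack-class]
#' @param sites data.frame with columns `easting`, `northing`
#' @return data.frame, one column per layer
#' @export
extractSiteCovariates <- function(stack, sites) {
  stopifnot(all(c("easting", "northing") %in% names(sites)))
  idx <- cellIndex(sites$easting, sites$northing, cellSize(stack),
                   gridOrigin(stack), gridDim(stack))
  if (anyNA(idx)) {
    bad <- which(is.na(idx[, 1L]))[1L]
    stop("site ", bad, " at (", sites$easting[bad], ", ",
         sites$northing[bad], ") lies outside the grid extent")
  }
  out <- lapply(layerNames(stack), function(nm) {
    v <- getLayer(stack, nm)[idx]
    if (layerKind(stack)[[nm]] == "categorical")
      factor(as.integer(v), levels = sort(unique(as.integer(getLayer(stack, nm)))))
    else v
  })
  names(out) <- layerNames(stack)
  as.data.frame(out, optional = TRUE)
}

#' Aggregate covariates over a 2 x 2 km tetrad
#'
#' Tetrads are 2 x 2 blocks of 1-km cells. Continuous layers are averaged
#' over the four member cells; categorical layers take the modal category
#' (smallest code on ties).
#'
#' @param stack a [GridStack-class] of 1-km layers
#' @param tetrads two-column matrix of tetrad block indices (tx, ty), 1-based
#' @return data.frame, one row per tetrad
#' @export
tetradCovariates <- function(stack, tetrads) {
  d <- gridDim(stack)
  kinds <- layerKind(stack)
  out <- vector("list", nLayers(stack))
  names(out) <- layerNames(stack)
  ix0 <- (tetrads[, 1L] - 1L) * 2L
  iy0 <- (tetrads[, 2L] - 1L) * 2L
  stopifnot(all(ix0 + 2L <= d[1]), all(iy0 + 2L <= d[2]))
  for (nm in layerNames(stack)) {
    lay <- getLayer(stack, nm)
    vals <- cbind(lay[cbind(ix0 + 1L, iy0 + 1L)],
                  lay[cbind(ix0 + 2L, iy0 + 1L)],
                  lay[cbind(ix0 + 1L, iy0 + 2L)],
                  lay[cbind(ix0 + 2L, iy0 + 2L)])
    if (kinds[[nm]] == "categorical") {
      mode1 <- apply(vals, 1L, function(v) {
        tb <- table(v)
        as.integer(names(tb)[which.max(tb)])
      })
      out[[nm]] <- factor(mode1,
        levels = sort(unique(as.integer(lay))))
    } else out[[nm]] <- rowMeans(vals)
  }
  as.data.frame(out, optional = TRUE)
}

## ---- plain-text raster I/O -------------------------------------------------

#' Write a matrix as an ESRI ASCII grid
#'
#' Plain-text raster interchange: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of values
#' from the top row (max y) down, as GIS tools expect.
#'
#' @param values matrix `[x, y]` with y increasing upward
#' @param path output file
#' @param cellsize,origin grid geometry
#' @param nodata value standing in for `NA`
#' @export
writeAsciiGrid <- function(values, path, cellsize = 1000, origin = c(0, 0),
                           nodata = -9999) {
  nx <- nrow(values); ny <- ncol(values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", nx), paste("nrows", ny),
    paste("xllcorner", format(origin[1], scientific = FALSE)),
    paste("yllcorner", format(origin[2], scientific = FALSE)),
    paste("cellsize", format(cellsize, scientific = FALSE)),
    paste("NODATA_value", nodata)
  ), con)
  m <- values
  m[is.na(m)] <- nodata
  for (iy in ny:1)
    writeLines(paste(sprintf("%.17g", m[, iy]), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [writeAsciiGrid()]
#'
#' @param path input file
#' @return list with elements `values` (matrix `[x, y]`), `cellsize`, `origin`
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1L))
  vals <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(vals) <- keys
  nx <- as.integer(vals[["ncols"]]); ny <- as.integer(vals[["nrows"]])
  body <- lapply(lines[7:(6 + ny)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
  m <- matrix(NA_real_, nx, ny)
  for (i in seq_len(ny)) m[, ny - i + 1L] <- body[[i]]
  m[m == vals[["nodata_value"]]] <- NA_real_
  list(values = m, cellsize = vals[["cellsize"]],
       origin = c(vals[["xllcorner"]], vals[["yllcorner"]]))
}

#' Write a GridStack as ASCII grids plus a CSV manifest
#'
#' One `.asc` file per layer and a `<prefix>_manifest.csv` recording layer
#' name, kind, priority and file, sufficient to rebuild the stack with
#' [readGridStack()].
#'
#' @param stack a [GridStack-class]
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return path of the manifest, invisibly
#' @export
writeGridStack <- function(stack, dir, prefix = "stack") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(nLayers(stack))
  for (i in seq_len(nLayers(stack))) {
    nm <- layerNames(stack)[i]
    files[i] <- file.path(dir, paste0(prefix, "_", nm, ".asc"))
    writeAsciiGrid(stack@layers[, , i], files[i],
                   cellsize = cellSize(stack), origin = gridOrigin(stack))
  }
  manifest <- data.frame(
    name = layerNames(stack), kind = stack@kind,
    priority = stack@priority, file = basename(files),
    stringsAsFactors = FALSE
  )
  mpath <- file.path(dir, paste0(prefix, "_manifest.csv"))
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Rebuild a GridStack from a manifest written by [writeGridStack()]
#'
#' @param manifestPath path to the manifest CSV
#' @return a [GridStack-class]
#' @export
readGridStack <- function(manifestPath) {
  manifest <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  dir <- dirname(manifestPath)
  grids <- lapply(file.path(dir, manifest$file), readAsciiGrid)
  layers <- lapply(grids, `[[`, "values")
  names(layers) <- manifest$name
  gridStack(layers, kind = manifest$kind, priority = manifest$priority,
            cellsize = grids[[1L]]$cellsize, origin = grids[[1L]]$origin)
}
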