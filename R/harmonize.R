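## Abundance-survey harmonization: converts the two heterogeneous survey
## dialects to a common unit — hectares covered by the species per square
## kilometre, numerically equal to percent cover of the 1-km cell — and
## derives the woodland-edge cover layer from a fine-scale woodland mask.

#' Rescale within-patch percent cover to whole-cell cover
#'
#' Patch-dialect surveys report a species' percent cover *within the
#' woodland patch*; whole-cell cover is that percentage times the fraction
#' of the 1-km cell that is woodland.
#'
#' @param patchPercent percent cover within the woodland patch, `[0, 100]`
#' @param woodlandFraction woodland fraction of the cell, `[0, 1]`
#' @return cover in ha/km^2 (= percent cover of the cell), clipped to
#'   `[0, 100]`
#' @examples
#' rescalePatchCover(40, 0.25) # 10
#' @export
rescalePatchCover <- function(patchPercent, woodlandFraction) {
  if (any(patchPercent < 0 | patchPercent > 100, na.rm = TRUE))
    stop("patchPercent must lie in [0, 100]")
  if (any(woodlandFraction < 0 | woodlandFraction > 1, na.rm = TRUE))
    stop("woodlandFraction must lie in [0, 1]")
  pmin(pmax(patchPercent * woodlandFraction, 0), 100)
}

#' Weight linear-feature and areal plot cover into whole-cell cover
#'
#' Plot-dialect surveys sample linear features (hedgerows etc.) separately
#' from the rest of the landscape; whole-cell cover is the mixture
#' `linear% x linear fraction + nonlinear% x (1 - linear fraction)`, a
#' convex combination of the two plot percentages.
#'
#' @param linearPercent percent cover in linear-feature plots, `[0, 100]`
#' @param linearFraction fraction of the cell covered by linear features,
#'   `[0, 1]`
#' @param nonlinearPercent percent cover in areal plots, `[0, 100]`
#' @return cover in ha/km^2, clipped to `[0, 100]`
#' @examples
#' weightLinearFeatures(50, 0.1, 10) # 5 + 9 = 14
#' @export
weightLinearFeatures <- function(linearPercent, linearFraction,
                                 nonlinearPercent) {
  if (any(linearPercent < 0 | linearPercent > 100, na.rm = TRUE) ||
      any(nonlinearPercent < 0 | nonlinearPercent > 100, na.rm = TRUE))
    stop("plot percentages must lie in [0, 100]")
  if (any(linearFraction < 0 | linearFraction > 1, na.rm = TRUE))
    stop("linearFraction must lie in [0, 1]")
  pmin(pmax(linearPercent * linearFraction +
              nonlinearPercent * (1 - linearFraction), 0), 100)
}

#' Merge the two abundance dialects into harmonized records
#'
#' Converts each raw record by its dialect's formula, looking the required
#' layer value up at the record's cell; records in cells lacking the layer
#' value (`NA`) are dropped and counted. Duplicate records per
#' (species, cell) are retained as separate rows.
#'
#' @param patch patch-dialect records: species, cell_x, cell_y,
#'   patch_percent
#' @param plot plot-dialect records: species, cell_x, cell_y,
#'   linear_percent, nonlinear_percent
#' @param woodlandFractionLayer matrix of per-cell woodland fractions
#' @param linearFractionLayer matrix of per-cell linear-feature fractions
#' @return data.frame (species, cell_x, cell_y, cover, source) with
#'   attribute `dropped` (count); source is `"patch_source"` or
#'   `"plot_source"`
#' @export
mergeSources <- function(patch, plot, woodlandFractionLayer,
                         linearFractionLayer) {
  dropped <- 0L
  out <- list()
  if (nrow(patch)) {
    w <- woodlandFractionLayer[cbind(patch$cell_x, patch$cell_y)]
    ok <- !is.na(w)
    dropped <- dropped + sum(!ok)
    out$patch <- data.frame(
      species = patch$species[ok],
      cell_x = patch$cell_x[ok], cell_y = patch$cell_y[ok],
      cover = rescalePatchCover(patch$patch_percent[ok], w[ok]),
      source = "patch_source", stringsAsFactors = FALSE)
  }
  if (nrow(plot)) {
    l <- linearFractionLayer[cbind(plot$cell_x, plot$cell_y)]
    ok <- !is.na(l)
    dropped <- dropped + sum(!ok)
    out$plot <- data.frame(
      species = plot$species[ok],
      cell_x = plot$cell_x[ok], cell_y = plot$cell_y[ok],
      cover = weightLinearFeatures(plot$linear_percent[ok], l[ok],
                                   plot$nonlinear_percent[ok]),
      source = "plot_source", stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(species = character(), cell_x = integer(),
               cell_y = integer(), cover = numeric(), source = character())
  rownames(res) <- NULL
  if (dropped > 0)
    warning(dropped, " record(s) dropped for missing layer values")
  attr(res, "dropped") <- dropped
  res
}

#' Woodland-edge cover fraction per 1-km cell
#'
#' Edge is any woodland within `distance` metres of nonwoodland, measured
#' centre-to-centre on the fine grid (Euclidean). Fine edge cells are
#' aggregated to the fraction of each coarse cell that is edge. An
#' all-woodland mask has no nonwoodland so no edge; an all-nonwoodland mask
#' has no woodland: both give zero everywhere.
#'
#' @param mask fine-resolution binary matrix (1 = woodland)
#' @param distance edge distance in metres (default 50)
#' @param fineCellsize fine cell edge length in metres (default 10; must
#'   not exceed `distance`)
#' @param outCellsize coarse cell edge length in metres (default 1000;
#'   `outCellsize / fineCellsize` must be an integer dividing the mask
#'   dimensions)
#' @return matrix of edge fractions in `[0, 1]` on the coarse grid
#' @export
computeEdgeCover <- function(mask, distance = 50, fineCellsize = 10,
                             outCellsize = 1000) {
  if (fineCellsize > distance)
    stop("fine grid resolution must not exceed the edge distance")
  f <- outCellsize / fineCellsize
  if (abs(f - round(f)) > 1e-9)
    stop("outCellsize must be an integer multiple of fineCellsize")
  f <- as.integer(round(f))
  nx <- nrow(mask); ny <- ncol(mask)
  if (nx %% f != 0 || ny %% f != 0)
    stop("mask dimensions must be divisible by the aggregation factor")
  wood <- mask == 1
  nonwood <- !wood
  r <- floor(distance / fineCellsize)
  ## a woodland cell is edge iff any nonwoodland cell lies within `distance`:
  ## dilate the nonwoodland mask by the disc of radius `distance` via
  ## explicit integer offsets, then intersect with woodland
  nearNon <- matrix(FALSE, nx, ny)
  for (dx in -r:r) for (dy in -r:r) {
    if ((dx^2 + dy^2) * fineCellsize^2 > distance^2) next
    if (dx == 0 && dy == 0) next
    sx <- max(1, 1 + dx):min(nx, nx + dx)
    tx <- max(1, 1 - dx):min(nx, nx - dx)
    sy <- max(1, 1 + dy):min(ny, ny + dy)
    ty <- max(1, 1 - dy):min(ny, ny - dy)
    nearNon[tx, ty] <- nearNon[tx, ty] | nonwood[sx, sy]
  }
  edge <- wood & nearNon
  ncx <- nx %/% f; ncy <- ny %/% f
  out <- matrix(0, ncx, ncy)
  for (dx in seq_len(f)) for (dy in seq_len(f))
    out <- out + edge[seq(dx, by = f, length.out = ncx),
                      seq(dy, by = f, length.out = ncy)]
  out / f^2
}
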