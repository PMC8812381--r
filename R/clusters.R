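#' Threshold a t-map and extract supra-threshold clusters
#'
#' Voxels exceeding the threshold (positively or negatively, per `sign`) are
#' grouped into connected components on the 3-D grid (26-neighbour vertex
#' connectivity by default, 6-neighbour face connectivity optionally); only
#' components with strictly more than `minSize` voxels are kept and labelled
#' 1, 2, ... in decreasing size order.
#'
#' @param tMap a [GroupWeightStats-class], or a numeric t vector if
#'   `gridDim` is supplied.
#' @param tThresh threshold (non-negative); applied as `t > tThresh` for the
#'   positive sign and `t < -tThresh` for the negative sign.
#' @param minSize minimum cluster extent, strictly exceeded.
#' @param sign `"positive"` or `"negative"`.
#' @param connectivity 26 (vertex) or 6 (face).
#' @param gridDim grid dimensions when `tMap` is a plain vector.
#' @return list with `labels` (integer per voxel, 0 = no cluster) and
#'   `sizes` (voxel count per retained cluster).
#' @export
thresholdClusters <- function(tMap, tThresh = 1.7, minSize = 200L,
                              sign = c("positive", "negative"),
                              connectivity = 26L, gridDim = NULL) {
  sign <- match.arg(sign)
  if (tThresh < 0) stop("tThresh must be non-negative")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  if (is(tMap, "GroupWeightStats")) {
    t <- tMap@tValues
    gridDim <- tMap@gridDim
  } else {
    t <- as.numeric(tMap)
    if (is.null(gridDim)) stop("gridDim is required for a plain t vector")
    gridDim <- as.integer(gridDim)
  }
  if (prod(gridDim) != length(t))
    stop("gridDim does not match the map length")
  supra <- if (sign == "positive") t > tThresh else t < -tThresh
  supra[is.na(supra)] <- FALSE

  labels <- integer(length(t))
  if (!any(supra))
    return(list(labels = labels, sizes = integer(0)))

  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  if (connectivity == 6L)
    off <- off[abs(off$dx) + abs(off$dy) + abs(off$dz) == 1, ]
  coords <- arrayInd(seq_along(t), gridDim)

  comp <- integer(length(t))
  nComp <- 0L
  for (v in which(supra)) {
    if (comp[v] != 0L) next
    nComp <- nComp + 1L
    queue <- v
    comp[v] <- nComp
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      cc <- coords[cur, ]
      nx <- cc[1] + off$dx
      ny <- cc[2] + off$dy
      nz <- cc[3] + off$dz
      ok <- nx >= 1 & nx <= gridDim[1] & ny >= 1 & ny <= gridDim[2] &
        nz >= 1 & nz <= gridDim[3]
      nb <- nx[ok] + (ny[ok] - 1L) * gridDim[1] +
        (nz[ok] - 1L) * gridDim[1] * gridDim[2]
      nb <- nb[supra[nb] & comp[nb] == 0L]
      comp[nb] <- nComp
      queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(comp, nComp)
  keep <- which(sizes > minSize)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  for (i in seq_along(keep)) labels[comp == keep[i]] <- i
  list(labels = labels, sizes = as.integer(sizes[keep]))
}
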