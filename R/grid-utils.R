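# Grid primitives shared by the spatial modules. Grids are plain R matrices;
# cells are addressed (row, col) with row 1 at the top.

neighbor_offsets <- function(connectivity) {
  if (connectivity == 4) {
    list(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else if (connectivity == 8) {
    list(dr = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
         dc = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
  } else stop("connectivity must be 4 or 8")
}

# Dual rule for the background, avoiding topological paradoxes.
dual_connectivity <- function(connectivity) {
  if (connectivity == 8) 4L else 8L
}

# One binary dilation step of a logical matrix (no wrap-around).
mask_shift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

mask_dilate <- function(m, connectivity) {
  off <- neighbor_offsets(connectivity)
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (k in seq_along(off$dr)) {
    out <- out | mask_shift(m, off$dr[k], off$dc[k])
  }
  out
}

#' Label connected components of a mask
#'
#' Maximal connected components of the `TRUE` cells under 4- or 8-neighbor
#' adjacency. Components are numbered 1..k in raster-scan order (the
#' component whose first cell appears earliest, scanning row by row from the
#' top-left, gets label 1), which makes labeling deterministic.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return List with `labels` (integer matrix, 0 outside the mask) and
#'   `n` (component count).
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)  # column-major linear indices
  labels <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(list(labels = labels, n = 0L))
  off <- neighbor_offsets(connectivity)
  # edges between in-mask neighbors (each undirected edge gathered once by
  # using only "forward" offsets)
  fwd <- which(off$dr > 0L | (off$dr == 0L & off$dc > 0L))
  from <- integer(0); to <- integer(0)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  for (k in fwd) {
    r2 <- r + off$dr[k]; c2 <- c + off$dc[k]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- mask[j]
    from <- c(from, idx[ok][keep])
    to <- c(to, j[keep])
  }
  vid <- match(seq_len(nr * nc), idx)  # map linear index -> vertex id
  g <- igraph::make_graph(as.vector(rbind(vid[from], vid[to])),
                          n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  # deterministic relabel in raster-scan (row-major) order
  scan_order <- order(r, c)
  first_seen <- !duplicated(comp[scan_order])
  relab <- integer(max(comp))
  relab[comp[scan_order][first_seen]] <- seq_len(sum(first_seen))
  labels[idx] <- relab[comp]
  list(labels = labels, n = max(relab))
}

# Geodesic step counts from each of a set of core components (contracted
# to single vertices) to every cell of a link region, moving through the
# region's cells under the given connectivity. 'idxL' holds the region's
# linear cell indices, 'rows' the (cell, core) adjacency table, 'cores_k'
# the core ids. Returns a length(cores_k) x length(idxL) matrix of step
# counts (a seed cell adjacent to a core is at distance 1), Inf where
# unreachable.
region_core_distances <- function(idxL, rows, cores_k, nr, nc, conn) {
  n <- length(idxL)
  vid <- integer(nr * nc)
  vid[idxL] <- seq_len(n)
  off <- neighbor_offsets(conn)
  r <- ((idxL - 1L) %% nr) + 1L
  c <- ((idxL - 1L) %/% nr) + 1L
  fwd <- which(off$dr > 0L | (off$dr == 0L & off$dc > 0L))
  from <- integer(0); to <- integer(0)
  for (k in fwd) {
    r2 <- r + off$dr[k]; c2 <- c + off$dc[k]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- vid[j] > 0L
    from <- c(from, vid[idxL[ok][keep]])
    to <- c(to, vid[j[keep]])
  }
  # Core-to-seed edges carry a large weight so that no geodesic can cut
  # through another contracted core vertex (paths must stay inside the
  # region); the offset is removed afterwards, leaving seed cells at
  # distance 1.
  W <- n + 2
  g <- igraph::make_graph(
    as.vector(rbind(c(from, n + match(rows$core, cores_k)),
                    c(to, vid[rows$cell]))),
    n = n + length(cores_k), directed = FALSE
  )
  wts <- c(rep(1, length(from)), rep(W, nrow(rows)))
  d <- igraph::distances(g, v = n + seq_along(cores_k), to = seq_len(n),
                         weights = wts)
  d - (W - 1)
}

#' Euclidean distance to the background
#'
#' Per-cell Euclidean distance (cell units, center to center) to the nearest
#' background cell, where the region outside the map also counts as
#' background. Background cells have distance 0. A landscape with no
#' background cell inside the map still has finite distances because of the
#' virtual background ring outside the border.
#'
#' @param landscape A [binary_landscape()] or logical foreground matrix.
#' @return Numeric matrix of distances.
#' @export
distance_to_background <- function(landscape) {
  fg <- if (inherits(landscape, "binary_landscape")) landscape$grid else landscape
  stopifnot(is.matrix(fg), is.logical(fg))
  # pad with one background ring so the exterior acts as background; the
  # nearest exterior cell is always within the first ring
  pad <- matrix(FALSE, nrow(fg) + 2L, ncol(fg) + 2L)
  pad[2:(nrow(fg) + 1L), 2:(ncol(fg) + 1L)] <- fg
  dm <- EBImage::distmap(pad * 1, metric = "euclidean")
  unclass(dm)[2:(nrow(fg) + 1L), 2:(ncol(fg) + 1L), drop = FALSE]
}

# Euclidean distance to the nearest TRUE cell of 'target' (Inf if none).
distance_to_mask <- function(target) {
  if (!any(target)) {
    return(matrix(Inf, nrow(target), ncol(target)))
  }
  unclass(EBImage::distmap((!target) * 1, metric = "euclidean"))
}

#' Find background holes
#'
#' A hole is a background connected component (under the dual of the
#' foreground connectivity) that does not touch the map border; such
#' background is fully enclosed by foreground.
#'
#' @param landscape A [binary_landscape()] or logical foreground matrix.
#' @param connectivity Foreground connectivity (4 or 8); the background is
#'   labeled with the dual rule.
#' @return List with `labels` (integer matrix, holes numbered 1..k, 0
#'   elsewhere) and `n` (hole count).
#' @export
find_holes <- function(landscape, connectivity = 8) {
  fg <- if (inherits(landscape, "binary_landscape")) landscape$grid else landscape
  bgc <- dual_connectivity(connectivity)
  lab <- label_components(!fg, bgc)
  if (lab$n == 0L) return(list(labels = lab$labels, n = 0L))
  nr <- nrow(fg); nc <- ncol(fg)
  border_labels <- unique(c(lab$labels[1, ], lab$labels[nr, ],
                            lab$labels[, 1], lab$labels[, nc]))
  border_labels <- setdiff(border_labels, 0L)
  hole_ids <- setdiff(seq_len(lab$n), border_labels)
  labels <- matrix(0L, nr, nc)
  for (i in seq_along(hole_ids)) {
    labels[lab$labels == hole_ids[i]] <- i
  }
  list(labels = labels, n = length(hole_ids))
}

# Count holes of an arbitrary cell set (logical matrix), using the given
# background connectivity, inside the set's padded bounding box (valid since
# the set lies entirely within the box and the pad ring joins everything
# that can reach the border).
count_holes_of_set <- function(set, bg_connectivity) {
  idx <- which(set, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0L)
  r1 <- min(idx[, 1]); r2 <- max(idx[, 1])
  c1 <- min(idx[, 2]); c2 <- max(idx[, 2])
  box <- matrix(FALSE, r2 - r1 + 3L, c2 - c1 + 3L)
  box[2:(r2 - r1 + 2L), 2:(c2 - c1 + 2L)] <- set[r1:r2, c1:c2, drop = FALSE]
  lab <- label_components(!box, bg_connectivity)
  nr <- nrow(box); nc <- ncol(box)
  border_labels <- setdiff(unique(c(lab$labels[1, ], lab$labels[nr, ],
                                    lab$labels[, 1], lab$labels[, nc])), 0L)
  lab$n - length(border_labels)
}
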