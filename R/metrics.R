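# Class-level landscape pattern indices (patch density, normalized
# landscape shape index, cohesion, effective mesh size) and the
# landscape-level contagion index. Areas are kept in cell units internally
# and converted at the reporting boundary (ha for MESH, per-100-ha for PD).

#' Delineate foreground patches
#'
#' Labels foreground connected components and tallies per-patch area (cells)
#' and perimeter (cell edges adjoining background or the map border; the
#' landscape boundary counts toward the perimeter).
#'
#' @param landscape A [binary_landscape()].
#' @param connectivity Patch rule, 4 or 8 (default 8, matching the MSPA
#'   connectivity).
#' @return A `patch_set`: `patches` (data.frame with `id`, `area_cells`,
#'   `perimeter_edges`), `n`, `Z` (total landscape cells), `A_ha`
#'   (landscape area, hectares), `cell_area` (ha/cell) and `cell_size` (m).
#' @export
delineate_patches <- function(landscape, connectivity = 8) {
  stopifnot(inherits(landscape, "binary_landscape"))
  fg <- landscape$grid
  lab <- label_components(fg, connectivity)
  edges <- perimeter_edge_count(fg)
  if (lab$n > 0L) {
    area <- tabulate(lab$labels[fg], nbins = lab$n)
    perim <- integer(lab$n)
    for (k in seq_len(lab$n)) perim[k] <- 0L
    # per-patch perimeter: count the 4-neighbor bg/border edges of each cell
    perim <- as.integer(rowsum(as.numeric(edges[fg]), lab$labels[fg])[, 1])
    patches <- data.frame(id = seq_len(lab$n), area_cells = area,
                          perimeter_edges = perim)
  } else {
    patches <- data.frame(id = integer(0), area_cells = integer(0),
                          perimeter_edges = integer(0))
  }
  structure(
    list(patches = patches, n = lab$n,
         labels = lab$labels,
         Z = landscape$n_rows * landscape$n_cols,
         A_ha = landscape$n_rows * landscape$n_cols * landscape$cell_area,
         cell_area = landscape$cell_area,
         cell_size = landscape$cell_size,
         dims = c(landscape$n_rows, landscape$n_cols)),
    class = "patch_set"
  )
}

# Per-cell count of exposed 4-neighbor sides (background neighbor or map
# border), i.e. the cell's contribution to its patch perimeter.
perimeter_edge_count <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  exposed <- matrix(0L, nr, nc)
  off <- neighbor_offsets(4)
  for (k in seq_along(off$dr)) {
    nb_bg <- matrix(TRUE, nr, nc)  # outside the map counts as background
    dr <- off$dr[k]; dc <- off$dc[k]
    rs <- max(1L, 1L + dr):min(nr, nr + dr)
    cs <- max(1L, 1L + dc):min(nc, nc + dc)
    nb_bg[rs, cs] <- !fg[rs - dr, cs - dc]
    exposed <- exposed + (nb_bg & fg)
  }
  exposed
}

#' Patch density (PD)
#'
#' Number of patches per unit area; rises as the class fragments.
#'
#' @param ps A `patch_set` from [delineate_patches()].
#' @param per `"100ha"` (patches per 100 ha, the usual report unit) or
#'   `"km2"`.
#' @return Scalar density.
#' @export
patch_density <- function(ps, per = c("100ha", "km2")) {
  per <- match.arg(per)
  stopifnot(inherits(ps, "patch_set"), ps$A_ha > 0)
  if (per == "100ha") ps$n / ps$A_ha * 100 else ps$n / (ps$A_ha / 100)
}

# Minimum possible total edge for a class of 'a' cells arranged maximally
# compactly (integer-square construction): a near-square block of side
# n = floor(sqrt(a)) plus a partial row.
min_edge_for_area <- function(a) {
  n <- floor(sqrt(a))
  m <- a - n^2
  if (m == 0) 4 * n else if (m <= n) 4 * n + 2 else 4 * n + 4
}

# Maximum possible total edge for 'a' cells on an R x C landscape, border
# included: full dispersion (4 edges per cell) while the class fits a
# checkerboard; beyond that the background disperses instead.
max_edge_for_area <- function(a, dims) {
  Z <- dims[1] * dims[2]
  if (a <= ceiling(Z / 2)) {
    4 * a
  } else {
    4 * (Z - a) + 2 * (dims[1] + dims[2])
  }
}

#' Normalized landscape shape index (NLSI)
#'
#' Total class edge rescaled between the minimum (one maximally compact
#' block) and maximum (maximal dispersion) possible for the class area on
#' this landscape: `(e - e_min) / (e_max - e_min)`, clamped to `[0, 1]`.
#' When the class fills the landscape (`e_max == e_min`) the index is
#' defined as 0.
#'
#' @param ps A `patch_set`.
#' @return Scalar in `[0, 1]`.
#' @export
normalized_lsi <- function(ps) {
  stopifnot(inherits(ps, "patch_set"))
  a <- sum(ps$patches$area_cells)
  if (a == 0) stop("empty class: NLSI undefined")
  e <- sum(ps$patches$perimeter_edges)
  e_min <- min_edge_for_area(a)
  e_max <- max_edge_for_area(a, ps$dims)
  if (e_max <= e_min) return(0)
  min(1, max(0, (e - e_min) / (e_max - e_min)))
}

#' Patch cohesion index (COHESION)
#'
#' Perimeter-area measure of the physical connectedness of the class:
#' `[1 - sum(p_j) / sum(p_j sqrt(a_j))] * [1 - 1/sqrt(Z)]^-1 * 100`,
#' with `p_j`, `a_j` in cell units and `Z` the landscape cell count.
#' 0 when every patch is a single cell; 100 when one patch fills the
#' landscape.
#'
#' @param ps A `patch_set`.
#' @return Scalar in `[0, 100]`.
#' @export
cohesion <- function(ps) {
  stopifnot(inherits(ps, "patch_set"), ps$Z > 1, ps$n > 0)
  p <- ps$patches$perimeter_edges
  a <- ps$patches$area_cells
  val <- (1 - sum(p) / sum(p * sqrt(a))) / (1 - 1 / sqrt(ps$Z)) * 100
  max(0, val)
}

#' Effective mesh size (MESH)
#'
#' `sum(a_j^2) / A_total` in hectares: the expected area of the patch
#' containing a randomly chosen cell; decreases under fragmentation and
#' equals the landscape area when one patch covers everything.
#'
#' @param ps A `patch_set`.
#' @return Scalar in hectares.
#' @export
effective_mesh <- function(ps) {
  stopifnot(inherits(ps, "patch_set"), ps$A_ha > 0)
  a_ha <- ps$patches$area_cells * ps$cell_area
  sum(a_ha^2) / ps$A_ha
}

#' Contagion index (CONTAG)
#'
#' Landscape-level aggregation index over all classes of a categorical
#' grid, from cell-class abundances and rook (4-neighbor) adjacencies with
#' double counting:
#' `CONTAG = [1 + sum_ik q_ik ln q_ik / (2 ln m)] * 100`, where
#' `q_ik = P_i * g_ik / sum_k g_ik`, `P_i` is the proportional abundance of
#' class `i` and `g_ik` the number of adjacencies between classes `i` and
#' `k`. 100 means maximal aggregation; a one-cell checkerboard of two
#' classes gives 0.
#'
#' @param grid Integer/factor matrix of class codes, or a
#'   [binary_landscape()] (treated as a 2-class grid).
#' @return Scalar percentage in `(0, 100]`.
#' @export
contagion <- function(grid) {
  if (inherits(grid, "binary_landscape")) grid <- grid$grid + 0L
  stopifnot(is.matrix(grid))
  classes <- sort(unique(as.vector(grid)))
  m <- length(classes)
  if (m < 2) stop("contagion requires at least 2 classes")
  code <- matrix(match(grid, classes), nrow(grid), ncol(grid))
  g <- matrix(0, m, m)
  # horizontal + vertical internal adjacencies, double-counted
  h1 <- code[, -ncol(code), drop = FALSE]; h2 <- code[, -1, drop = FALSE]
  v1 <- code[-nrow(code), , drop = FALSE]; v2 <- code[-1, , drop = FALSE]
  for (pair in list(cbind(as.vector(h1), as.vector(h2)),
                    cbind(as.vector(v1), as.vector(v2)))) {
    t1 <- table(factor(pair[, 1], levels = seq_len(m)),
                factor(pair[, 2], levels = seq_len(m)))
    g <- g + t1 + t(t1)
  }
  P <- tabulate(code, nbins = m) / length(code)
  q <- P * g / rowSums(g)
  terms <- q * log(q)
  terms[q == 0] <- 0
  (1 + sum(terms) / (2 * log(m))) * 100
}

#' All class-level indices in one report
#'
#' Convenience wrapper computing PD, NLSI, COHESION, MESH (on the
#' foreground class) and CONTAG (on the binary grid).
#'
#' @param landscape A [binary_landscape()].
#' @param connectivity Patch rule for the class-level indices.
#' @return data.frame with columns `index`, `value`, `units`.
#' @export
landscape_metrics <- function(landscape, connectivity = 8) {
  ps <- delineate_patches(landscape, connectivity)
  data.frame(
    index = c("PD", "NLSI", "COHESION", "MESH", "CONTAG"),
    value = c(patch_density(ps), normalized_lsi(ps), cohesion(ps),
              effective_mesh(ps), contagion(landscape)),
    units = c("patches/100ha", "dimensionless", "percent", "ha", "percent"),
    row.names = NULL
  )
}
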