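#' MSPA parameters
#'
#' Edge width and connectivity rule for morphological spatial pattern
#' analysis. The edge width `D` is a Euclidean distance in cell units
#' (`D = sqrt(a^2 + b^2)` for axis offsets `a`, `b`); at 30 m cells the
#' default `D = 4` corresponds to a 120 m edge zone. Foreground connectivity
#' `R` is 4 or 8; the background always uses the dual rule (8 implies
#' 4-connected background and vice versa), which avoids topological
#' paradoxes in hole detection.
#'
#' @param edge_width Positive edge width `D` in cell units.
#' @param connectivity Foreground connectivity, 4 or 8.
#' @param boundary_over_connector If `TRUE`, the boundary classes
#'   (perforation/edge) take precedence over the connector classes
#'   (bridge/loop) within the edge zone, so corridors shorter than `2 D`
#'   are absorbed into the boundary. Default `FALSE`: connectors are
#'   detected first, keeping short corridors visible.
#' @return List of class `mspa_params`.
#' @export
mspa_params <- function(edge_width = 4, connectivity = 8,
                        boundary_over_connector = FALSE) {
  if (!is.numeric(edge_width) || length(edge_width) != 1L || edge_width <= 0) {
    stop("'edge_width' must be a positive scalar")
  }
  if (!connectivity %in% c(4, 8)) stop("'connectivity' must be 4 or 8")
  structure(
    list(edge_width = edge_width,
         connectivity = as.integer(connectivity),
         background_connectivity = dual_connectivity(connectivity),
         boundary_over_connector = isTRUE(boundary_over_connector)),
    class = "mspa_params"
  )
}

new_mspa_map <- function(labels, params, cell_size) {
  cls <- mspa_classes()
  counts <- tabulate(labels, nbins = 8L)
  names(counts) <- cls
  cell_area <- cell_size^2 / 1e4
  structure(
    list(labels = labels, params = params, cell_size = cell_size,
         class_areas = data.frame(
           class = cls,
           cells = counts,
           hectares = counts * cell_area,
           row.names = NULL
         )),
    class = "mspa_map"
  )
}

#' @export
print.mspa_map <- function(x, ...) {
  cat(sprintf("<mspa_map> %d x %d cells", nrow(x$labels), ncol(x$labels)))
  if (!is.null(x$params)) {
    cat(sprintf(" (D = %g, R = %d)", x$params$edge_width,
                x$params$connectivity))
  }
  cat("\n")
  print(x$class_areas)
  invisible(x)
}

#' Extract core cells
#'
#' Core cells are foreground cells whose Euclidean distance to the
#' background strictly exceeds the edge width `D` (the map exterior counts
#' as background).
#'
#' @param landscape A [binary_landscape()].
#' @param params An [mspa_params()].
#' @return Logical matrix.
#' @export
extract_core <- function(landscape, params = mspa_params()) {
  fg <- landscape$grid
  fg & distance_to_background(fg) > params$edge_width
}

#' Segment a binary landscape into the seven MSPA classes
#'
#' Assigns every foreground cell exactly one of the seven morphological
#' classes, in this decision order:
#'
#' 1. **core** — Euclidean distance to background `> D` (strict);
#' 2. **islet** — the cell's foreground component contains no core;
#' 3. **bridge** — the cell lies on a minimal geodesic path (through
#'    non-core foreground, connectivity `R`) joining two *distinct* core
#'    components;
#' 4. **loop** — the cell belongs to a non-core link region that closes a
#'    cycle with its adjacent core (the region together with those cores
#'    encloses background that the cores alone do not), and lies beyond
#'    `D` of the core;
#' 5. **perforation** — within `D` of core, with the nearest background in
#'    a hole (enclosed background);
#' 6. **edge** — within `D` of core, facing outer (non-hole) background;
#' 7. **branch** — everything left.
#'
#' The seven classes partition the foreground exactly; no background cell
#' is ever labeled.
#'
#' @param landscape A [binary_landscape()].
#' @param edge_width,connectivity,boundary_over_connector Passed to
#'   [mspa_params()]; alternatively supply `params`.
#' @param params An [mspa_params()] object (overrides the scalars).
#' @return An `mspa_map`: `labels` (integer matrix indexing
#'   [mspa_classes()]), `params`, `cell_size`, and a `class_areas` table in
#'   cells and hectares.
#' @export
mspa_segment <- function(landscape, edge_width = 4, connectivity = 8,
                         boundary_over_connector = FALSE, params = NULL) {
  stopifnot(inherits(landscape, "binary_landscape"))
  if (is.null(params)) {
    params <- mspa_params(edge_width, connectivity, boundary_over_connector)
  }
  fg <- landscape$grid
  nr <- nrow(fg); nc <- ncol(fg)
  D <- params$edge_width
  conn <- params$connectivity
  bg_conn <- params$background_connectivity
  labels <- matrix(1L, nr, nc)  # background
  if (!any(fg)) return(new_mspa_map(labels, params, landscape$cell_size))

  dist_bg <- distance_to_background(fg)
  core <- fg & dist_bg > D

  comp <- label_components(fg, conn)
  with_core <- unique(comp$labels[core])
  islet <- fg & !(matrix(comp$labels %in% with_core, nr, nc))

  core_lab <- label_components(core, conn)
  dist_core <- distance_to_mask(core)
  hole_info <- find_holes(fg, conn)
  hole <- hole_info$labels > 0L

  bridge <- matrix(FALSE, nr, nc)
  loop <- matrix(FALSE, nr, nc)
  noncore <- fg & !core & !islet
  if (any(noncore) && core_lab$n > 0L) {
    reg <- label_components(noncore, conn)
    # region/core adjacency (+ per-pair seed cells) via neighbor shifts
    off <- neighbor_offsets(conn)
    adj <- vector("list", length(off$dr))
    for (k in seq_along(off$dr)) {
      shifted <- matrix(0L, nr, nc)
      dr <- off$dr[k]; dc <- off$dc[k]
      rs <- max(1L, 1L + dr):min(nr, nr + dr)
      cs <- max(1L, 1L + dc):min(nc, nc + dc)
      shifted[rs, cs] <- core_lab$labels[rs - dr, cs - dc]
      m <- reg$labels > 0L & shifted > 0L
      adj[[k]] <- data.frame(cell = which(m), region = reg$labels[m],
                             core = shifted[m])
    }
    adj <- unique(do.call(rbind, adj))
    for (k in unique(adj$region)) {
      rows <- adj[adj$region == k, , drop = FALSE]
      cores_k <- unique(rows$core)
      L <- reg$labels == k
      if (length(cores_k) >= 2L) {
        idxL <- which(L)
        dm <- region_core_distances(idxL, rows, cores_k, nr, nc, conn)
        allowed <- if (params$boundary_over_connector) {
          dist_core[idxL] > D
        } else TRUE
        mark <- logical(length(idxL))
        np <- length(cores_k)
        for (ai in seq_len(np - 1L)) for (bi in (ai + 1L):np) {
          s <- dm[ai, ] + dm[bi, ]
          if (all(is.infinite(s))) next
          mark <- mark | (s == min(s))
        }
        bridge[idxL[mark & allowed]] <- TRUE
      }
      K <- matrix(core_lab$labels %in% cores_k, nr, nc) & core
      if (count_holes_of_set(L | K, bg_conn) > count_holes_of_set(K, bg_conn)) {
        loop[L & dist_core > D] <- TRUE
      }
    }
    loop <- loop & !bridge
  }

  # boundary on what remains: perforation faces enclosed background, edge
  # faces the outside; ties go to edge
  remaining <- fg & !core & !islet & !bridge & !loop
  in_edge_zone <- remaining & dist_core <= D
  dist_hole <- distance_to_mask(hole)
  dist_outer <- distance_to_background(fg | hole)
  perforation <- in_edge_zone & dist_hole < dist_outer
  edge <- in_edge_zone & !perforation
  branch <- remaining & !in_edge_zone

  labels[core] <- 2L
  labels[islet] <- 3L
  labels[bridge] <- 4L
  labels[loop] <- 5L
  labels[perforation] <- 6L
  labels[edge] <- 7L
  labels[branch] <- 8L
  new_mspa_map(labels, params, landscape$cell_size)
}

#' Per-class proportions of an MSPA map
#'
#' @param map An `mspa_map`.
#' @param per `"foreground"` (fractions of the 7 classes over foreground
#'   cells, as class shares of total farmland are usually reported) or
#'   `"landscape"` (all 8 labels over all cells).
#' @return Named numeric vector summing to 1.
#' @export
class_proportions <- function(map, per = c("foreground", "landscape")) {
  per <- match.arg(per)
  stopifnot(inherits(map, "mspa_map"))
  counts <- map$class_areas$cells
  names(counts) <- map$class_areas$class
  if (per == "foreground") {
    fgc <- counts[-1]
    if (sum(fgc) == 0) stop("empty foreground: per-foreground proportions undefined")
    fgc / sum(fgc)
  } else {
    counts / sum(counts)
  }
}
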