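# Independent literal-definition oracles, written before the package
# implementations they check. Everything here is deliberately naive: stack
# flood fill, brute-force pairwise distances, queue BFS. No code is shared
# with R/.

# --- flood-fill component labeling -----------------------------------------

oracle_neighbors <- function(r, c, nr, nc, conn) {
  if (conn == 4) {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  } else {
    dr <- c(-1, 1, 0, 0, -1, -1, 1, 1); dc <- c(0, 0, -1, 1, -1, 1, -1, 1)
  }
  rs <- r + dr; cs <- c + dc
  ok <- rs >= 1 & rs <= nr & cs >= 1 & cs <= nc
  cbind(rs[ok], cs[ok])
}

oracle_label <- function(mask, conn) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nextlab <- 0L
  # row-major scan for deterministic numbering
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nextlab <- nextlab + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- nextlab
    while (length(stack) > 0L) {
      cell <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      nb <- oracle_neighbors(cell[1], cell[2], nr, nc, conn)
      for (i in seq_len(nrow(nb))) {
        rr <- nb[i, 1]; cc <- nb[i, 2]
        if (mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nextlab
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  list(labels = lab, n = nextlab)
}

# --- brute-force Euclidean distances ---------------------------------------

# Distance of every cell to the nearest background cell, where everything
# outside the map is also background (represented by a 1-cell virtual ring,
# which always contains the nearest outside cell).
oracle_dist_to_background <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  bg <- which(!fg, arr.ind = TRUE)
  ring <- rbind(
    cbind(0, 0:(nc + 1)), cbind(nr + 1, 0:(nc + 1)),
    cbind(1:nr, 0), cbind(1:nr, nc + 1)
  )
  pts <- rbind(bg, ring)
  d <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (fg[r, c]) {
      d[r, c] <- sqrt(min((pts[, 1] - r)^2 + (pts[, 2] - c)^2))
    }
  }
  d
}

# Distance of every cell to the nearest TRUE cell of 'target' (in-map only).
oracle_dist_to_mask <- function(target) {
  nr <- nrow(target); nc <- ncol(target)
  pts <- which(target, arr.ind = TRUE)
  d <- matrix(Inf, nr, nc)
  if (nrow(pts) == 0L) return(d)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    d[r, c] <- sqrt(min((pts[, 1] - r)^2 + (pts[, 2] - c)^2))
  }
  d
}

# --- queue BFS geodesic steps ----------------------------------------------

# Steps from seed cells (distance given in 'init') through 'allowed' cells.
oracle_bfs <- function(allowed, seeds_idx, conn) {
  nr <- nrow(allowed); nc <- ncol(allowed)
  dist <- matrix(NA_integer_, nr, nc)
  queue <- seeds_idx  # two-column matrix (row, col), all at distance 1
  for (i in seq_len(nrow(queue))) dist[queue[i, 1], queue[i, 2]] <- 1L
  head <- 1L
  queue <- as.list(as.data.frame(t(queue)))
  while (head <= length(queue)) {
    cell <- queue[[head]]; head <- head + 1L
    d0 <- dist[cell[1], cell[2]]
    nb <- oracle_neighbors(cell[1], cell[2], nr, nc, conn)
    for (i in seq_len(nrow(nb))) {
      rr <- nb[i, 1]; cc <- nb[i, 2]
      if (allowed[rr, cc] && is.na(dist[rr, cc])) {
        dist[rr, cc] <- d0 + 1L
        queue[[length(queue) + 1L]] <- c(rr, cc)
      }
    }
  }
  dist
}

# --- holes ------------------------------------------------------------------

# Number of bounded complement components of an arbitrary cell set.
oracle_count_holes <- function(set, bg_conn) {
  nr <- nrow(set); nc <- ncol(set)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- set
  lab <- oracle_label(!pad, bg_conn)
  border <- unique(c(lab$labels[1, ], lab$labels[nrow(pad), ],
                     lab$labels[, 1], lab$labels[, ncol(pad)]))
  lab$n - length(setdiff(border, 0L))
}

# Hole mask of a landscape: background components (dual connectivity) that
# do not touch the map border.
oracle_holes <- function(fg, conn) {
  bg_conn <- if (conn == 8) 4 else 8
  lab <- oracle_label(!fg, bg_conn)
  nr <- nrow(fg); nc <- ncol(fg)
  border <- setdiff(unique(c(lab$labels[1, ], lab$labels[nr, ],
                             lab$labels[, 1], lab$labels[, nc])), 0L)
  hole <- lab$labels > 0L
  for (b in border) hole[lab$labels == b] <- FALSE
  hole
}

# --- the literal seven-class classifier ------------------------------------

# Classifies every cell of a binary map by applying the class definitions
# directly, in the fixed decision order:
#   core > islet > bridge > loop > perforation > edge > branch.
# Returns an integer matrix indexing
# c("background","core","islet","bridge","loop","perforation","edge","branch").
oracle_mspa <- function(fg, D = 4, conn = 8) {
  nr <- nrow(fg); nc <- ncol(fg)
  out <- matrix(1L, nr, nc)  # background
  if (!any(fg)) return(out)

  dist_bg <- oracle_dist_to_background(fg)
  core <- fg & dist_bg > D

  comp <- oracle_label(fg, conn)
  core_comp <- oracle_label(core, conn)
  dist_core <- oracle_dist_to_mask(core)
  hole <- oracle_holes(fg, conn)

  # islet: foreground component containing no core cell
  islet <- matrix(FALSE, nr, nc)
  for (k in seq_len(comp$n)) {
    cells <- comp$labels == k
    if (!any(core[cells])) islet[cells] <- TRUE
  }

  # connector candidacy on non-core, non-islet foreground, per link region
  noncore <- fg & !core & !islet
  bridge <- matrix(FALSE, nr, nc)
  loop <- matrix(FALSE, nr, nc)
  region <- oracle_label(noncore, conn)
  bg_conn <- if (conn == 8) 4 else 8
  for (k in seq_len(region$n)) {
    L <- region$labels == k
    # adjacent core components
    adj <- integer(0)
    Lidx <- which(L, arr.ind = TRUE)
    for (i in seq_len(nrow(Lidx))) {
      nb <- oracle_neighbors(Lidx[i, 1], Lidx[i, 2], nr, nc, conn)
      for (j in seq_len(nrow(nb))) {
        lb <- core_comp$labels[nb[j, 1], nb[j, 2]]
        if (lb > 0L) adj <- union(adj, lb)
      }
    }
    if (length(adj) == 0L) next
    # bridge: cells on a minimal geodesic joining two distinct core comps
    if (length(adj) >= 2L) {
      dists <- list()
      for (a in adj) {
        seeds <- Lidx[apply(Lidx, 1, function(rc) {
          nb <- oracle_neighbors(rc[1], rc[2], nr, nc, conn)
          any(core_comp$labels[nb] == a)
        }), , drop = FALSE]
        dists[[as.character(a)]] <- oracle_bfs(L, seeds, conn)
      }
      for (a_i in seq_along(adj)) for (b_i in seq_along(adj)) {
        if (a_i >= b_i) next
        s <- dists[[as.character(adj[a_i])]] + dists[[as.character(adj[b_i])]]
        if (all(is.na(s) | !L)) next
        m <- min(s[L], na.rm = TRUE)
        if (is.finite(m)) bridge[!is.na(s) & s == m & L] <- TRUE
      }
    }
    # loop: region closes a cycle with its adjacent cores (new enclosed
    # background); loop cells are those beyond the edge width from core
    K <- matrix(FALSE, nr, nc)
    for (a in adj) K[core_comp$labels == a] <- TRUE
    if (oracle_count_holes(L | K, bg_conn) > oracle_count_holes(K, bg_conn)) {
      loop[L & dist_core > D] <- TRUE
    }
  }
  bridge <- bridge & !core
  loop <- loop & !bridge

  # boundary: within D of core; perforation faces a hole, edge the outside
  dist_hole <- oracle_dist_to_mask(hole)
  nonhole_bg <- !fg & !hole
  # distance to non-hole background including the virtual outside ring
  dist_out <- oracle_dist_to_background(fg | hole)  # holes removed from bg
  # for background cells oracle_dist_to_background returns 0 only where
  # !(fg|hole); recompute on the full grid footprint:
  perf <- matrix(FALSE, nr, nc)
  edge <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!fg[r, c] || core[r, c] || islet[r, c] || bridge[r, c] || loop[r, c]) next
    if (dist_core[r, c] <= D) {
      if (dist_hole[r, c] < dist_out[r, c]) perf[r, c] <- TRUE else edge[r, c] <- TRUE
    }
  }

  out[core] <- 2L
  out[islet] <- 3L
  out[bridge] <- 4L
  out[loop] <- 5L
  out[perf] <- 6L
  out[edge] <- 7L
  branch <- fg & out == 1L
  out[branch] <- 8L
  out
}

# --- patch tally oracle -----------------------------------------------------

# Independent per-patch area/perimeter tally: flood-fill components and
# explicit edge walking (an edge is counted when a 4-neighbor is background
# or lies outside the map).
oracle_patches <- function(fg, conn = 8) {
  lab <- oracle_label(fg, conn)
  nr <- nrow(fg); nc <- ncol(fg)
  if (lab$n == 0L) {
    return(data.frame(id = integer(0), area = integer(0), perim = integer(0)))
  }
  area <- integer(lab$n); perim <- integer(lab$n)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    k <- lab$labels[r, c]
    if (k == 0L) next
    area[k] <- area[k] + 1L
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      out <- rr < 1 || rr > nr || cc < 1 || cc > nc
      if (out || !fg[rr, cc]) perim[k] <- perim[k] + 1L
    }
  }
  data.frame(id = seq_len(lab$n), area = area, perim = perim)
}

# random binary map helper used across property tests
random_map <- function(nr, nc, p) matrix(stats::runif(nr * nc) < p, nr, nc)
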