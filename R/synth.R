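# Synthetic landscapes: a modified-random-clusters neutral model calibrated
# by foreground proportion and clustering, deterministic geometric fixtures
# with analytically known MSPA classes, and loss-edit change scenarios.

# Run code under a local RNG state seeded by 'seed'; the caller's state is
# untouched (single explicit generator state, no global randomness leaks).
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Generate a modified-random-clusters landscape
#'
#' Neutral landscape model with controlled composition (foreground
#' proportion `target_f`) and configuration (clustering `cluster_p`):
#' cells are marked by Bernoulli percolation at probability `cluster_p`,
#' marked clusters (4-neighbor rule) are assigned to the foreground in
#' random order until the foreground share of marked cells reaches
#' `target_f`, and the remaining cells take the majority class of their
#' already-assigned neighbors (ties broken by seeded coin flips). Larger
#' `cluster_p` yields more aggregated maps (higher contagion) at the same
#' composition; `cluster_p = 0` degenerates to an independent random map.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param target_f Target foreground proportion, strictly in (0, 1). The
#'   realized proportion is stochastic; for grids of 256 x 256 and larger
#'   it is typically within 0.02 of the target.
#' @param cluster_p Cluster-growth probability in `[0, 1)`; keep below the
#'   4-neighbor percolation threshold (~0.593) for finite clusters.
#' @param seed Integer seed; identical parameters and seed give an
#'   identical landscape.
#' @param cell_size Cell side in meters.
#' @param coarse_factor Integer >= 1. When > 1, the cluster map is built on
#'   a lattice coarsened by this factor and each coarse cell is replicated
#'   as a `coarse_factor` x `coarse_factor` block. This produces the
#'   block-scale contiguity of real regional land-cover maps: the contagion
#'   index rises with the factor at fixed composition (about 47-48 at
#'   `target_f = 0.55`, `cluster_p = 0.55`, factor 16 on a 512 x 512 grid,
#'   the regime of strongly aggregated regional farmland maps).
#' @return A [binary_landscape()].
#' @export
generate_mrc <- function(n_rows, n_cols, target_f, cluster_p = 0.5, seed = 1,
                         cell_size = 30, coarse_factor = 1) {
  if (target_f <= 0 || target_f >= 1) stop("'target_f' must be in (0, 1)")
  if (cluster_p < 0 || cluster_p >= 1) stop("'cluster_p' must be in [0, 1)")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L)
  coarse_factor <- as.integer(coarse_factor)
  stopifnot(coarse_factor >= 1L)
  if (coarse_factor > 1L) {
    coarse <- generate_mrc(ceiling(n_rows / coarse_factor),
                           ceiling(n_cols / coarse_factor),
                           target_f, cluster_p, seed, cell_size,
                           coarse_factor = 1)
    big <- kronecker(coarse$grid * 1L,
                     matrix(1L, coarse_factor, coarse_factor)) > 0L
    big <- big[seq_len(n_rows), seq_len(n_cols), drop = FALSE]
    big <- with_seed(seed + 1L, adjust_composition(big, target_f))
    return(binary_landscape(big, cell_size))
  }
  n <- n_rows * n_cols
  need <- ceiling(1 / min(target_f, 1 - target_f))
  if (n < need) {
    stop("grid too small for target_f = ", target_f,
         ": need at least ", need, " cells")
  }
  with_seed(seed, {
    if (cluster_p == 0) {
      fg <- matrix(stats::runif(n) < target_f, n_rows, n_cols)
      return(binary_landscape(adjust_composition(fg, target_f), cell_size))
    }
    marked <- matrix(stats::runif(n) < cluster_p, n_rows, n_cols)
    if (!any(marked)) {
      fg <- matrix(stats::runif(n) < target_f, n_rows, n_cols)
      return(binary_landscape(adjust_composition(fg, target_f), cell_size))
    }
    lab <- label_components(marked, 4)
    sizes <- tabulate(lab$labels[marked], nbins = lab$n)
    ord <- sample.int(lab$n)
    csum <- cumsum(sizes[ord])
    total <- sum(sizes)
    k <- findInterval(target_f * total, csum) + 1L
    k <- min(k, lab$n)
    # dropping the last cluster may land closer to the target share
    if (k > 1L && abs(csum[k - 1L] / total - target_f) <
          abs(csum[k] / total - target_f)) {
      k <- k - 1L
    }
    fg_clusters <- ord[seq_len(k)]
    cls <- matrix(0L, n_rows, n_cols)  # 0 unknown, 1 background, 2 foreground
    cls[marked] <- ifelse(lab$labels[marked] %in% fg_clusters, 2L, 1L)
    # fill unmarked cells from the neighborhood majority, ring by ring
    while (any(cls == 0L)) {
      fgn <- neighbor_count(cls == 2L)
      bgn <- neighbor_count(cls == 1L)
      front <- cls == 0L & (fgn + bgn) > 0L
      if (!any(front)) break
      take_fg <- front & fgn > bgn
      take_bg <- front & bgn > fgn
      tie <- front & fgn == bgn
      if (any(tie)) {
        coin <- matrix(FALSE, n_rows, n_cols)
        coin[tie] <- stats::runif(sum(tie)) < 0.5
        take_fg <- take_fg | (tie & coin)
        take_bg <- take_bg | (tie & !coin)
      }
      cls[take_fg] <- 2L
      cls[take_bg] <- 1L
    }
    binary_landscape(adjust_composition(cls == 2L, target_f), cell_size)
  })
}

# Nudge the realized composition to the target cell count by removing
# random boundary foreground cells (excess) or converting random
# foreground-adjacent background cells (deficit); configuration changes
# stay confined to patch boundaries.
adjust_composition <- function(fg, target_f) {
  n <- length(fg)
  want <- round(target_f * n)
  guard <- 0L
  while (sum(fg) != want && guard < 1000L) {
    guard <- guard + 1L
    delta <- sum(fg) - want
    if (delta > 0L) {
      cand <- which(fg & mask_dilate(!fg, 4))
      if (length(cand) == 0L) cand <- which(fg)
      drop <- cand[sample.int(length(cand), min(delta, length(cand)))]
      fg[drop] <- FALSE
    } else {
      cand <- which(!fg & mask_dilate(fg, 4))
      if (length(cand) == 0L) cand <- which(!fg)
      add <- cand[sample.int(length(cand), min(-delta, length(cand)))]
      fg[add] <- TRUE
    }
  }
  fg
}

# number of 8-neighbors of each cell that are TRUE in m
neighbor_count <- function(m) {
  off <- neighbor_offsets(8)
  out <- matrix(0L, nrow(m), ncol(m))
  for (k in seq_along(off$dr)) {
    out <- out + mask_shift(m, off$dr[k], off$dc[k])
  }
  out
}

# ---------------------------------------------------------------------------
# geometric fixtures with analytically known classes

# Euclidean distance from every cell to a solid block of cells
# rows r1..r2, cols c1..c2 (0 inside the block).
block_dist <- function(nr, nc, r1, r2, c1, c2) {
  dr <- pmax(0, r1 - seq_len(nr), seq_len(nr) - r2)
  dc <- pmax(0, c1 - seq_len(nc), seq_len(nc) - c2)
  sqrt(outer(dr^2, dc^2, "+"))
}

# distance to the virtual background outside the map border
outside_dist <- function(nr, nc) {
  dr <- pmin(seq_len(nr), nr + 1 - seq_len(nr))
  dc <- pmin(seq_len(nc), nc + 1 - seq_len(nc))
  outer(dr, dc, pmin)
}

cheb_to_point <- function(nr, nc, r0, c0) {
  outer(abs(seq_len(nr) - r0), abs(seq_len(nc) - c0), pmax)
}

cheb_to_block <- function(nr, nc, r1, r2, c1, c2) {
  dr <- pmax(0, r1 - seq_len(nr), seq_len(nr) - r2)
  dc <- pmax(0, c1 - seq_len(nc), seq_len(nc) - c2)
  outer(dr, dc, pmax)
}

cls_id <- function(name) match(name, mspa_classes())

#' Deterministic geometric fixtures with known MSPA classes
#'
#' Builds small binary landscapes whose class map follows in closed form
#' from the class definitions, for validating the segmentation:
#'
#' * `solid_square` — one filled square; interior core, edge band, branch
#'   corners (corner cells are farther than `D` from core by Euclidean
#'   distance even though geodesically attached).
#' * `scatter` — isolated single cells; all islet.
#' * `ring` — a one-cell-wide closed ring; a single coreless component,
#'   all islet.
#' * `donut` — a thick square annulus; core ring, perforation along the
#'   enclosed hole, edge along the outside, branch corners.
#' * `dumbbell` — two squares joined by a one-cell corridor longer than
#'   `2 D`; the corridor and its geodesic continuations into the squares
#'   are bridge.
#' * `two_cores_with_branch` — the dumbbell plus a stub attached to one
#'   square; stub cells beyond `D` of core are branch.
#' * `core_with_handle` — a square with a one-cell-wide handle leaving and
#'   re-entering it, enclosing new background; handle cells beyond `D` are
#'   loop, hole-facing cells perforation.
#'
#' @param name Fixture name.
#' @param size Principal size (side of the square / ring / scatter field /
#'   donut); fixtures with compound geometry take their own defaults.
#' @param edge_width Edge width `D` used for the expected labels.
#' @param cell_size Cell side in meters.
#' @return List with `landscape` (a [binary_landscape()]) and `expected`
#'   (integer label matrix indexing [mspa_classes()]).
#' @export
generate_fixture <- function(name = c("solid_square", "scatter", "ring",
                                      "donut", "dumbbell",
                                      "two_cores_with_branch",
                                      "core_with_handle"),
                             size = NULL, edge_width = 4, cell_size = 30) {
  name <- match.arg(name)
  D <- edge_width
  out <- switch(
    name,
    solid_square = fixture_solid_square(if (is.null(size)) 11 else size, D),
    scatter = fixture_scatter(if (is.null(size)) 15 else size),
    ring = fixture_ring(if (is.null(size)) 15 else size),
    donut = fixture_donut(if (is.null(size)) 32 else size, D),
    dumbbell = fixture_dumbbell(if (is.null(size)) 13 else size, D, stub = 0),
    two_cores_with_branch =
      fixture_dumbbell(if (is.null(size)) 13 else size, D, stub = 6),
    core_with_handle = fixture_handle(if (is.null(size)) 13 else size, D)
  )
  list(landscape = binary_landscape(out$fg, cell_size),
       expected = out$expected, name = name, edge_width = D)
}

fixture_solid_square <- function(S, D) {
  if (S < 2 * D + 3) stop("solid_square needs size >= ", 2 * D + 3)
  fg <- matrix(TRUE, S, S)
  out <- outside_dist(S, S)
  core <- out > D
  dcore <- block_dist(S, S, D + 1, S - D, D + 1, S - D)
  expected <- matrix(cls_id("branch"), S, S)
  expected[dcore <= D] <- cls_id("edge")
  expected[core] <- cls_id("core")
  list(fg = fg, expected = expected)
}

fixture_scatter <- function(S, spacing = 3) {
  fg <- matrix(FALSE, S, S)
  pos <- seq(2, S - 1, by = spacing)
  fg[pos, pos] <- TRUE
  expected <- matrix(cls_id("background"), S, S)
  expected[fg] <- cls_id("islet")
  list(fg = fg, expected = expected)
}

fixture_ring <- function(S) {
  if (S < 7) stop("ring needs size >= 7")
  fg <- matrix(FALSE, S, S)
  fg[3, 3:(S - 2)] <- TRUE
  fg[S - 2, 3:(S - 2)] <- TRUE
  fg[3:(S - 2), 3] <- TRUE
  fg[3:(S - 2), S - 2] <- TRUE
  expected <- matrix(cls_id("background"), S, S)
  expected[fg] <- cls_id("islet")  # one component, no core
  list(fg = fg, expected = expected)
}

fixture_donut <- function(S, D) {
  hole_side <- S - 2 * (2 * D + 3)
  if (hole_side < 2) stop("donut needs size >= ", 2 * (2 * D + 3) + 2)
  h1 <- (S - hole_side) %/% 2 + 1L
  h2 <- h1 + hole_side - 1L
  fg <- matrix(TRUE, S, S)
  fg[h1:h2, h1:h2] <- FALSE
  out <- outside_dist(S, S)
  hd <- block_dist(S, S, h1, h2, h1, h2)
  core <- fg & out > D & hd > D
  rim <- block_dist(S, S, D + 1, S - D, D + 1, S - D)
  expected <- matrix(cls_id("background"), S, S)
  expected[fg] <- cls_id("branch")
  expected[fg & !core & out <= D & rim <= D] <- cls_id("edge")
  expected[fg & !core & hd <= D] <- cls_id("perforation")
  expected[core] <- cls_id("core")
  list(fg = fg, expected = expected)
}

# One-cell bulge of the core toward a 1-wide appendage attached at
# (row y0, leaving the square across column s): the appendage removes the
# straight-ahead background, so cells on its axis just outside the core
# block can exceed distance D from the remaining background. Returns the
# bulge coordinate offsets along the axis, possibly empty.
bulge_cols <- function(s, D) {
  cand <- seq.int(s - D + 1, s)
  keep <- (s + 1 - cand)^2 + 1 > D^2
  cand[keep]
}

fixture_dumbbell <- function(s, D, stub = 0) {
  if (s %% 2 == 0 || s < 2 * D + 5) {
    stop("dumbbell needs odd size >= ", 2 * D + 5)
  }
  corridor <- 2 * D + 4
  nr <- s + stub
  nc <- 2 * s + corridor
  y0 <- (s + 1) %/% 2
  x0 <- y0  # stub column (below square A), far from the corridor row
  fg <- matrix(FALSE, nr, nc)
  fg[1:s, 1:s] <- TRUE
  fg[1:s, (s + corridor + 1):nc] <- TRUE
  fg[y0, (s + 1):(s + corridor)] <- TRUE
  if (stub > 0) fg[(s + 1):(s + stub), x0] <- TRUE

  tipA <- bulge_cols(s, D)            # cols of core bulge toward the mouth
  tipB <- (2 * s + corridor + 1) - tipA
  bulge_r <- if (stub > 0) bulge_cols(s, D) else integer(0)  # rows, same math

  blockA <- c(D + 1, s - D, D + 1, s - D)
  blockB <- c(D + 1, s - D, s + corridor + D + 1, nc - D)
  core <- matrix(FALSE, nr, nc)
  core[blockA[1]:blockA[2], blockA[3]:blockA[4]] <- TRUE
  core[blockB[1]:blockB[2], blockB[3]:blockB[4]] <- TRUE
  for (tc in tipA) core[y0, tc] <- TRUE
  for (tc in tipB) core[y0, tc] <- TRUE
  for (br in bulge_r) core[br, x0] <- TRUE

  # Euclidean distance to core (closed form over the block/tip parts)
  dcore <- pmin(
    block_dist(nr, nc, blockA[1], blockA[2], blockA[3], blockA[4]),
    block_dist(nr, nc, blockB[1], blockB[2], blockB[3], blockB[4])
  )
  euclid_pt <- function(r0, c0) {
    sqrt(outer((seq_len(nr) - r0)^2, (seq_len(nc) - c0)^2, "+"))
  }
  for (tc in tipA) dcore <- pmin(dcore, euclid_pt(y0, tc))
  for (tc in tipB) dcore <- pmin(dcore, euclid_pt(y0, tc))
  for (br in bulge_r) dcore <- pmin(dcore, euclid_pt(br, x0))

  # geodesic (Chebyshev-step) distances for the bridge fan
  tA <- if (length(tipA)) max(tipA) else s - D
  tB <- (2 * s + corridor + 1) - tA
  D_AB <- tB - tA
  chebA <- pmin(cheb_to_block(nr, nc, blockA[1], blockA[2], blockA[3],
                              blockA[4]),
                if (length(tipA)) cheb_to_point(nr, nc, y0, max(tipA))
                else Inf)
  chebB <- pmin(cheb_to_block(nr, nc, blockB[1], blockB[2], blockB[3],
                              blockB[4]),
                if (length(tipB)) cheb_to_point(nr, nc, y0, min(tipB))
                else Inf)
  if (length(bulge_r)) {
    chebA <- pmin(chebA, cheb_to_point(nr, nc, max(bulge_r), x0))
  }
  mouthA <- cheb_to_point(nr, nc, y0, s + 1)
  mouthB <- cheb_to_point(nr, nc, y0, s + corridor)
  col_ix <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  in_sqA <- matrix(FALSE, nr, nc); in_sqA[1:s, 1:s] <- TRUE
  in_sqB <- matrix(FALSE, nr, nc); in_sqB[1:s, (s + corridor + 1):nc] <- TRUE
  in_cor <- matrix(FALSE, nr, nc); in_cor[y0, (s + 1):(s + corridor)] <- TRUE
  total <- matrix(Inf, nr, nc)
  total[in_sqA] <- chebA[in_sqA] + mouthA[in_sqA] + (tB - (s + 1))
  total[in_sqB] <- chebB[in_sqB] + mouthB[in_sqB] + ((s + corridor) - tA)
  total[in_cor] <- (col_ix[in_cor] - tA) + (tB - col_ix[in_cor])
  bridge <- fg & !core & total == D_AB

  expected <- matrix(cls_id("background"), nr, nc)
  expected[fg] <- cls_id("branch")
  expected[fg & !core & dcore <= D] <- cls_id("edge")
  expected[bridge] <- cls_id("bridge")
  expected[core] <- cls_id("core")
  list(fg = fg, expected = expected)
}

fixture_handle <- function(s, D, h = 5) {
  if (s %% 2 == 0 || s < 2 * D + 5) {
    stop("core_with_handle needs odd size >= ", 2 * D + 5)
  }
  rt <- 3L; rb <- s - 2L
  if (rt > D || rb < s - D + 1) stop("handle arms must flank the core rows")
  nr <- s; nc <- s + h
  fg <- matrix(FALSE, nr, nc)
  fg[1:s, 1:s] <- TRUE
  fg[rt, (s + 1):(s + h)] <- TRUE
  fg[rb, (s + 1):(s + h)] <- TRUE
  fg[(rt + 1):(rb - 1), s + h] <- TRUE

  core <- matrix(FALSE, nr, nc)
  core[(D + 1):(s - D), (D + 1):(s - D)] <- TRUE
  dcore <- block_dist(nr, nc, D + 1, s - D, D + 1, s - D)
  hd <- block_dist(nr, nc, rt + 1, rb - 1, s + 1, s + h - 1)
  # non-hole background: outside the map plus the two corner rectangles
  # beside the handle arms
  dnon <- pmin(outside_dist(nr, nc),
               block_dist(nr, nc, 1, rt - 1, s + 1, nc),
               block_dist(nr, nc, rb + 1, nr, s + 1, nc))

  expected <- matrix(cls_id("background"), nr, nc)
  expected[fg & dcore > D] <- cls_id("loop")
  inband <- fg & !core & dcore <= D
  expected[inband & hd < dnon] <- cls_id("perforation")
  expected[inband & hd >= dnon] <- cls_id("edge")
  expected[core] <- cls_id("core")
  list(fg = fg, expected = expected)
}

# ---------------------------------------------------------------------------
# change scenarios (loss edits only; foreground never grows)

#' Apply a sequence of loss edits to a landscape
#'
#' Each step removes foreground: `erode_edge` strips boundary cells with
#' the given probability, `punch_holes` removes random small disks until
#' the given fraction of foreground is gone, `remove_patches` deletes whole
#' patches with the given probability, `carve_corridors` cuts straight
#' one-cell background lines across the map. Foreground area is
#' non-increasing; the whole sequence is deterministic given `seed`.
#'
#' @param base A [binary_landscape()].
#' @param steps List of steps, each `list(op = , rate = )` with `op` one of
#'   `"erode_edge"`, `"punch_holes"`, `"remove_patches"`,
#'   `"carve_corridors"` and `rate` in `[0, 1]`.
#' @param seed Integer seed.
#' @return List of landscapes: the base followed by one landscape per step.
#' @export
apply_scenario <- function(base, steps = list(), seed = 1) {
  stopifnot(inherits(base, "binary_landscape"))
  for (st in steps) {
    if (!st$op %in% c("erode_edge", "punch_holes", "remove_patches",
                      "carve_corridors")) {
      stop("unknown edit op: ", st$op)
    }
    if (st$rate < 0 || st$rate > 1) stop("edit rate must be in [0, 1]")
  }
  out <- vector("list", length(steps) + 1L)
  out[[1]] <- base
  with_seed(seed, {
    cur <- base$grid
    for (i in seq_along(steps)) {
      cur <- apply_edit(cur, steps[[i]]$op, steps[[i]]$rate)
      out[[i + 1L]] <- binary_landscape(cur, base$cell_size)
    }
  })
  out
}

apply_edit <- function(fg, op, rate) {
  nr <- nrow(fg); nc <- ncol(fg)
  if (rate == 0) return(fg)
  if (op == "erode_edge") {
    boundary <- fg & mask_dilate(!fg, 8)
    # map border is background too
    brd <- matrix(FALSE, nr, nc)
    brd[c(1, nr), ] <- TRUE; brd[, c(1, nc)] <- TRUE
    boundary <- boundary | (fg & brd)
    hit <- which(boundary)
    drop <- hit[stats::runif(length(hit)) < rate]
    fg[drop] <- FALSE
  } else if (op == "punch_holes") {
    target <- rate * sum(fg)
    removed <- 0
    guard <- 0L
    while (removed < target && guard < 10000L) {
      guard <- guard + 1L
      r <- sample.int(nr, 1); c <- sample.int(nc, 1)
      if (!fg[r, c]) next
      rr <- max(1, r - 2):min(nr, r + 2)
      cc <- max(1, c - 2):min(nc, c + 2)
      disk <- fg[rr, cc]
      removed <- removed + sum(disk)
      fg[rr, cc] <- FALSE
    }
  } else if (op == "remove_patches") {
    lab <- label_components(fg, 8)
    if (lab$n > 0L) {
      kill <- which(stats::runif(lab$n) < rate)
      fg[lab$labels %in% kill] <- FALSE
    }
  } else if (op == "carve_corridors") {
    n_lines <- max(1L, round(rate * (nr + nc) / 8))
    for (k in seq_len(n_lines)) {
      if (stats::runif(1) < 0.5) fg[sample.int(nr, 1), ] <- FALSE
      else fg[, sample.int(nc, 1)] <- FALSE
    }
  }
  fg
}
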