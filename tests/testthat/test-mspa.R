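test_that("distance to background matches brute force, exterior included", {
  set.seed(101)
  for (i in 1:10) {
    fg <- random_map(sample(5:20, 1), sample(5:20, 1), runif(1, 0.3, 0.9))
    expect_equal(distance_to_background(fg), oracle_dist_to_background(fg))
  }
  # all-background map: zeros
  expect_true(all(distance_to_background(matrix(FALSE, 4, 4)) == 0))
  # single foreground cell in background: distance 1
  fg <- matrix(FALSE, 5, 5); fg[3, 3] <- TRUE
  expect_equal(distance_to_background(fg)[3, 3], 1)
  # 11x11 solid square: center cell is 6 rows from the nearest exterior cell
  sq <- matrix(TRUE, 11, 11)
  expect_equal(distance_to_background(sq)[6, 6], 6)
})

test_that("component labeling agrees with flood fill at both connectivities", {
  # diagonal pair: one 8-component, two 4-components
  d <- matrix(FALSE, 3, 3); d[1, 1] <- d[2, 2] <- TRUE
  expect_equal(label_components(d, 8)$n, 1L)
  expect_equal(label_components(d, 4)$n, 2L)
  expect_equal(label_components(matrix(FALSE, 3, 3), 8)$n, 0L)
  set.seed(202)
  for (i in 1:100) {
    m <- random_map(20, 20, runif(1, 0.2, 0.7))
    conn <- sample(c(4, 8), 1)
    got <- label_components(m, conn)
    want <- oracle_label(m, conn)
    expect_equal(got$n, want$n)
    expect_identical(got$labels, want$labels)  # raster-scan numbering too
  }
})

test_that("holes are enclosed background only, with dual connectivity", {
  fx <- generate_fixture("donut")
  h <- find_holes(fx$landscape)
  expect_equal(h$n, 1L)
  expect_identical(h$labels > 0, oracle_holes(fx$landscape$grid, 8))
  # solid square has no holes; border-touching background is no hole
  expect_equal(find_holes(matrix(TRUE, 5, 5))$n, 0L)
  strip <- matrix(TRUE, 5, 5); strip[3, 1:3] <- FALSE
  expect_equal(find_holes(strip)$n, 0L)
  # a diagonal ring encloses under R=8 (4-connected background) but its
  # diagonal gaps leak under R=4 (8-connected background)
  diam <- matrix(FALSE, 7, 7)
  for (k in 0:3) {
    diam[4 - k, 1 + k] <- TRUE; diam[4 + k, 1 + k] <- TRUE
    diam[4 - k, 7 - k] <- TRUE; diam[4 + k, 7 - k] <- TRUE
  }
  expect_equal(find_holes(diam, connectivity = 8)$n, 1L)
  expect_equal(find_holes(diam, connectivity = 4)$n, 0L)
})

test_that("core extraction is a strict Euclidean threshold", {
  sq <- binary_landscape(matrix(TRUE, 11, 11))
  core <- extract_core(sq, mspa_params(edge_width = 4))
  expect_equal(sum(core), 9)
  expect_true(all(which(core, arr.ind = TRUE) >= 5) &&
                all(which(core, arr.ind = TRUE) <= 7))
  # thin shapes (width <= 2D) never contain core
  thin <- matrix(FALSE, 12, 30); thin[2:9, ] <- TRUE  # width 8 = 2D
  expect_equal(sum(extract_core(binary_landscape(thin), mspa_params(4))), 0)
})

test_that("segmentation matches the literal-definition oracle on random maps", {
  set.seed(303)
  for (i in 1:40) {
    fg <- random_map(sample(8:40, 1), sample(8:40, 1), runif(1, 0.25, 0.85))
    D <- sample(c(1, 2, 4, 6), 1)
    conn <- sample(c(4, 8), 1)
    m <- mspa_segment(binary_landscape(fg), edge_width = D,
                      connectivity = conn)
    expect_identical(unname(m$labels), unname(oracle_mspa(fg, D, conn)))
    # partition invariant: the 7 classes tile the foreground exactly
    expect_equal(sum(m$class_areas$cells[-1]), sum(fg))
    expect_true(all(m$labels[!fg] == 1L))
  }
})

test_that("fixtures carry their analytically derived class maps", {
  for (nm in c("solid_square", "scatter", "ring", "donut", "dumbbell",
               "two_cores_with_branch", "core_with_handle")) {
    fx <- generate_fixture(nm)
    m <- mspa_segment(fx$landscape, edge_width = fx$edge_width)
    expect_identical(unname(m$labels), unname(fx$expected), label = nm)
    expect_identical(unname(oracle_mspa(fx$landscape$grid, fx$edge_width, 8)),
                     unname(fx$expected), label = paste("oracle", nm))
  }
  # structural spot checks
  dm <- mspa_segment(generate_fixture("dumbbell")$landscape)
  expect_gt(dm$class_areas$cells[mspa_classes() == "bridge"], 0)
  expect_equal(label_components(dm$labels == 2, 8)$n, 2L)  # two cores
  hm <- mspa_segment(generate_fixture("core_with_handle")$landscape)
  expect_gt(hm$class_areas$cells[mspa_classes() == "loop"], 0)
  expect_gt(hm$class_areas$cells[mspa_classes() == "perforation"], 0)
})

test_that("core shrinks and islets grow as the edge width increases", {
  set.seed(404)
  for (i in 1:20) {
    fg <- random_map(30, 30, runif(1, 0.4, 0.8))
    ls <- binary_landscape(fg)
    prev_core <- NULL
    prev_islets <- -1
    for (D in c(1, 2, 4, 6)) {
      m <- mspa_segment(ls, edge_width = D)
      core <- m$labels == 2L
      if (!is.null(prev_core)) expect_true(all(prev_core | !core))
      islets <- m$class_areas$cells[mspa_classes() == "islet"]
      expect_gte(islets, prev_islets)
      prev_core <- core
      prev_islets <- islets
    }
  }
})

test_that("padding with background leaves class counts unchanged", {
  set.seed(505)
  for (i in 1:10) {
    fg <- random_map(15, 15, 0.6)
    pad <- matrix(FALSE, 21, 21)
    pad[4:18, 4:18] <- fg
    m1 <- mspa_segment(binary_landscape(fg))
    m2 <- mspa_segment(binary_landscape(pad))
    expect_equal(m1$class_areas$cells[-1], m2$class_areas$cells[-1])
  }
})

test_that("class proportions normalize over the chosen denominator", {
  fx <- generate_fixture("dumbbell")
  m <- mspa_segment(fx$landscape)
  pf <- class_proportions(m, "foreground")
  expect_equal(sum(pf), 1, tolerance = 1e-12)
  expect_equal(unname(pf), unname(m$class_areas$cells[-1] /
                                    sum(m$class_areas$cells[-1])))
  pl <- class_proportions(m, "landscape")
  expect_equal(sum(pl), 1, tolerance = 1e-12)
  # scatter: islet is all of the foreground
  ms <- mspa_segment(generate_fixture("scatter")$landscape)
  expect_equal(unname(class_proportions(ms)["islet"]), 1)
  m0 <- mspa_segment(binary_landscape(matrix(FALSE, 3, 3)))
  expect_error(class_proportions(m0, "foreground"), "empty")
})

test_that("boundary-over-connector switch absorbs the corridor edge zone", {
  # short corridor: all bridge by default; with the switch, corridor cells
  # inside the edge zone (within D of core) become edge and only the
  # middle (beyond D of both cores) stays bridge
  s <- 13; gap <- 5
  fg <- matrix(FALSE, s, 2 * s + gap)
  fg[1:s, 1:s] <- TRUE
  fg[1:s, (s + gap + 1):(2 * s + gap)] <- TRUE
  fg[7, (s + 1):(s + gap)] <- TRUE
  ls <- binary_landscape(fg)
  m1 <- mspa_segment(ls)
  m2 <- mspa_segment(ls, boundary_over_connector = TRUE)
  corridor <- cbind(7, (s + 1):(s + gap))
  expect_true(all(m1$labels[corridor] == 4L))
  core <- m2$labels == 2L
  dcore <- fragscape:::distance_to_mask(core)
  in_zone <- dcore[corridor] <= 4
  expect_true(any(in_zone) && !all(in_zone))
  expect_true(all(m2$labels[corridor][in_zone] == 7L))
  expect_true(all(m2$labels[corridor][!in_zone] == 4L))
})
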