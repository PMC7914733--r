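test_that("sparsify keeps exactly the strictly-above-threshold fields", {
  lay <- tinyLayout()
  st <- applyMessage(initState(lay),
                     sensorMessage(1, "A", c(0.03, 0.031, 0.5, 0, 0, 0, 0, 0.029)))
  sp <- sparsify(st, 0.03)
  expect_equal(nrow(sp), 2L)
  expect_equal(sort(sp$c), c(0.031, 0.5))
  expect_error(sparsify(st, 1), "cThreshold")
  expect_error(sparsify(st, -0.1), "cThreshold")
})

test_that("trackedPosition is the capacitance-weighted centroid", {
  sp <- sparseFixture(x = c(0, 1), y = c(0, 2), c = c(1, 3))
  expect_equal(trackedPosition(sp), c(3 / 4, 6 / 4))
  expect_null(trackedPosition(sp[0, ]))
  ## a single active field tracks to its own centroid
  expect_equal(trackedPosition(sparseFixture(0.4, 0.7, 0.2)), c(0.4, 0.7))
})

test_that("walkingAngle maps the walking direction onto (0, 1)", {
  expect_equal(walkingAngle(c(0, 0), c(0, 5)), 0)
  expect_equal(walkingAngle(c(0, 0), c(3, 0)), pi / 2)
  expect_equal(walkingAngle(c(0, 0), c(0, -1)), pi)
  expect_equal(walkingAngle(c(1, 1), c(2, 2)), pi / 4)
  expect_error(walkingAngle(c(1, 1), c(1, 1)), "degenerate")
  ## rotating the displacement by the angle gives (0, |d|)
  for (theta in c(0.3, -1.2, 2.9)) {
    d <- c(sin(theta), cos(theta)) * 2.5
    ang <- walkingAngle(c(0, 0), d)
    expect_equal(ang, theta, tolerance = 1e-12)
  }
})

test_that("toLocal performs the rigid motion and strict radius cut", {
  sp <- sparseFixture(x = c(1, 2), y = c(1, 1), c = c(0.5, 0.7))
  ## walker at (1, 0) walking +x (theta = pi/2); +y in the world is the
  ## walker's left, which is local -x. Field at (1,1): one to the left ->
  ## (-1, 0); field at (2,1): one ahead, one left -> (-1, 1)
  loc <- toLocal(sp, c(1, 0), pi / 2, radius = 10)
  expect_equal(loc$x, c(-1, -1), tolerance = 1e-12)
  expect_equal(loc$y, c(0, 1), tolerance = 1e-12)
  expect_equal(loc$c, c(0.5, 0.7))
  ## strict cut: a field exactly at the radius is dropped
  loc2 <- toLocal(sparseFixture(c(0, 3), c(1, 0), c(0.2, 0.3)),
                  c(0, 0), 0, radius = 1)
  expect_equal(nrow(loc2), 0L)
  loc3 <- toLocal(sparseFixture(0, 0.999, 0.2), c(0, 0), 0, radius = 1)
  expect_equal(nrow(loc3), 1L)
  expect_error(toLocal(sp, c(0, 0), 0, radius = 0), "radius")
})

test_that("makeGrid enumerates the lattice inside the radius in meander order", {
  g <- makeGrid(0.5, 1.0)
  pts <- gridPoints(g)
  ## brute-force oracle: all integer lattice points strictly inside r
  all <- expand.grid(i = -2:2, j = -2:2)
  inside <- all[(all$i * 0.5)^2 + (all$j * 0.5)^2 < 1, ]
  expect_equal(gridSize(g), nrow(inside))
  expect_equal(nrow(unique(pts)), gridSize(g))
  ## same point set
  key <- function(m) sort(paste(round(m[, 1], 9), round(m[, 2], 9)))
  expect_equal(key(pts), key(cbind(inside$i * 0.5, inside$j * 0.5)))
  ## meander: first row at the most negative y, x ascending; next row reversed
  expect_equal(unname(pts[1, 2]), min(pts[, 2]))
  r1 <- pts[pts[, 2] == pts[1, 2], 1]
  expect_true(all(diff(r1) > 0))
  ys <- sort(unique(pts[, 2]))
  r2 <- pts[pts[, 2] == ys[2], 1]
  expect_true(all(diff(r2) < 0))
  expect_error(makeGrid(0, 1), "invalid grid")
  expect_error(makeGrid(0.1, -1), "invalid grid")
})

test_that("resampleToGrid deposits on the nearest point with max collisions", {
  g <- makeGrid(1, 1.5)  # points: (0,-1), (-1,0), (0,0), (1,0), (0,1)
  pts <- gridPoints(g)
  ## single entry near (1, 0)
  lg <- resampleToGrid(sparseFixture(0.9, 0.1, 0.4), g)
  v <- unroll(lg)
  expect_equal(sum(v > 0), 1L)
  expect_equal(v[which(pts[, 1] == 1 & pts[, 2] == 0)], 0.4)
  ## two entries nearest to the same point: maximum wins
  lg2 <- resampleToGrid(sparseFixture(c(0.9, 1.1), c(0, 0), c(0.4, 0.9)), g)
  expect_equal(max(unroll(lg2)), 0.9)
  expect_equal(sum(unroll(lg2) > 0), 1L)
  ## exact tie between (0,0) and (1,0): lower x wins
  lg3 <- resampleToGrid(sparseFixture(0.5, 0, 0.7), g)
  expect_equal(unroll(lg3)[which(pts[, 1] == 0 & pts[, 2] == 0)], 0.7)
  expect_equal(sum(unroll(lg3) > 0), 1L)
  ## empty input: all zeros
  expect_true(all(unroll(resampleToGrid(sparseFixture(numeric(), numeric(),
                                                      numeric()), g)) == 0))
})

test_that("the local transform is rigid-motion invariant", {
  set.seed(21)
  g <- makeGrid(0.25, 1.0)
  for (rep in 1:5) {
    n <- 6
    sp <- sparseFixture(runif(n, -0.8, 0.8), runif(n, -0.8, 0.8),
                        runif(n, 0.05, 0.9))
    pos <- c(runif(1, -0.2, 0.2), runif(1, -0.2, 0.2))
    theta <- runif(1, -pi, pi)
    v1 <- unroll(resampleToGrid(toLocal(sp, pos, theta, 1.0), g))
    ## rotate the world by phi and translate by tau
    phi <- runif(1, -pi, pi); tau <- runif(2, -5, 5)
    Rw <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    xy <- Rw %*% rbind(sp$x, sp$y)
    sp2 <- sparseFixture(xy[1, ] + tau[1], xy[2, ] + tau[2], sp$c)
    pos2 <- as.numeric(Rw %*% pos + tau)
    v2 <- unroll(resampleToGrid(toLocal(sp2, pos2, theta - phi, 1.0), g))
    expect_equal(v2, v1, tolerance = 1e-9)
  }
})

test_that("a fine grid conserves every activation value", {
  set.seed(22)
  spacing <- 0.05
  g <- makeGrid(spacing, 1.0)
  for (rep in 1:3) {
    ## entries separated by > 2 spacings so no two share a nearest point
    repeat {
      n <- 5
      sp <- sparseFixture(runif(n, -0.6, 0.6), runif(n, -0.6, 0.6),
                          runif(n, 0.05, 0.9))
      d <- as.matrix(dist(cbind(sp$x, sp$y)))
      diag(d) <- Inf
      if (min(d) > 2 * spacing) break
    }
    v <- unroll(resampleToGrid(sp, g))
    expect_equal(sort(v[v > 0]), sort(sp$c))
  }
})

test_that("preprocessWalk emits one grid vector per tracked state", {
  set.seed(23)
  lay <- makeFloorGrid(3, 12, 0.38)
  rec <- simulateRecording(gaitParams(), lay, simConfig(pathLength = 3),
                           outAndBack = FALSE)
  series <- replayMessages(lay, rec$messages)
  mat <- preprocessWalk(series, spacing = 0.25, radius = 1.0)
  g <- makeGrid(0.25, 1.0)
  expect_equal(ncol(mat), gridSize(g))
  expect_gt(nrow(mat), 10)
  expect_true(all(mat >= 0) && all(mat <= 1))
  expect_true(is.numeric(attr(mat, "theta")))
  expect_equal(length(attr(mat, "times")), nrow(mat))
  ## the walk runs along +y, so theta should be near 0
  expect_lt(abs(attr(mat, "theta")), 0.3)
})

test_that("preprocessed walks round trip through disk", {
  set.seed(24)
  lay <- makeFloorGrid(3, 8, 0.38)
  rec <- simulateRecording(gaitParams(), lay, simConfig(pathLength = 2),
                           outAndBack = FALSE)
  series <- replayMessages(lay, rec$messages)
  mat <- preprocessWalk(series, spacing = 0.25, radius = 1.0)
  path <- tempfile(fileext = ".csv")
  writePreprocessedWalk(mat, path)
  back <- readPreprocessedWalk(path)
  expect_equal(unclass(back)[seq_len(nrow(mat)), ], unclass(mat)[, ],
               ignore_attr = TRUE)
  expect_equal(attr(back, "theta"), attr(mat, "theta"))
  expect_equal(attr(back, "spacing"), attr(mat, "spacing"))
  expect_equal(attr(back, "times"), as.numeric(attr(mat, "times")))
  unlink(c(path, paste0(path, ".json")))
})
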