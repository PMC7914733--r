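test_that("gait parameters validate and derive cadence", {
  p <- gaitParams()
  expect_equal(p$cadence, 60 * 1.35 / 0.70)
  expect_error(gaitParams(speed = 0), "positive")
  expect_error(gaitParams(stepTimeCV = -0.1), "non-negative")
  expect_error(gaitParams(doubleSupport = 1), "doubleSupport")
})

test_that("the mode library perturbs parameters as configured", {
  lib <- modeLibrary("default")
  p <- gaitParams()
  ce <- applyMode(p, lib$closed_eyes)
  expect_equal(ce$speed, 1.35 * 0.85)
  expect_equal(ce$stepLength, 0.70 * 0.90)
  expect_equal(ce$stepWidthSD, p$stepWidthSD * 2)
  expect_equal(ce$stepTimeCV, p$stepTimeCV * 2)
  strong <- applyMode(p, modeLibrary("strong")$closed_eyes)
  expect_equal(strong$speed, 1.35 * 0.75)
  expect_equal(strong$sway, p$sway * 2)
  pu <- applyMode(p, lib$post_uhr)
  expect_equal(pu$stanceAsymmetry, 0.10)
  ## the null library leaves every mode at baseline
  none <- modeLibrary("none")
  for (mode in names(none))
    expect_equal(applyMode(p, none[[mode]]), p)
})

test_that("simulated footfalls alternate feet with plausible spacing", {
  set.seed(41)
  p <- gaitParams()
  ff <- simulateFootfalls(p, 6)
  expect_gte(nrow(ff), 6)
  expect_true(all(ff$foot[c(TRUE, FALSE)] == "left"))
  expect_true(all(ff$foot[c(FALSE, TRUE)] == "right"))
  ## forward progression ~ stepLength per footfall (walking +y)
  dy <- diff(ff$y)
  expect_equal(mean(dy), p$stepLength, tolerance = 0.1)
  ## lateral offsets put right foot at +x, left at -x of the line
  expect_gt(mean(ff$x[ff$foot == "right"]), mean(ff$x[ff$foot == "left"]))
  ## stance intervals are positive and overlap (double support)
  expect_true(all(ff$t_up > ff$t_down))
  expect_true(all(diff(ff$t_down) > 0))
  ov <- ff$t_up[-nrow(ff)] - ff$t_down[-1]
  expect_gt(mean(ov > 0), 0.8)
  expect_error(simulateFootfalls(p, 0), "pathLength")
})

test_that("stance asymmetry lengthens left stance", {
  set.seed(42)
  ff <- simulateFootfalls(gaitParams(stanceAsymmetry = 0.2), 6)
  stance <- ff$t_up - ff$t_down
  expect_gt(mean(stance[ff$foot == "left"]), mean(stance[ff$foot == "right"]))
})

test_that("footprint capacitance conserves the covered-area oracle", {
  lay <- makeFloorGrid(3, 3, 0.38)
  ## small foot well inside the floor: no field clips, so the contributions
  ## must sum to gain x ellipse area / field area exactly (deterministic
  ## subsampling assigns every sample point to exactly one field)
  fl <- 0.20; fw <- 0.08; gain <- 0.9
  contrib <- footprintToCapacitance(c(0.57, 0.57), 0.3, lay, gain, fl, fw)
  expect_gt(length(contrib), 0)
  expect_true(all(contrib > 0 & contrib <= gain))
  oracle <- gain * (pi * (fl / 2) * (fw / 2)) / fieldArea(0.38)
  expect_equal(sum(contrib), oracle, tolerance = 1e-9)
  ## a foot entirely off the floor touches nothing
  expect_length(footprintToCapacitance(c(10, 10), 0, lay), 0)
})

test_that("foot placement maps points to the correct field slot", {
  lay <- makeFloorGrid(1, 1, 0.38)
  f <- fieldTable(lay)
  ## a tiny foot centered on each field centroid loads mostly that field
  for (i in seq_len(8)) {
    contrib <- footprintToCapacitance(c(f$x[i], f$y[i]), 0, lay,
                                      gain = 0.9, footLength = 0.05,
                                      footWidth = 0.03)
    expect_equal(names(which.max(contrib)), f$field_id[i])
  }
})

test_that("emitMessages implements change-triggered per-module emission", {
  lay <- tinyLayout()
  f <- fieldTable(lay)
  times <- c(0, 0.1, 0.2, 0.3)
  cap <- matrix(0, 4, 16)
  cap[2, 1] <- 0.5            # module A changes at t=0.1
  cap[3, 1] <- 0.505          # below-threshold change: no message
  cap[3, 9] <- 0.4            # module B changes at t=0.2
  cap[4, 1] <- 0.505          # nothing changes at t=0.3
  cap[4, 9] <- 0.4
  msgs <- emitMessages(cap, times, f, threshold = 0.02)
  expect_equal(nrow(msgs), 2)
  expect_equal(msgs$module, c("A", "B"))
  expect_equal(msgs$t, c(0.1, 0.2))
  expect_equal(msgs$c1[1], 0.5)
  expect_equal(msgs$c1[2], 0.4)
  ## an all-zero series emits nothing
  expect_equal(nrow(emitMessages(matrix(0, 3, 16), 1:3, f, 0.02)), 0)
})

test_that("replaying emitted messages reconstructs the sampled series", {
  set.seed(44)
  lay <- makeFloorGrid(3, 10, 0.38)
  cfg <- simConfig(pathLength = 3)
  rec <- simulateRecording(gaitParams(), lay, cfg, outAndBack = FALSE)
  expect_gt(nrow(rec$messages), 20)
  ## at every sampling tick the replayed state matches the sampled
  ## capacitances to within the emission threshold per field
  ticks <- sample(seq_along(rec$sampled$times), 12)
  for (ti in ticks) {
    recon <- reconstructAt(lay, rec$messages, rec$sampled$times[ti])
    expect_lte(max(abs(recon - rec$sampled$cap[ti, ])),
               cfg$emissionThreshold + 1e-9)
  }
})

test_that("generateCohort produces the configured design and is reproducible", {
  lay <- makeFloorGrid(3, 10, 0.38)
  cfg <- simConfig(pathLength = 2.5)
  co <- generateCohort(3, lay, modes = c("normal", "closed_eyes"),
                       repsPerMode = 2, cfg = cfg, seed = 5)
  expect_equal(nrow(co$manifest), 3 * 2 * 2)
  expect_length(co$recordings, 12)
  expect_equal(sort(unique(co$manifest$participant)), c("p01", "p02", "p03"))
  expect_true(all(table(co$manifest$participant, co$manifest$mode) == 2))
  expect_true(all(co$participants$uhr_left >= 10 & co$participants$uhr_left <= 45))
  expect_true(all(co$participants$uhr_right >= 10 & co$participants$uhr_right <= 45))
  ## same seed -> bit-identical streams; different seed -> different
  co2 <- generateCohort(3, lay, modes = c("normal", "closed_eyes"),
                        repsPerMode = 2, cfg = cfg, seed = 5)
  expect_identical(co$recordings[[1]]$messages, co2$recordings[[1]]$messages)
  expect_identical(co$participants, co2$participants)
  co3 <- generateCohort(3, lay, modes = c("normal", "closed_eyes"),
                        repsPerMode = 2, cfg = cfg, seed = 6)
  expect_false(identical(co$recordings[[1]]$messages,
                         co3$recordings[[1]]$messages))
  expect_error(generateCohort(2, lay, modes = "hopping"), "unknown walking mode")
})

test_that("uhr coupling shifts walking speed with latent strength", {
  lay <- makeFloorGrid(2, 2, 0.38)
  ## couple = 1: stronger participants (higher uhr) walk faster on average
  set.seed(50)
  n <- 60
  strengths <- rnorm(n)
  speeds1 <- 1.35 * (1 + 0.08 * 1 * strengths) * exp(rnorm(n, 0, 0.04))
  speeds0 <- 1.35 * (1 + 0.08 * 0 * strengths) * exp(rnorm(n, 0, 0.04))
  expect_gt(cor(strengths, speeds1), 0.6)
  expect_lt(abs(cor(strengths, speeds0)), 0.35)
})
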