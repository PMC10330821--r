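test_that("segmentation handles blank and uncalibrated input", {
  expect_equal(max(segmentParticles(Micrograph(matrix(0.75, 64, 64), 1))$labels),
               0)
  expect_error(segmentParticles(matrix(0.75, 64, 64)), "Micrograph")
  ft <- extractParticleFeatures(list(labels = matrix(0L, 10, 10),
                                     enhanced = matrix(0, 10, 10),
                                     nmPerPx = 1))
  expect_equal(nrow(ft), 0L)
})

test_that("rendered gold disks are measured at their true size, position
           and shape", {
  m <- diskMicrograph(c(50.3, 100.6), c(50.7, 100.2), c(6, 12), side = 150)
  ft <- extractParticleFeatures(segmentParticles(m))
  ft <- ft[order(ft$area_nm2), ]
  expect_equal(nrow(ft), 2L)
  ## areas within the 15% rasterization bound
  expect_lt(abs(ft$area_nm2[1] - pi * 9) / (pi * 9), 0.15)
  expect_lt(abs(ft$area_nm2[2] - pi * 36) / (pi * 36), 0.15)
  ## centroids within 1 px
  expect_lt(abs(ft$x_nm[1] - 50.3), 1)
  expect_lt(abs(ft$y_nm[1] - 50.7), 1)
  expect_lt(abs(ft$x_nm[2] - 100.6), 1)
  ## circular disks have low eccentricity
  expect_true(all(ft$ecc < 0.5))
})

test_that("moment ellipse eccentricity matches the closed form for a 2:1
           ellipse", {
  side <- 101
  xs <- matrix(seq_len(side) - 0.5, side, side)
  ys <- t(xs)
  lab <- matrix(0L, side, side)
  lab[((xs - 50) / 30)^2 + ((ys - 50) / 15)^2 <= 1] <- 1L
  ft <- extractParticleFeatures(list(labels = lab,
    enhanced = matrix(1, side, side), nmPerPx = 1))
  expect_equal(ft$ecc, sqrt(3) / 2, tolerance = 0.02)
  expect_equal(ft$major_nm / ft$minor_nm, 2, tolerance = 0.05)
})

test_that("touching disks are split into separate particles", {
  m <- diskMicrograph(c(55, 62.5), c(55, 55.4), c(6, 6))
  expect_equal(max(segmentParticles(m)$labels), 2)
  m2 <- diskMicrograph(c(55, 65), c(55, 55.4), c(6, 12))
  cls <- classifyParticles(extractParticleFeatures(segmentParticles(m2)))
  expect_setequal(cls$class[!cls$removed], c("insulin", "chgb"))
})

test_that("size/shape classification applies the standard thresholds and
           partitions the detections", {
  tab <- data.frame(id = 1:6,
                    area_nm2 = c(28, 113, 15, 80, 20, 65),
                    ecc = c(0.1, 0.1, 0.1, 0.8, 0.3, 0.74))
  cls <- classifyParticles(tab)
  expect_equal(cls$class, c("insulin", "chgb", "noise", "chgb", "insulin",
                            "chgb"))
  expect_equal(cls$removed, c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(cls$removalReason[3], "noise")
  expect_equal(cls$removalReason[4], "eccentricity")
  ## partition: removed and kept cover everything, disjoint by construction
  expect_equal(sum(cls$removed) + sum(!cls$removed), nrow(tab))
})

test_that("ring assignment honours the 20-nm extension and nearest-boundary
           tie-break", {
  rings <- GranuleRingSet(list(GranulePhys:::circlePolygon(100, 100, 50),
                               GranulePhys:::circlePolygon(230, 100, 50)))
  tab <- data.frame(x_nm = c(100, 160, 185, 100, 163),
                    y_nm = c(100, 100, 100, 25, 100),
                    area_nm2 = 100, ecc = 0.1)
  tab <- classifyParticles(tab)
  asg <- assignToRings(tab, rings)
  expect_equal(asg$ring_id, c(1L, 1L, 2L, NA, 1L))
  expect_equal(asg$d_nm[1], 50, tolerance = 0.2)     # centre: +R
  expect_equal(asg$d_nm[2], -10, tolerance = 0.2)    # 10 nm outside ring 1
  expect_equal(asg$d_nm[3], 5, tolerance = 0.2)      # 5 nm inside ring 2
  expect_true(is.na(asg$d_nm[4]))                    # 30+ nm outside all
  expect_error(assignToRings(tab, GranuleRingSet(list())), "no rings")
})

test_that("signed membrane distance is positive inside, negative outside,
           and matches generator truth through the full pipeline", {
  ring <- GranulePhys:::circlePolygon(0, 0, 98)
  expect_equal(signedMembraneDistance(c(0, 0), ring), 98, tolerance = 0.25)
  expect_equal(signedMembraneDistance(c(108, 0), ring), -10, tolerance = 0.05)
  expect_equal(signedMembraneDistance(c(50, 0), ring), 48, tolerance = 0.25)
  ## full-pipeline distances within 1 px + 0.5 nm of truth
  f <- makeEMField(EMFieldParams(nGranules = 10, seed = 21, noiseSd = 0))
  cls <- classifyParticles(extractParticleFeatures(segmentParticles(f$image)))
  asg <- assignToRings(cls, f$rings)
  kept <- asg[!asg$removed & !is.na(asg$ring_id), ]
  m <- matchTruth(f$truth, kept)
  ok <- m$dist < 2
  expect_gt(mean(ok), 0.98)
  expect_lt(max(abs(kept$d_nm[m$near][ok] - f$truth$d_nm[ok])), 1.5)
})

test_that("distance histograms use left-closed 20-nm bins, conserve counts
           and flag underflow", {
  h <- distanceHistogram(c(-10, 5, 25))
  expect_equal(h$count, c(1, 1, 1))
  expect_equal(h$lower, c(-20, 0, 20))
  h0 <- distanceHistogram(numeric())
  expect_true(all(h0$count == 0))
  expect_warning(hU <- distanceHistogram(c(-30, -10, 5)), "underflow")
  expect_equal(attr(hU, "underflow"), 1)
  expect_equal(sum(hU$count) + attr(hU, "underflow"), 3)
  ## bin-edge convention: a value on an interior edge joins the upper bin
  expect_equal(distanceHistogram(c(0, 19.9))$count[2], 2)
  expect_error(distanceHistogram(1:5, binWidth = 0), "binWidth")
})

test_that("membrane-zone fraction counts -20 <= d <= 40", {
  expect_equal(fractionWithinMembraneZone(c(-10, 10, 30, 50, 100)), 0.6)
  expect_equal(fractionWithinMembraneZone(c(50, 60)), 0)
  expect_equal(fractionWithinMembraneZone(c(-25, 10)), 0.5)
})

test_that("antibody-geometry displacement bounds reproduce the canonical
           40/26 nm limits", {
  b <- labelDisplacementBounds()
  expect_equal(unname(b["luminalMaxNm"]), 40)
  expect_equal(unname(b["externalMaxNm"]), 26)
  z <- labelDisplacementBounds(LabelGeometry(primaryAb = 0, secondaryAb = 0,
    linker = 0, epitopeExtension = 0, goldDiameter = 0, bilayer = 0))
  expect_equal(unname(z), c(0, 0))
  b6 <- labelDisplacementBounds(LabelGeometry(goldDiameter = 6))
  expect_equal(unname(b6), c(37, 23))
})

test_that("ring equivalent diameter recovers a circle's diameter", {
  ring <- GranulePhys:::circlePolygon(10, 10, 98)
  rs <- GranuleRingSet(list(ring))
  expect_equal(equivalentDiameters(rs), 196, tolerance = 0.5)
})

test_that("blob counting finds every simulated punctum, none on blank
           fields, deterministically", {
  p <- makePunctaImage(25, seed = 2)
  r <- countSurfacePuncta(p$image)
  expect_equal(r$count, 25)
  m <- matchTruth(p$truth, r$centroids)
  expect_lt(max(m$dist), 50)  # within one 50-nm pixel
  blank <- makePunctaImage(0, seed = 2)
  expect_equal(countSurfacePuncta(blank$image)$count, 0)
  expect_identical(countSurfacePuncta(p$image)$centroids, r$centroids)
})
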