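test_that("the default 2x2 layout places spots on a grid and enforces bounds", {
  img <- constImage(0, 480, 640)
  ss <- defaultSpotLayout(img, anchor = c(240, 320), spacing = 40,
                          diameter = 33)
  expect_equal(spotCenters(ss),
               rbind(c(220, 300), c(220, 340), c(260, 300), c(260, 340)))
  expect_equal(spotDiameter(ss), 33)

  expect_error(defaultSpotLayout(img, anchor = c(5, 5), spacing = 40,
                                 diameter = 33), "bounds")
  # tangent circles (center distance == diameter) violate strict non-overlap
  expect_error(defaultSpotLayout(img, anchor = c(240, 320), spacing = 33,
                                 diameter = 33), "exceed")
  expect_error(SpotSet(rbind(c(50, 50), c(50, 83), c(100, 50), c(100, 83)),
                       diameter = 33), "overlap")
  expect_error(defaultSpotLayout(img, anchor = c(600, 320)), "outside")
})

test_that("spot membership is strict Euclidean distance on pixel centers", {
  img <- GreyImage(matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64))
  # diameter 3 at an integer center: all 9 lattice points within radius 1.5
  # (the 4-neighbours at distance 1 and the diagonals at sqrt(2) ~ 1.414)
  v <- spotPixelValues(img, c(10, 10), 3)
  expect_length(v, 9)
  expect_equal(sort(v), sort(as.vector(pixels(img)[9:11, 9:11])))

  # row-major order: (9,9),(9,10),(9,11),(10,9),...
  expect_equal(v, as.vector(t(pixels(img)[9:11, 9:11])))

  # count at diameter 33 equals the brute-force lattice count inside
  # radius 16.5, identically for every in-bounds center
  bruteCount <- sum(outer(-17:17, -17:17,
                          function(i, j) i^2 + j^2 < 16.5^2))
  for (ctr in list(c(20, 20), c(32, 32), c(45, 20))) {
    expect_length(spotPixelValues(img, ctr, 33), bruteCount)
  }

  expect_error(spotPixelValues(img, c(2, 2), 33), "bounds")
  cimg <- constImage(7, 64, 64)
  expect_true(all(spotPixelValues(cimg, c(30, 30), 15) == 7))
})

test_that("MPI is the mean of spot means and MPH the mean of spot SDs", {
  # constant image: zero-variance case
  img <- constImage(42, 128, 128)
  ss <- defaultSpotLayout(img, diameter = 33, spacing = 40)
  st <- computeMpiMph(img, ss)
  expect_equal(st$mpi, 42)
  expect_equal(st$mph, 0)

  # quadrant image: per-spot constant 10/20/30/40 -> mpi 25, per-spot mph 0,
  # across-spot mph = sd of the spot means
  q <- matrix(0, 128, 128)
  q[1:64, 1:64] <- 10; q[1:64, 65:128] <- 20
  q[65:128, 1:64] <- 30; q[65:128, 65:128] <- 40
  qimg <- GreyImage(q)
  qs <- SpotSet(rbind(c(32, 32), c(32, 96), c(96, 32), c(96, 96)),
                diameter = 33)
  expect_equal(computeMpiMph(qimg, qs)$mpi, 25)
  expect_equal(computeMpiMph(qimg, qs)$mph, 0)
  expect_equal(computeMpiMph(qimg, qs, mphMode = "across-spots")$mph,
               sd(c(10, 20, 30, 40)))

  # 4-pixel spot {0, 0, 255, 255}: mean 127.5, sample SD sqrt(65025/3)
  b <- matrix(0, 32, 32); b[11, 10:11] <- 255
  v <- spotPixelValues(GreyImage(b), c(10.5, 10.5), 3)
  expect_length(v, 4)
  expect_equal(mean(v), 127.5)
  expect_equal(sd(v), sqrt(65025 / 3))
  expect_equal(round(sd(v), 2), 147.22)
})

test_that("MPI/MPH match a naive per-pixel recomputation and obey invariants", {
  set.seed(99)
  for (k in 1:40) {
    img <- randomGreyImage(64, 64)
    dia <- sample(c(9, 11, 15), 1)
    anchor <- c(sample(25:39, 1), sample(25:39, 1))
    ss <- defaultSpotLayout(img, anchor = anchor, spacing = dia + 3,
                            diameter = dia)
    st <- computeMpiMph(img, ss)
    oracle <- naiveSpotStats(img, spotCenters(ss), dia)
    expect_equal(st$mpi, oracle$mpi, tolerance = 1e-12)
    expect_equal(st$mph, oracle$mph, tolerance = 1e-12)

    # bounded by the pixel range over the union of spots
    union <- unlist(lapply(1:4, function(i)
      spotPixelValues(img, spotCenters(ss)[i, ], dia)))
    expect_gte(st$mpi, min(union))
    expect_lte(st$mpi, max(union))

    # permuting spot order changes nothing
    perm <- SpotSet(spotCenters(ss)[sample(1:4), ], dia)
    expect_equal(computeMpiMph(img, perm)[c("mpi", "mph")],
                 st[c("mpi", "mph")])

    # adding a constant shifts MPI, leaves MPH
    capped <- GreyImage(pmin(pixels(img), 200))
    st0 <- computeMpiMph(capped, ss)
    st50 <- computeMpiMph(GreyImage(pixels(capped) + 50), ss)
    expect_equal(st50$mpi, st0$mpi + 50, tolerance = 1e-12)
    expect_equal(st50$mph, st0$mph, tolerance = 1e-12)
  }
})

test_that("batch analysis yields one record per bird and plane with per-row error capture", {
  d <- withr::local_tempdir()
  manifest <- writeConstantStudy(file.path(d, "imgs"), nPerGroup = 3)
  rec <- suppressWarnings(analyzeBatch(manifest, diameter = 21,
                                       normalize = FALSE))
  expect_equal(nrow(rec), 36)  # 3 groups x 3 birds x 4 planes
  expect_equal(nrow(attr(rec, "failures")), 0)
  summ <- groupSummary(rec)
  expect_true(all(summ$sem == 0))
  expect_true(all(summ$mean[grepl("MPI", summ$variable)] == 42))
  expect_true(all(summ$mean[grepl("MPH", summ$variable)] == 0))
  # deterministic ordering by (group, bird, plane)
  expect_equal(rec$plane[1:4], c("L", "T", "O1", "O2"))
  expect_false(is.unsorted(rec$group))

  file.remove(manifest$path[7])
  rec2 <- suppressWarnings(analyzeBatch(manifest, diameter = 21))
  expect_equal(nrow(rec2), 35)
  expect_equal(nrow(attr(rec2, "failures")), 1)
  expect_match(attr(rec2, "failures")$error, "not found")
})

test_that("spot CSVs round-trip into validated SpotSets", {
  d <- withr::local_tempdir()
  f <- file.path(d, "spots.csv")
  df <- data.frame(bird_id = "b1", plane = "L", spot_index = 1:4,
                   center_row = c(40, 40, 80, 80),
                   center_col = c(40, 80, 40, 80), diameter = 33)
  write.csv(df, f, row.names = FALSE)
  sl <- readSpotsCsv(f)
  expect_named(sl, "b1:L")
  expect_equal(spotDiameter(sl[["b1:L"]]), 33)
  write.csv(df[1:3, ], f, row.names = FALSE)
  expect_error(readSpotsCsv(f), "exactly 4")
})

test_that("speckle batches calibrated to a target MPI recover it within 2 grey levels", {
  d <- withr::local_tempdir()
  sigma <- calibrateSigma(52.6)
  expect_equal(sigma, 52.6 / sqrt(pi / 2), tolerance = 1e-12)
  rows <- list()
  for (b in 1:15) {
    img <- simulateSpeckleImage(sigma, c(128, 128), seed = 7000 + b)
    f <- file.path(d, sprintf("C_%02d_L.png", b))
    writeGreyPNG(img, f)
    rows[[b]] <- data.frame(bird_id = sprintf("C_%02d", b), group = "C",
                            plane = "L", path = f)
  }
  rec <- analyzeBatch(do.call(rbind, rows), diameter = 33,
                      normalize = FALSE)
  expect_lt(abs(mean(rec$mpi) - 52.6), 2)
})
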