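test_that("MSE: hand values, masked restriction, symmetry", {
  x <- array(c(1, 2, 3), c(1, 1, 3))
  y <- array(c(1, 2, 5), c(1, 1, 3))
  expect_equal(mseMetric(x, y), 4 / 3)
  expect_equal(mseMetric(x, x), 0)
  # masked MSE equals the unmasked MSE of the extracted voxel pair
  v1 <- randVol(c(4, 6, 6), 1); v2 <- randVol(c(4, 6, 6), 2)
  m <- array(FALSE, c(4, 6, 6)); m[c(3, 77)] <- TRUE
  expect_equal(mseMetric(v1, v2, m),
               mean((v1[c(3, 77)] - v2[c(3, 77)])^2))
  expect_equal(mseMetric(v1, v2), mseMetric(v2, v1))
  expect_error(mseMetric(v1, v2, array(FALSE, c(4, 6, 6))), "empty")
})

test_that("PSNR closed forms and the reference-first convention", {
  x <- array(c(0, 2), c(1, 1, 2))
  y <- array(c(1, 3), c(1, 1, 2))        # MSE = 1
  expect_equal(psnrMetric(x, y, m = 255), 20 * log10(255))
  expect_equal(psnrMetric(x, y, m = 255), 48.1308, tolerance = 1e-4)
  # MSE = m^2 gives 0 dB
  a <- array(0, c(1, 1, 4)); b <- array(3, c(1, 1, 4))
  expect_equal(psnrMetric(a, b, m = 3), 0)
  # doubling the peak adds 20 log10(2) dB
  expect_equal(psnrMetric(x, y, m = 510) - psnrMetric(x, y, m = 255),
               20 * log10(2))
  expect_equal(psnrMetric(x, x, m = 255), Inf)
})

test_that("UQI: identity, scaling, luminance shift, degeneracy", {
  x <- randVol(c(4, 8, 8), 5, mean = 50, sd = 20)
  expect_equal(uqiMetric(x, x), 1)
  expect_equal(uqiMetric(x, 2 * x), 0.64, tolerance = 1e-12)
  expect_lt(uqiMetric(x, x + 30), 1)
  expect_error(uqiMetric(array(1, c(1, 1, 4)), array(1, c(1, 1, 4))),
               "degenerate")
  expect_equal(uqiMetric(x, 2 * x), uqiMetric(2 * x, x))
})

test_that("global SSIM agrees with the loss module and brute force", {
  x <- randVol(c(16, 16, 16), 6); y <- randVol(c(16, 16, 16), 7)
  pa <- ssimParams()
  expect_equal(ssimGlobal(x, x, pa), 1)
  m <- randMask(c(16, 16, 16), 8, 0.4)
  expect_equal(ssimGlobal(x, y, pa, m),
               regionSSIM(x, y, m, ssimParams(window = "global")),
               tolerance = 1e-10)
  expect_equal(ssimGlobal(x, y, pa),
               bruteSSIM(as.vector(x), as.vector(y), pa$c1, pa$c2),
               tolerance = 1e-9)
  expect_equal(ssimGlobal(x, y, pa), ssimGlobal(y, x, pa))
})

test_that("Dice: identity, disjoint, half overlap, empty convention", {
  a <- randMask(c(6, 6, 6), 9, 0.3)
  expect_equal(diceCoefficient(a, a), 1)
  b <- array(FALSE, c(6, 6, 6)); b[1:4] <- TRUE
  c_ <- array(FALSE, c(6, 6, 6)); c_[3:6] <- TRUE
  expect_equal(diceCoefficient(b, c_), 0.5)     # |A|=|B|=4, overlap 2
  d_ <- array(FALSE, c(6, 6, 6)); d_[10:13] <- TRUE
  expect_equal(diceCoefficient(b, d_), 0)
  e_ <- array(FALSE, c(6, 6, 6))
  expect_warning(v <- diceCoefficient(e_, e_), "empty")
  expect_equal(v, 1)
  expect_equal(diceCoefficient(b, c_), diceCoefficient(c_, b))
})

test_that("surface extraction: point counts and boundary definition", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  s <- extractSurface(m, c(1, 1, 1))
  expect_equal(s$n, 1)
  expect_equal(unname(s$points[1, ]), c(2, 2, 2))
  cube <- array(FALSE, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
  expect_equal(extractSurface(cube, c(1, 1, 1))$n, 26)   # all but the centre
  # a mask touching the volume border is all surface
  slab <- array(TRUE, c(1, 3, 3))
  expect_equal(extractSurface(slab, c(1, 1, 1))$n, 9)
  expect_error(extractSurface(array(FALSE, c(2, 2, 2))), "empty")
  # every surface voxel has a 6-neighbour outside (brute check)
  rm_ <- randMask(c(6, 6, 6), 12, 0.4)
  got <- extractSurface(rm_, c(2, 1, 1))$points
  want <- bruteSurface(rm_, c(2, 1, 1))
  expect_equal(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE],
               unname(want[order(want[, 1], want[, 2], want[, 3]), ,
                           drop = FALSE]),
               ignore_attr = TRUE)
})

test_that("HD95: identities, two-point case, shifted line oracle", {
  a <- array(FALSE, c(5, 5, 5)); a[2, 2, 2] <- TRUE
  expect_equal(hausdorff95(a, a, c(1, 1, 1)), 0)
  b <- array(FALSE, c(5, 5, 5)); b[2, 2, 4] <- TRUE
  expect_equal(hausdorff95(a, b, c(1, 1, 5)), 10)   # two points 10 mm apart
  # 21-voxel line vs the same line shifted one voxel laterally at 1 mm
  d <- c(1, 3, 21)
  l1 <- array(FALSE, d); l1[1, 1, ] <- TRUE
  l2 <- array(FALSE, d); l2[1, 2, ] <- TRUE
  expect_equal(hausdorff95(l1, l2, c(1, 1, 1)), 1)
  expect_equal(hausdorff95(l1, l2, c(1, 1, 1)),
               bruteHD(l1, l2, c(1, 1, 1))$hd95, tolerance = 1e-6)
  # symmetry and the <= full-Hausdorff bound on random blobs
  for (i in 1:5) {
    ra <- randMask(c(8, 8, 8), 600 + i, 0.08)
    rb <- randMask(c(8, 8, 8), 700 + i, 0.08)
    if (!any(ra) || !any(rb)) next
    sp <- c(2, 1.5, 1.5)
    h1 <- hausdorff95(ra, rb, sp)
    expect_equal(h1, hausdorff95(rb, ra, sp))
    expect_lte(h1, bruteHD(ra, rb, sp)$hdmax + 1e-9)
  }
})

test_that("CT statistics: constants, phantom construction, loop oracle", {
  const <- array(50, c(4, 6, 6))
  masks <- list(A = randMask(c(4, 6, 6), 13, 0.5))
  cs <- ctStatistics(const, masks)
  expect_equal(cs$mean_hu, 50)
  expect_equal(cs$sd_hu, 0)
  ph <- tinyPhantom(seed = 4, noiseFree = TRUE)
  cs2 <- ctStatistics(noncontrast(ph), maskSet(ph), "Vessels")
  expect_equal(cs2$mean_hu, 46.67, tolerance = 1e-9)
  # independent voxel-loop oracle on a noisy phantom
  ph2 <- tinyPhantom(seed = 4)
  v <- voxelData(noncontrast(ph2)); m <- getMask(ph2, "Fat")
  s <- 0; n <- 0
  for (i in which(m)) { s <- s + v[i]; n <- n + 1 }
  cs3 <- ctStatistics(noncontrast(ph2), maskSet(ph2), "Fat")
  expect_equal(cs3$mean_hu, s / n, tolerance = 1e-9)
  # missing tissues are reported absent, not dropped
  cs4 <- ctStatistics(const, masks, c("A", "Ghost"))
  expect_equal(cs4$present, c(TRUE, FALSE))
  expect_true(is.na(cs4$mean_hu[2]))
})

test_that("line profiles: constants, vessel plateau, crossing point", {
  const <- CTVolume(array(7, c(4, 6, 8)), spacing = c(3, 2, 1))
  pr <- lineProfile(const, "horizontal", 2, 3)
  expect_equal(pr$hu, rep(7, 8))
  expect_equal(pr$position_mm, (0:7) * 1)
  expect_error(lineProfile(const, "vertical", 9, 1), "out of range")
  # a profile crossing a noise-free vessel tube plateaus at vessel HU with
  # width set by the tube geometry
  ph <- tinyPhantom(seed = 6, noiseFree = TRUE, grid = c(16, 64, 64))
  geo <- ph@provenance$geometry$vessel_l
  xidx <- round(geo$cv * 64)
  zmid <- 8
  pv <- lineProfile(noncontrast(ph), "vertical", zmid, xidx)
  expect_true(any(abs(pv$hu - 46.67) < 1e-6))
  width <- sum(abs(pv$hu - 46.67) < 1e-6)
  expect_lte(abs(width - 2 * geo$r * 64), 2)
  # vertical and horizontal profiles agree at their crossing voxel
  yidx <- round(geo$cu * 64)
  phz <- lineProfile(noncontrast(ph), "horizontal", zmid, yidx)
  expect_equal(phz$hu[xidx], pv$hu[yidx])
})

test_that("hallucination proxy: identity, band placement, positive control", {
  ph <- tinyPhantom(seed = 14, grid = c(20, 32, 32),
                    noiseFree = TRUE)
  truth <- voxelData(enhanced(ph))
  ms <- maskSet(ph)
  r0 <- hallucinationRate(truth, truth, ms)
  expect_equal(r0$rate, 0)
  # CTV z-extent and the 50 mm band at 3 mm slices
  zs <- which(apply(getMask(ph, "CTV"), 1, any))
  # inject a 200 HU blob outside every enhancing mask but inside the band
  pred <- truth
  blob <- array(FALSE, dim(truth))
  blob[min(zs), 4:8, 14:17] <- TRUE          # fat rind region, 20 voxels
  stopifnot(sum(blob & getMask(ph, "Vessels")) == 0)
  pred[blob] <- pred[blob] + 200
  r1 <- hallucinationRate(pred, truth, ms, min_component_voxels = 10)
  expect_equal(r1$rate, 1)
  expect_equal(r1$n_components, 1L)
  # the same blob beyond the band is not flagged (shrink the band instead
  # of growing the grid: band_mm = 0 keeps only the CTV slices)
  pred2 <- truth
  blob2 <- array(FALSE, dim(truth))
  blob2[1, 4:8, 14:17] <- TRUE
  pred2[blob2] <- pred2[blob2] + 200
  r2 <- hallucinationRate(pred2, truth, ms, band_mm = 0,
                          min_component_voxels = 10)
  expect_equal(r2$rate, 0)
  expect_error(hallucinationRate(truth, truth, MaskSet(
    list(Body = getMask(ph, "Body")), spacing = voxelSpacing(ms))),
    "CTV")
})

test_that("full-grid ROI restriction reproduces whole-image metrics", {
  x <- randVol(c(6, 10, 10), 15); y <- randVol(c(6, 10, 10), 16)
  full <- array(TRUE, c(6, 10, 10))
  expect_equal(mseMetric(x, y, full), mseMetric(x, y))
  expect_equal(psnrMetric(x, y, mask = full), psnrMetric(x, y))
  expect_equal(ssimGlobal(x, y, mask = full), ssimGlobal(x, y))
})

test_that("self-evaluation of a phantom yields perfect scores everywhere", {
  ph <- tinyPhantom(seed = 17, noiseFree = TRUE)
  rep <- evaluateVolume(enhanced(ph), enhanced(ph), maskSet(ph))
  expect_s4_class(rep, "MetricReport")
  expect_true(all(rep@perRegion$mse == 0))
  expect_true(all(rep@perRegion$uqi == 1))
  expect_true(all(rep@perRegion$ssim == 1))
  expect_true(all(rep@geometry$dsc == 1))
  expect_true(all(rep@geometry$hd95_mm == 0))
  expect_equal(unname(rep@overall["mse"]), 0)
  expect_equal(rep@hallucination$rate, 0)
  expect_true(all(is.infinite(rep@perRegion$psnr)))
})
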