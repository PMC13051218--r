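test_that("default tissue table carries the cohort HU values and deltas", {
  tt <- defaultTissueTable()
  g <- function(n, col) tt[tt$name == n, col]
  expect_equal(g("vessels", "hu_noncontrast"), 46.67)
  expect_equal(g("vessels", "hu_enhanced"), 227.66)
  expect_equal(g("fat", "hu_noncontrast"), -104.24)
  expect_equal(g("vertebrae", "hu_noncontrast"), 518.86)
  expect_equal(g("marrow", "hu_enhanced") - g("marrow", "hu_noncontrast"),
               13.68)
  # enhancing tissues never de-enhance; SDs are nonnegative
  expect_gte(g("vessels", "hu_enhanced") - g("vessels", "hu_noncontrast"), 0)
  expect_true(all(tt$hu_sd >= 0))
  expect_true(all(c("bladder", "rectum", "kidney", "liver", "ctv", "air")
                  %in% tt$name))
})

test_that("noise-free phantom paints exact tissue means and deltas", {
  ph <- tinyPhantom(seed = 3, noiseFree = TRUE)
  tt <- defaultTissueTable()
  nc <- voxelData(noncontrast(ph)); en <- voxelData(enhanced(ph))
  for (pair in list(c("Vessels", "vessels"), c("Muscle", "muscle"),
                    c("Fat", "fat"), c("Vertebrae", "vertebrae"),
                    c("Marrow", "marrow"))) {
    m <- getMask(ph, pair[1])
    r <- tt[tt$name == pair[2], ]
    # independent voxel-loop recomputation of the mask mean
    s <- 0; n <- 0
    idx <- which(m)
    for (i in idx) { s <- s + nc[i]; n <- n + 1 }
    expect_equal(s / n, r$hu_noncontrast, tolerance = 1e-6)
    expect_equal(mean(en[m]), r$hu_enhanced, tolerance = 1e-6)
  }
  # vessel enhancement delta holds voxelwise, not just in the mean
  vm <- getMask(ph, "Vessels")
  expect_equal(unique(round(en[vm] - nc[vm], 9)), 227.66 - 46.67)
  expect_true(all(en[vm] - nc[vm] >= 0))
})

test_that("identical seed and config reproduce the phantom bit-identically", {
  a <- tinyPhantom(seed = 7)
  b <- tinyPhantom(seed = 7)
  expect_identical(voxelData(noncontrast(a)), voxelData(noncontrast(b)))
  expect_identical(voxelData(enhanced(a)), voxelData(enhanced(b)))
  expect_identical(maskSet(a)@masks, maskSet(b)@masks)
  d <- tinyPhantom(seed = 8)
  expect_false(identical(voxelData(noncontrast(a)),
                         voxelData(noncontrast(d))))
})

test_that("mask taxonomy: containment, binarity and declared disjointness", {
  ph <- tinyPhantom(seed = 5)
  body <- getMask(ph, "Body")
  for (nm in setdiff(maskNames(ph), "Body")) {
    m <- getMask(ph, nm)
    expect_type(m, "logical")
    expect_true(all(body[m]), info = paste(nm, "inside body"))
  }
  expect_equal(sum(getMask(ph, "Vessels") & getMask(ph, "Vertebrae")), 0)
  expect_equal(sum(getMask(ph, "Kidney_Left") & getMask(ph, "Liver")), 0)
  expect_equal(sum(getMask(ph, "Kidney_Right") & getMask(ph, "Liver")), 0)
  expect_equal(sum(getMask(ph, "Kidney_Left") & getMask(ph, "Kidney_Right")),
               0)
  # every required loss region is present and nonempty
  for (nm in kappaRegions())
    expect_gt(sum(getMask(ph, nm)), 0)
})

test_that("voxel noise perturbs tissue mask means within the CLT envelope", {
  # mean shift under sd-8 noise stays below 5*sigma/sqrt(n) across seeds
  sigma <- 8
  fails <- 0
  for (s in 1:50) {
    ph <- generatePhantom(phantomConfig(grid_shape = tinyGrid, seed = s,
                                        noise_sd_hu = sigma,
                                        bias_amplitude_hu = 0,
                                        tissue_jitter = 0,
                                        anatomy_jitter = 0))
    m <- getMask(ph, "Muscle")
    shift <- abs(mean(voxelData(noncontrast(ph))[m]) - 54.69)
    if (shift > 5 * sigma / sqrt(sum(m))) fails <- fails + 1
  }
  expect_equal(fails, 0)
})

test_that("NIfTI round trip preserves voxels at the on-disk dtype", {
  ph <- tinyPhantom(seed = 2)
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(noncontrast(ph), f)
  v1 <- readVolume(f)
  expect_equal(voxelSpacing(v1), voxelSpacing(noncontrast(ph)))
  # float32 on disk: a second round trip is bit-exact
  f2 <- tempfile(fileext = ".nii.gz")
  writeVolume(v1, f2)
  v2 <- readVolume(f2)
  expect_identical(voxelData(v1), voxelData(v2))
  expect_equal(voxelData(v1), voxelData(noncontrast(ph)), tolerance = 1e-4)
  # masks are uint8 and exact
  fm <- tempfile(fileext = ".nii.gz")
  writeVolume(getMask(ph, "CTV"), fm, spacing = voxelSpacing(maskSet(ph)))
  expect_identical(readMask(fm), getMask(ph, "CTV"))
})

test_that("dataset generation: split arithmetic, determinism, manifest", {
  d1 <- tempfile(); d2 <- tempfile()
  man1 <- generateDataset(4, phantomConfig(grid_shape = tinyGrid),
                          split = c(0.5, 0.25, 0.25), seed = 9, outDir = d1)
  man2 <- generateDataset(4, phantomConfig(grid_shape = tinyGrid),
                          split = c(0.5, 0.25, 0.25), seed = 9, outDir = d2)
  expect_equal(unlist(man1$split_counts), c(train = 2, val = 1, test = 1))
  expect_equal(vapply(man1$samples, `[[`, character(1), "split"),
               vapply(man2$samples, `[[`, character(1), "split"))
  expect_equal(vapply(man1$samples, `[[`, numeric(1), "seed"),
               vapply(man2$samples, `[[`, numeric(1), "seed"))
  # split counts at the study proportions
  expect_equal(unname(vceCT:::splitCounts(10, c(0.8, 0.1, 0.1))),
               c(8L, 1L, 1L))
  expect_equal(unname(vceCT:::splitCounts(200, c(0.9, 0.1, 0))),
               c(180L, 20L, 0L))
  # round-trip a written sample
  ph <- loadSample(man1$samples[[1]], spacing = man1$spacing_mm)
  expect_s4_class(ph, "PairedSample")
  expect_true(all(kappaRegions() %in% maskNames(ph)))
  # volumes on disk agree with a fresh regeneration at the recorded seed
  cfg <- phantomConfig(grid_shape = tinyGrid)
  cfg$seed <- man1$samples[[1]]$seed
  fresh <- generatePhantom(cfg)
  expect_equal(voxelData(noncontrast(ph)),
               voxelData(noncontrast(fresh)), tolerance = 1e-4)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("configuration errors are explicit", {
  expect_error(phantomConfig(grid_shape = c(8, 64, 64)), ">= 16")
  expect_error(phantomConfig(noise_sd_hu = -1), ">= 0")
  tt <- defaultTissueTable()
  expect_error(generatePhantom(phantomConfig(grid_shape = tinyGrid),
                               tissues = tt[tt$name != "vessels", ]),
               "missing required")
  expect_error(generateDataset(2, outDir = tempfile()), "n >= 3")
  expect_error(vceCT:::splitCounts(5, c(0.98, 0.01, 0.01)),
               "zero samples")
  bad <- tt
  bad$hu_enhanced[bad$name == "vessels"] <- 0
  expect_error(generatePhantom(phantomConfig(grid_shape = tinyGrid),
                               tissues = bad), "de-enhance")
})
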