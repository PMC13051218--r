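# Paired pelvic CT phantom simulator.
#
# Generates seeded noncontrast / venous-phase enhanced volume pairs with a
# full per-organ mask set, so the loss, metrics, model and pipeline can be
# exercised end to end without patient data. Tissue HU means and the
# venous-phase enhancement deltas for vessels, muscle, fat, vertebrae and
# bone marrow follow the cohort CT-value table; organs without published
# values carry literature-typical stand-ins (see defaultTissueTable).

#' Default tissue table
#'
#' Mean HU before contrast, mean HU at the venous phase, and the cohort
#' (between-patient) SD for each simulated tissue. Vessels, muscle, fat,
#' vertebrae and bone marrow carry measured cohort values; bladder (urine),
#' rectum wall and gas, kidney, liver, target volume and air are
#' literature-typical stand-ins and are overridable.
#'
#' @return data.frame with columns name, hu_noncontrast, hu_enhanced, hu_sd.
#' @examples
#' tt <- defaultTissueTable()
#' tt[tt$name == "vessels", ]
#' @export
defaultTissueTable <- function() {
  tt <- data.frame(
    name = c("vessels", "muscle", "fat", "vertebrae", "marrow",
             "bladder", "rectum", "rectum_gas", "kidney", "liver",
             "ctv", "air"),
    hu_noncontrast = c(46.67, 54.69, -104.24, 518.86, 53.01,
                       10, 40, -800, 32, 55, 45, -1000),
    hu_enhanced = c(227.66, 57.34, -100.28, 519.64, 66.69,
                    10, 40, -800, 92, 100, 70, -1000),
    hu_sd = c(5.58, 6.39, 3.60, 164.38, 20.48,
              5, 5, 20, 8, 7, 8, 0),
    stringsAsFactors = FALSE
  )
  validateTissueTable(tt)
  tt
}

requiredTissues <- function() {
  c("vessels", "muscle", "fat", "vertebrae", "marrow", "bladder",
    "rectum", "rectum_gas", "kidney", "liver", "ctv", "air")
}

validateTissueTable <- function(tt) {
  need <- c("name", "hu_noncontrast", "hu_enhanced", "hu_sd")
  if (!all(need %in% names(tt))) stop("tissue table lacks required columns")
  if (any(tt$hu_sd < 0)) stop("hu_sd must be >= 0")
  for (enh in intersect(c("vessels", "marrow"), tt$name)) {
    r <- tt[tt$name == enh, ]
    if (r$hu_enhanced - r$hu_noncontrast < 0)
      stop("tissue '", enh, "' must not de-enhance (delta < 0)")
  }
  invisible(tt)
}

#' Phantom generation configuration
#'
#' @param grid_shape voxels per (z, y, x) axis; each >= 16.
#' @param spacing_mm voxel size per axis, mm.
#' @param noise_sd_hu additive Gaussian voxel noise SD, independent between
#'   the two volumes of a pair.
#' @param bias_amplitude_hu amplitude of the smooth low-frequency additive
#'   bias field shared by the pair (patient-scale inhomogeneity).
#' @param anatomy_jitter fractional randomisation of organ positions/sizes.
#' @param tissue_jitter scales per-sample tissue-mean draws: each tissue
#'   mean is offset by N(0, hu_sd * tissue_jitter), identically in both
#'   volumes (cohort variation; enhancement deltas are preserved). Set 0
#'   for exact table means.
#' @param seed RNG seed; identical seed + config reproduce the phantom
#'   bit-identically.
#' @return validated list of class \code{phantomConfig}.
#' @export
phantomConfig <- function(grid_shape = c(32, 128, 128),
                          spacing_mm = c(3, 1.5, 1.5),
                          noise_sd_hu = 8,
                          bias_amplitude_hu = 10,
                          anatomy_jitter = 0.05,
                          tissue_jitter = 1,
                          seed = 1L) {
  if (length(grid_shape) != 3L || any(grid_shape < 16))
    stop("grid_shape must be 3 values, each >= 16")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive values")
  if (noise_sd_hu < 0) stop("noise_sd_hu must be >= 0")
  if (bias_amplitude_hu < 0) stop("bias_amplitude_hu must be >= 0")
  if (anatomy_jitter < 0 || anatomy_jitter > 0.3)
    stop("anatomy_jitter must lie in [0, 0.3]")
  if (tissue_jitter < 0) stop("tissue_jitter must be >= 0")
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 noise_sd_hu = noise_sd_hu,
                 bias_amplitude_hu = bias_amplitude_hu,
                 anatomy_jitter = anatomy_jitter,
                 tissue_jitter = tissue_jitter,
                 seed = as.integer(seed)),
            class = "phantomConfig")
}

#' Noise-free phantom configuration
#'
#' Convenience wrapper: zero voxel noise, zero bias field and exact tissue
#' table means, so per-tissue mask means match the table to floating
#' tolerance.
#' @param ... passed to \code{\link{phantomConfig}}.
#' @export
noiseFreeConfig <- function(...) {
  phantomConfig(noise_sd_hu = 0, bias_amplitude_hu = 0, tissue_jitter = 0,
                ...)
}

# Structure layout in fractional grid coordinates. u = y/Y, v = x/X,
# w = z/Z; in-plane radii are fractions of min(Y, X).
phantomLayout <- function() {
  list(
    body      = list(cu = 0.50, cv = 0.50, su = 0.40, sv = 0.46),
    muscle_in = 0.86,                                     # inner-ellipse scale
    vertebrae = list(cu = 0.80, cv = 0.50, r = 0.075),
    marrow    = list(cu = 0.80, cv = 0.50, r = 0.040),
    vessel_l  = list(cu = 0.58, cv = 0.36, r = 0.030),
    vessel_r  = list(cu = 0.58, cv = 0.64, r = 0.030),
    rectum    = list(cu = 0.655, cv = 0.50, r = 0.045, gas_r = 0.020),
    bladder   = list(cu = 0.38, cv = 0.50, su = 0.08, sv = 0.10,
                     cw = 0.55, sw = 0.25),
    kidney_l  = list(cu = 0.60, cv = 0.20, su = 0.07, sv = 0.055,
                     cw = 0.55, sw = 0.20),
    kidney_r  = list(cu = 0.60, cv = 0.80, su = 0.07, sv = 0.055,
                     cw = 0.55, sw = 0.20),
    liver     = list(cu = 0.42, cv = 0.30, su = 0.13, sv = 0.15,
                     cw = 0.10, sw = 0.16),
    ctv       = list(cu = 0.54, cv = 0.50, r = 0.050, cw = 0.50, sw = 0.18)
  )
}

#' Generate one paired phantom
#'
#' Builds the anatomy (elliptical body with a fat rind and muscle interior,
#' posterior vertebral column with a marrow core, paraspinal vessel tubes,
#' bladder, rectum with a gas pocket, bilateral kidneys, a superior liver
#' cap and a midline target volume), paints per-tissue HU, adds the
#' venous-phase enhancement deltas to the enhanced copy, then applies a
#' shared smooth bias field and independent voxel noise. Deterministic
#' given the config seed.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @param tissues tissue table, see \code{\link{defaultTissueTable}}.
#' @return a \code{PairedSample}; \code{provenance} holds the config, the
#'   realised (jittered) geometry in voxel units, and the tissue means used.
#' @export
generatePhantom <- function(config = phantomConfig(),
                            tissues = defaultTissueTable()) {
  if (!inherits(config, "phantomConfig")) stop("config must be a phantomConfig")
  validateTissueTable(tissues)
  missing <- setdiff(requiredTissues(), tissues$name)
  if (length(missing))
    stop("tissue table missing required label(s): ",
         paste(missing, collapse = ", "))
  d <- config$grid_shape
  Z <- d[1]; Y <- d[2]; X <- d[3]
  if (min(Y, X) < 24)
    stop("in-plane grid too small to place the anatomy (need >= 24 voxels)")

  withSeed(config$seed, {
    jit <- config$anatomy_jitter
    L <- phantomLayout()
    jshift <- function(c0, r) c0 + jit * r * runif(1, -1, 1)
    jscale <- function(r) r * (1 + jit * runif(1, -1, 1))
    # realised geometry (fractional), drawn in a fixed order
    geo <- list()
    geo$body <- list(cu = jshift(L$body$cu, 0.02), cv = jshift(L$body$cv, 0.02),
                     su = jscale(L$body$su), sv = jscale(L$body$sv))
    for (nm in c("vertebrae", "marrow", "vessel_l", "vessel_r", "rectum",
                 "ctv")) {
      s <- L[[nm]]
      g <- list(cu = jshift(s$cu, s$r), cv = jshift(s$cv, s$r),
                r = jscale(s$r))
      if (!is.null(s$gas_r)) g$gas_r <- jscale(s$gas_r)
      if (!is.null(s$cw)) { g$cw <- jshift(s$cw, s$sw); g$sw <- jscale(s$sw) }
      geo[[nm]] <- g
    }
    # marrow shares the vertebral centre
    geo$marrow$cu <- geo$vertebrae$cu; geo$marrow$cv <- geo$vertebrae$cv
    for (nm in c("bladder", "kidney_l", "kidney_r", "liver")) {
      s <- L[[nm]]
      geo[[nm]] <- list(cu = jshift(s$cu, s$su), cv = jshift(s$cv, s$sv),
                        su = jscale(s$su), sv = jscale(s$sv),
                        cw = jshift(s$cw, s$sw), sw = jscale(s$sw))
    }

    # per-sample tissue-mean offsets (cohort variation), delta-preserving
    off <- setNames(rnorm(nrow(tissues), 0,
                          tissues$hu_sd * config$tissue_jitter),
                    tissues$name)

    # coordinate grids, voxel centres in fractional units
    zg <- array(rep(seq_len(Z), times = Y * X), d) / Z - 0.5 / Z
    yg <- array(rep(rep(seq_len(Y), each = Z), times = X), d) / Y - 0.5 / Y
    xg <- array(rep(seq_len(X), each = Z * Y), d) / X - 0.5 / X

    inEllipse2 <- function(g) {
      ((yg - g$cu) / g$su)^2 + ((xg - g$cv) / g$sv)^2 <= 1
    }
    inTube <- function(g) (yg - g$cu)^2 + (xg - g$cv)^2 <= g$r^2
    inEllipsoid <- function(g) {
      ((zg - g$cw) / g$sw)^2 + ((yg - g$cu) / g$su)^2 +
        ((xg - g$cv) / g$sv)^2 <= 1
    }
    inBlob <- function(g) {
      ((zg - g$cw) / g$sw)^2 + (yg - g$cu)^2 / g$r^2 +
        (xg - g$cv)^2 / g$r^2 <= 1
    }

    body <- inEllipse2(geo$body)
    inner <- inEllipse2(list(cu = geo$body$cu, cv = geo$body$cv,
                             su = geo$body$su * L$muscle_in,
                             sv = geo$body$sv * L$muscle_in))
    lab <- array("air", d)
    lab[body] <- "fat"
    lab[inner] <- "muscle"
    lab[inTube(geo$vertebrae)] <- "vertebrae"
    lab[inTube(geo$marrow)] <- "marrow"
    vesselL <- inTube(geo$vessel_l); vesselR <- inTube(geo$vessel_r)
    lab[vesselL | vesselR] <- "vessels"
    kidL <- inEllipsoid(geo$kidney_l); kidR <- inEllipsoid(geo$kidney_r)
    lab[kidL] <- "kidney"; lab[kidR] <- "kidney"
    liver <- inEllipsoid(geo$liver)
    lab[liver] <- "liver"
    bladder <- inEllipsoid(geo$bladder)
    lab[bladder] <- "bladder"
    rectumAll <- inTube(geo$rectum)
    gas <- inTube(list(cu = geo$rectum$cu, cv = geo$rectum$cv,
                       r = geo$rectum$gas_r))
    lab[rectumAll] <- "rectum"
    lab[gas] <- "rectum_gas"
    ctv <- inBlob(geo$ctv)
    lab[ctv] <- "ctv"

    if (!any(lab == "vessels") || !any(lab == "ctv"))
      stop("grid too small: could not place the vessel tubes / target volume")

    hu0 <- setNames(tissues$hu_noncontrast + off, tissues$name)
    hu1 <- setNames(tissues$hu_enhanced + off, tissues$name)
    nc <- array(hu0[lab], d)
    en <- array(hu1[lab], d)

    if (config$bias_amplitude_hu > 0) {
      nbases <- 3L
      bias <- array(0, d)
      for (i in seq_len(nbases)) {
        f <- runif(3, 0.3, 1.2); ph <- runif(1, 0, 2 * pi)
        bias <- bias + runif(1, 0.5, 1) *
          cos(2 * pi * (f[1] * zg + f[2] * yg + f[3] * xg) + ph)
      }
      bias <- bias / max(abs(bias)) * config$bias_amplitude_hu
      nc <- nc + bias; en <- en + bias
    }
    if (config$noise_sd_hu > 0) {
      nc <- nc + array(rnorm(length(nc), 0, config$noise_sd_hu), d)
      en <- en + array(rnorm(length(en), 0, config$noise_sd_hu), d)
    }

    masks <- list(
      Body = body,
      Muscle = lab == "muscle", Fat = lab == "fat",
      Vertebrae = lab == "vertebrae", Marrow = lab == "marrow",
      Vessels = lab == "vessels",
      Kidney_Left = lab == "kidney" & kidL,
      Kidney_Right = lab == "kidney" & kidR,
      Liver = lab == "liver",
      Bladder = lab == "bladder",
      Rectum = rectumAll,
      CTV = lab == "ctv"
    )

    sp <- config$spacing_mm
    prov <- list(config = config, geometry = geo,
                 tissue_means = list(noncontrast = hu0, enhanced = hu1),
                 label_counts = table(lab))
    PairedSample(CTVolume(nc, spacing = sp), CTVolume(en, spacing = sp),
                 MaskSet(masks, spacing = sp), provenance = prov)
  })
}

#' Generate a phantom dataset with a train/validation/test split
#'
#' Writes n paired samples as NIfTI files (volumes float32, masks uint8)
#' under \code{outDir} plus a JSON manifest assigning each sample to a
#' split. Per-sample anatomy and tissue-mean jitter draw from a seeded
#' stream, so the same seed reproduces the manifest and every volume.
#'
#' @param n number of samples (>= 3).
#' @param config base \code{\link{phantomConfig}}; each sample derives its
#'   own seed from \code{seed}.
#' @param split fractions (train, val, test) summing to 1.
#' @param seed dataset-level seed.
#' @param outDir output directory, created if needed.
#' @param tissues tissue table.
#' @return the manifest (invisibly also written to
#'   \code{outDir/manifest.json}).
#' @export
generateDataset <- function(n, config = phantomConfig(),
                            split = c(train = 0.9, val = 0.1, test = 0),
                            seed = config$seed, outDir,
                            tissues = defaultTissueTable()) {
  if (n < 3) stop("need n >= 3 samples")
  if (abs(sum(split) - 1) > 1e-9) stop("split fractions must sum to 1")
  counts <- splitCounts(n, split)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  assign_ <- rep(c("train", "val", "test"), times = counts)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- deriveSeed(seed, paste0("sample", i))
    ph <- generatePhantom(cfg_i, tissues = tissues)
    id <- sprintf("sample_%03d", i)
    ncf <- file.path(outDir, paste0(id, "_noncontrast.nii.gz"))
    enf <- file.path(outDir, paste0(id, "_enhanced.nii.gz"))
    writeVolume(noncontrast(ph), ncf)
    writeVolume(enhanced(ph), enf)
    mdir <- file.path(outDir, paste0(id, "_masks"))
    dir.create(mdir, showWarnings = FALSE)
    mfiles <- list()
    for (nm in maskNames(ph)) {
      mf <- file.path(mdir, paste0(nm, ".nii.gz"))
      writeVolume(getMask(ph, nm), mf, spacing = voxelSpacing(maskSet(ph)))
      mfiles[[nm]] <- mf
    }
    samples[[i]] <- list(id = id, split = assign_[i], seed = cfg_i$seed,
                         noncontrast = ncf, enhanced = enf, masks = mfiles)
  }
  manifest <- list(n = n, seed = seed,
                   split_counts = as.list(counts),
                   config = unclass(config),
                   config_hash = configHash(config),
                   spacing_mm = config$spacing_mm,
                   samples = samples)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

splitCounts <- function(n, split) {
  if (length(split) != 3L) stop("split must have 3 fractions")
  base <- floor(n * split)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * split - base
    ord <- order(frac, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  if (any(split > 0 & base == 0))
    stop("split rounding left a nonzero fraction with zero samples")
  counts <- as.integer(base)
  names(counts) <- c("train", "val", "test")
  counts
}

configHash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Read a dataset manifest
#' @param path manifest.json path or its directory.
#' @return manifest list.
#' @export
readManifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Load one manifest sample as a PairedSample
#' @param sample one element of \code{manifest$samples}.
#' @param spacing voxel spacing recorded in the manifest.
#' @return a \code{PairedSample}.
#' @export
loadSample <- function(sample, spacing = c(3, 1.5, 1.5)) {
  spacing <- as.numeric(spacing)
  nc <- readVolume(sample$noncontrast)
  en <- readVolume(sample$enhanced)
  masks <- lapply(sample$masks, readMask)
  PairedSample(nc, en, MaskSet(masks, spacing = spacing),
               provenance = list(id = sample$id, seed = sample$seed))
}
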