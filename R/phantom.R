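#' @include AllClasses.R
NULL

# Geometry helpers ------------------------------------------------------------

.ellipseMask <- function(s, centerRow, centerCol, semiRow, semiCol) {
  r <- matrix(seq_len(s), s, s)
  c <- matrix(seq_len(s), s, s, byrow = TRUE)
  ((r - centerRow) / semiRow)^2 + ((c - centerCol) / semiCol)^2 <= 1
}

.discMask <- function(s, centerRow, centerCol, radius) {
  .ellipseMask(s, centerRow, centerCol, radius, radius)
}

.bboxOf <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  as.integer(c(min(w[, 1]), min(w[, 2]), max(w[, 1]), max(w[, 2])))
}

# Class signatures -------------------------------------------------------------
# Each returns a logical mask of pixels to shift by +/- signalContrast.
# `side` is -1 (left lung) or +1 (right lung); lung centres are at columns
# 0.30*s and 0.70*s, rows centred on 0.42*s with semi-axes (0.30*s, 0.17*s).

.lungCenterCol <- function(s, side, pose) (0.5 + side * 0.20) * s + pose$jc

# pose: per-image anatomical jitter (global row/col shift jr/jc in pixels,
# lung scale js) emulating patient positioning variability.
# Returns NULL or list(mask = logical matrix of modified pixels,
# units = numeric matrix of per-pixel intensity shift in units of
# signalContrast).
.signatureMask <- function(label, s, side, pose) {
  jr <- pose$jr; jc <- pose$jc; js <- pose$js
  asUnits <- function(m, u = 1) list(mask = m, units = m * u)
  switch(label,
    "No Finding" = NULL,
    "Cardiomegaly" = asUnits(.ellipseMask(s, 0.58 * s + jr, 0.50 * s + jc,
                                          0.14 * s * js, 0.18 * s * js)),
    "Effusion" = {
      # bright basal wedge (lower third of a slightly shrunken lung
      # ellipse) topped by a brighter fluid meniscus line
      cc <- .lungCenterCol(s, side, pose)
      inner <- .ellipseMask(s, 0.42 * s + jr, cc, 0.24 * s * js, 0.13 * s * js)
      r <- matrix(seq_len(s), s, s)
      top <- 0.42 * s + jr + 0.05 * s * js
      wedge <- inner & (r >= top)
      # meniscus crosses the lung boundary into the costophrenic angle
      wide <- .ellipseMask(s, 0.42 * s + jr, cc, 0.24 * s * js, 0.19 * s * js)
      line <- wide & (r >= top) & (r <= top + max(2, 0.02 * s))
      list(mask = wedge | line, units = wedge * 1 + line * 1)
    },
    "Pneumothorax" = {
      # lucent crescent over the lung apex bounded below by a bright
      # visceral pleural line
      cc <- .lungCenterCol(s, side, pose)
      outer <- .discMask(s, 0.27 * s + jr, cc, 0.15 * s * js)
      lowC <- c(0.37 * s + jr, cc)
      lowR <- 0.15 * s * js
      lower <- .discMask(s, lowC[1], lowC[2], lowR)
      rm <- matrix(seq_len(s), s, s)
      cm <- matrix(seq_len(s), s, s, byrow = TRUE)
      dist <- sqrt((rm - lowC[1])^2 + (cm - lowC[2])^2)
      pline <- outer | .discMask(s, 0.27 * s + jr, cc, 0.16 * s * js)
      pline <- pline & abs(dist - lowR) <= max(1.2, 0.009 * s) & rm < lowC[1]
      crescent <- outer & !lower & !pline
      list(mask = crescent | pline, units = crescent * -1 + pline * 1.2)
    },
    "Pneumonia" = {
      # 3-6 overlapping bright blobs clustered inside one lung field
      cc <- .lungCenterCol(s, side, pose) + runif(1, -0.03, 0.03) * s
      cr <- runif(1, 0.32, 0.50) * s + jr
      k <- sample(3:6, 1)
      m <- matrix(FALSE, s, s)
      for (i in seq_len(k)) {
        br <- cr + runif(1, -0.06, 0.06) * s
        bc <- cc + runif(1, -0.05, 0.05) * s
        rad <- runif(1, 0.06, 0.085) * s * js
        m <- m | .discMask(s, br, bc, rad)
      }
      asUnits(m)
    },
    stop("unreachable"))
}

#' Generate one synthetic radiograph phantom
#'
#' Builds a radiograph-like grayscale image: a smooth vertical intensity
#' gradient with per-image exposure jitter, two darker elliptical lung
#' fields, a bright bottom band emulating the dense diaphragm/abdomen
#' region, a planted class-specific signature, and additive Gaussian
#' noise.  Signatures are: Cardiomegaly, an enlarged bright ellipse at the
#' lower middle (cardiac silhouette); Effusion, a bright basal wedge in
#' one lung field; Pneumothorax, a dark crescent at one lung apex;
#' Pneumonia, 3--6 clustered bright blobs in one lung field; No Finding
#' plants nothing.  The affected lung side is chosen by the RNG and the
#' tight bounding box of the modified pixels is recorded, along with the
#' exact modification mask, so downstream localisation tests are
#' side-agnostic.
#'
#' The diaphragm band intensity is drawn in `[0.92, 1] * 255` while all
#' other content is capped well below it, so an intensity threshold at
#' 90% of the dynamic range isolates the band by construction.  Output is
#' deterministic given the spec (which includes the seed).
#'
#' @param spec a [PhantomSpec-class], or a label string (other parameters
#'   then taken as [phantomSpec()] defaults via `...`).
#' @param ... passed to [phantomSpec()] when `spec` is a label string.
#' @return A [PhantomImage-class].
#' @examples
#' ph <- generatePhantom(phantomSpec("Effusion", imageSize = 64, seed = 3))
#' signatureBbox(ph)
#' @export
generatePhantom <- function(spec, ...) {
  if (is.character(spec)) spec <- phantomSpec(spec, ...)
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  s <- spec@imageSize
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec@seed)

  bandH <- max(1L, as.integer(round(spec@diaphragmHeightFrac * s)))
  bandRows <- (s - bandH + 1L):s

  # background: vertical gradient with exposure jitter
  nb <- s - bandH
  grad <- 95 + (155 - 95) * (seq_len(s) - 1) / max(1, nb - 1)
  img <- matrix(rep(grad, s), s, s)
  gain <- runif(1, 0.85, 1.15)
  offset <- runif(1, -15, 15)
  img <- gain * img + offset

  # low-frequency intensity clouds (soft-tissue / exposure field variation);
  # these decorrelate global image statistics from the planted signature so
  # class evidence stays local
  rr <- matrix(seq_len(s), s, s)
  cc2 <- matrix(seq_len(s), s, s, byrow = TRUE)
  for (i in 1:6) {
    amp <- runif(1, -12, 12)
    cr <- runif(1, 0.05, 0.95) * s
    ccl <- runif(1, 0.05, 0.95) * s
    sg <- runif(1, 0.15, 0.30) * s
    img <- img + amp * exp(-((rr - cr)^2 + (cc2 - ccl)^2) / (2 * sg^2))
  }

  # anatomical pose jitter (patient positioning): global shift and lung scale
  pose <- list(jr = runif(1, -0.03, 0.03) * s,
               jc = runif(1, -0.04, 0.04) * s,
               js = runif(1, 0.92, 1.08))

  # lung fields (darker ellipses)
  lungL <- .ellipseMask(s, 0.42 * s + pose$jr, 0.30 * s + pose$jc,
                        0.30 * s * pose$js, 0.17 * s * pose$js)
  lungR <- .ellipseMask(s, 0.42 * s + pose$jr, 0.70 * s + pose$jc,
                        0.30 * s * pose$js, 0.17 * s * pose$js)
  img[lungL | lungR] <- img[lungL | lungR] - 40

  # class signature
  side <- if (runif(1) < 0.5) -1 else 1
  sigRes <- .signatureMask(spec@label, s, side, pose)
  sig <- NULL
  if (!is.null(sigRes)) {
    sig <- sigRes$mask
    units <- sigRes$units
    sig[bandRows, ] <- FALSE
    units[bandRows, ] <- 0
    img <- img + units * spec@signalContrast
  }

  # cap everything outside the band below the diaphragm intensity range
  img <- pmin(img, 0.85 * 255)
  img[img < 0] <- 0

  # diaphragm band near the image maximum, with a soft dome transition
  # above it (the recorded diaphragm bbox covers the full-intensity band)
  bandLevel <- runif(1, 0.92, 1.0) * 255
  rampH <- max(1L, as.integer(round(0.04 * s)))
  rampRows <- pmax(1L, (s - bandH - rampH + 1L):(s - bandH))
  wgt <- seq_len(length(rampRows)) / (length(rampRows) + 1L)
  img[rampRows, ] <- img[rampRows, ] * (1 - wgt) + bandLevel * wgt
  img[bandRows, ] <- bandLevel

  # noise, clip, quantise to 8-bit levels
  if (spec@noiseSd > 0) img <- img + rnorm(s * s, 0, spec@noiseSd)
  img <- round(.clip(img, 0, 255))

  new("PhantomImage",
      pixels = img,
      label = spec@label,
      signatureBbox = if (is.null(sig) || !any(sig)) integer(0) else .bboxOf(sig),
      diaphragmBbox = as.integer(c(s - bandH + 1L, 1L, s, s)),
      signatureMask = if (is.null(sig)) matrix(FALSE, 0, 0) else sig,
      lungMask = lungL | lungR,
      spec = spec)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a grayscale matrix as an 8-bit PNG
#'
#' @param pixels numeric matrix with values in 0--255.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGrayPng <- function(pixels, path) {
  img <- EBImage::Image(t(pixels) / 255, colormode = EBImage::Grayscale)
  EBImage::writeImage(img, path, type = "png", bits.per.sample = 8L)
  invisible(path)
}

#' Read an image file as a grayscale intensity matrix
#'
#' Reads PNG/JPEG/TIFF; colour images are converted to luminance with
#' weights 0.299/0.587/0.114.  Values are returned on the 0--255 scale as
#' a matrix indexed `[row, col]`.
#'
#' @param path image file path.
#' @return numeric matrix, values in 0--255.
#' @export
readGrayImage <- function(path) {
  img <- tryCatch(EBImage::readImage(path), error = function(e)
    stop("io: failed to read image '", path, "': ", conditionMessage(e),
         call. = FALSE))
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3L) {
    nch <- dim(d)[3]
    d <- if (nch >= 3L)
      0.299 * d[, , 1] + 0.587 * d[, , 2] + 0.114 * d[, , 3]
    else d[, , 1]
  }
  t(d) * 255
}

#' Generate a phantom dataset on disk
#'
#' Writes PNG phantoms in a folder-per-class layout under `outDir`
#' together with a CSV manifest (`manifest.csv`, columns `path,label`).
#' Per-image seeds are derived deterministically from the master seed, so
#' repeated calls produce identical files.
#'
#' @param nPerClass named integer vector, images per class; every name
#'   must be a valid class label.  Unnamed scalar means that many per
#'   class for all five classes.
#' @param seed master integer seed.
#' @param outDir output directory (created if needed).
#' @param imageSize,signalContrast,noiseSd passed to [phantomSpec()].
#' @return The manifest as a data.frame with columns `path`, `label`
#'   (invisibly also written to `outDir/manifest.csv`).
#' @examples
#' \donttest{
#' d <- tempfile()
#' mf <- generatePhantomDataset(c("No Finding" = 2, "Pneumonia" = 2),
#'                              seed = 3, outDir = d, imageSize = 64)
#' nrow(mf)
#' }
#' @export
generatePhantomDataset <- function(nPerClass, seed, outDir,
                                   imageSize = 224L, signalContrast = 60,
                                   noiseSd = 8) {
  if (is.null(names(nPerClass))) {
    stopifnot(length(nPerClass) == 1L)
    nPerClass <- stats::setNames(rep(nPerClass, 5), cxrClasses())
  }
  for (lb in names(nPerClass)) .checkLabel(lb)
  stopifnot(all(nPerClass >= 0))
  ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir))
    stop("io: cannot create output directory '", outDir, "'", call. = FALSE)

  rows <- list()
  k <- 0L
  for (lb in names(nPerClass)) {
    n <- nPerClass[[lb]]
    if (n == 0) next
    clsDir <- file.path(outDir, gsub(" ", "_", lb))
    dir.create(clsDir, showWarnings = FALSE)
    for (i in seq_len(n)) {
      k <- k + 1L
      sp <- phantomSpec(lb, imageSize = imageSize,
                        signalContrast = signalContrast, noiseSd = noiseSd,
                        seed = .deriveSeed(seed, k))
      ph <- generatePhantom(sp)
      p <- file.path(clsDir, sprintf("%s_%04d.png", gsub(" ", "_", lb), i))
      writeGrayPng(pixels(ph), p)
      rows[[k]] <- data.frame(path = p, label = lb, stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(), label = character())
  write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Read a dataset manifest CSV
#'
#' @param path CSV with at least columns `path` and `label`.
#' @return data.frame.
#' @export
readManifest <- function(path) {
  mf <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(mf)))
    stop("manifest must have columns 'path' and 'label'", call. = FALSE)
  mf
}
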