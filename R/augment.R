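#' @include AllClasses.R
NULL

#' Augmentation policy
#'
#' The stochastic transform chain applied to each source image:
#' independent 50% horizontal and vertical flips, rotation uniform in
#' [-15, 15] degrees, translation uniform up to 5% of the side per axis,
#' and random crop-and-resize to 90--100% of the side length.  For
#' classes with low original representation the extended transforms are
#' enabled: zoom and brightness/contrast adjustment, each up to 10%.
#'
#' @param flipProb probability of each flip (default 0.5).
#' @param rotationRange degrees, `c(min, max)` (default c(-15, 15)).
#' @param translateFrac maximum shift per axis as a fraction of the side
#'   (default 0.05).
#' @param cropRange crop side as a fraction of the image side (default
#'   c(0.9, 1)).
#' @param extended enable zoom and brightness/contrast transforms.
#' @param zoomRange zoom factor range (default c(0.9, 1.1)).
#' @param bcRange brightness/contrast scale range (default c(0.9, 1.1)).
#' @return list of class `AugmentPolicy`.
#' @export
augmentPolicy <- function(flipProb = 0.5, rotationRange = c(-15, 15),
                          translateFrac = 0.05, cropRange = c(0.9, 1),
                          extended = FALSE, zoomRange = c(0.9, 1.1),
                          bcRange = c(0.9, 1.1)) {
  stopifnot(flipProb >= 0, flipProb <= 1, translateFrac >= 0,
            translateFrac <= 1, rotationRange[1] == -rotationRange[2] ||
              diff(rotationRange) >= 0)
  structure(list(flipProb = flipProb, rotationRange = rotationRange,
                 translateFrac = translateFrac, cropRange = cropRange,
                 extended = extended, zoomRange = zoomRange,
                 bcRange = bcRange),
            class = "AugmentPolicy")
}

#' Plan class-balancing augmentation
#'
#' For each class the number of augmented samples to generate is the
#' shortfall relative to the reference class:
#' `plan[c] = max(0, counts[reference] - counts[c])`, so after execution
#' every class matches the reference count.  Classes whose original
#' count is below `extendedThreshold` times the reference count get the
#' extended transforms enabled.
#'
#' @param counts named numeric vector of original per-class counts.
#' @param reference reference class name (default "No Finding").
#' @param extendedThreshold fraction of the reference count below which
#'   extended transforms are switched on (default 0.5).
#' @return An [AugmentationPlan-class].
#' @examples
#' planBalancing(c("No Finding" = 5600, "Cardiomegaly" = 1668))
#' @export
planBalancing <- function(counts, reference = "No Finding",
                          extendedThreshold = 0.5) {
  if (is.null(names(counts)) || !reference %in% names(counts))
    stop("reference class '", reference, "' missing from counts",
         call. = FALSE)
  stopifnot(all(counts >= 0))
  ref <- counts[[reference]]
  if (ref <= 0) stop("reference class count must be > 0", call. = FALSE)
  plan <- pmax(ref - counts, 0)
  extended <- counts < extendedThreshold * ref
  extended[reference] <- FALSE
  new("AugmentationPlan", counts = counts, reference = reference,
      plan = plan, extended = extended)
}

# geometric helpers on [row, col] matrices, 0-255 scale ----------------------

.rotateImage <- function(pixels, angle) {
  if (angle == 0) return(pixels)
  out <- EBImage::rotate(.asEB(pixels / 255), angle, filter = "bilinear",
                         output.dim = rev(dim(t(pixels))), bg.col = 0)
  .clip(.fromEB(out) * 255, 0, 255)
}

.translateImage <- function(pixels, dr, dc) {
  if (dr == 0 && dc == 0) return(pixels)
  out <- EBImage::translate(.asEB(pixels / 255), c(dc, dr), bg.col = 0)
  .clip(.fromEB(out) * 255, 0, 255)
}

.cropResize <- function(pixels, frac, r0frac, c0frac) {
  if (frac >= 1) return(pixels)
  nr <- nrow(pixels); nc <- ncol(pixels)
  h <- max(1L, round(frac * nr)); w <- max(1L, round(frac * nc))
  r0 <- 1L + round(r0frac * (nr - h)); c0 <- 1L + round(c0frac * (nc - w))
  resizeGray(pixels[r0:(r0 + h - 1L), c0:(c0 + w - 1L), drop = FALSE], nr)
}

.zoomImage <- function(pixels, factor) {
  if (factor == 1) return(pixels)
  nr <- nrow(pixels)
  big <- max(2L, round(nr * factor))
  z <- resizeGray(pixels, big)
  if (factor > 1) {                       # zoom in: centre crop
    off <- (big - nr) %/% 2L
    z[off + seq_len(nr), off + seq_len(nr), drop = FALSE]
  } else {                                # zoom out: centre pad with black
    out <- matrix(0, nr, nr)
    off <- (nr - big) %/% 2L
    out[off + seq_len(big), off + seq_len(big)] <- z
    out
  }
}

#' Apply one random augmentation chain
#'
#' Samples one transform chain from the policy using the current RNG
#' state (seed externally for determinism) and applies it: flips,
#' rotation, translation, crop-and-resize, and -- if
#' `policy$extended` -- zoom and brightness/contrast scaling.  Output
#' has the input's shape with intensities clipped to [0, 255].  A policy
#' with zero probabilities and degenerate ranges returns the input
#' unchanged.
#'
#' @param pixels numeric matrix, 0--255.
#' @param policy an [augmentPolicy()].
#' @return numeric matrix of the same shape.
#' @export
randomAugment <- function(pixels, policy = augmentPolicy()) {
  stopifnot(inherits(policy, "AugmentPolicy"))
  out <- pixels
  if (policy$flipProb > 0 && runif(1) < policy$flipProb)
    out <- out[, rev(seq_len(ncol(out))), drop = FALSE]   # horizontal flip
  if (policy$flipProb > 0 && runif(1) < policy$flipProb)
    out <- out[rev(seq_len(nrow(out))), , drop = FALSE]   # vertical flip
  angle <- runif(1, policy$rotationRange[1], policy$rotationRange[2])
  out <- .rotateImage(out, angle)
  if (policy$translateFrac > 0) {
    dr <- round(runif(1, -policy$translateFrac, policy$translateFrac) * nrow(out))
    dc <- round(runif(1, -policy$translateFrac, policy$translateFrac) * ncol(out))
    out <- .translateImage(out, dr, dc)
  }
  cropFrac <- runif(1, policy$cropRange[1], policy$cropRange[2])
  if (cropFrac < 1)
    out <- .cropResize(out, cropFrac, runif(1), runif(1))
  if (isTRUE(policy$extended)) {
    out <- .zoomImage(out, runif(1, policy$zoomRange[1], policy$zoomRange[2]))
    cf <- runif(1, policy$bcRange[1], policy$bcRange[2])
    bf <- runif(1, policy$bcRange[1] - 1, policy$bcRange[2] - 1) * 255
    out <- cf * (out - 127.5) + 127.5 + bf
  }
  .clip(out, 0, 255)
}

#' Execute a class-balancing augmentation plan
#'
#' Generates `plan[c]` augmented images per class by cycling
#' round-robin over the class's original images (so per-source
#' multiplicities differ by at most one), applying [randomAugment()]
#' with a per-image seed derived from the master seed.  Classes flagged
#' for extended transforms use the extended policy.  When the manifest
#' carries a `partition` column, only `partition == "train"` rows are
#' used as sources (augmenting test data would leak it into training);
#' generated rows inherit the source's partition.
#'
#' @param manifest data.frame with `path`, `label` (optionally
#'   `partition`).
#' @param plan an [AugmentationPlan-class] (classes must exist in the
#'   manifest).
#' @param policy base [augmentPolicy()].
#' @param seed master seed.
#' @param outDir directory for the augmented PNGs.
#' @return The extended manifest with an `augmented` column (0 original,
#'   1 generated) and a `source` column giving the source path of
#'   generated rows.
#' @export
executePlan <- function(manifest, plan, policy = augmentPolicy(), seed = 1L,
                        outDir) {
  stopifnot(is(plan, "AugmentationPlan"))
  mf <- manifest
  if (is.null(mf$augmented)) mf$augmented <- 0L
  if (is.null(mf$source)) mf$source <- NA_character_
  pool <- if (!is.null(mf$partition)) mf[mf$partition == "train", ] else mf
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  newRows <- list(); k <- 0L
  for (cls in names(plan@plan)) {
    nNew <- plan@plan[[cls]]
    if (nNew == 0) next
    src <- pool[pool$label == cls & pool$augmented == 0L, ]
    if (nrow(src) == 0L)
      stop("cannot augment class '", cls, "': no source images",
           call. = FALSE)
    pol <- policy
    pol$extended <- isTRUE(plan@extended[[cls]])
    clsDir <- file.path(outDir, gsub(" ", "_", cls))
    dir.create(clsDir, showWarnings = FALSE)
    for (i in seq_len(nNew)) {
      k <- k + 1L
      row <- src[((i - 1L) %% nrow(src)) + 1L, ]
      old <- .Random.seed_save()
      set.seed(.deriveSeed(seed, k))
      img <- randomAugment(readGrayImage(row$path), pol)
      .Random.seed_restore(old)
      p <- file.path(clsDir, sprintf("aug_%s_%05d.png", gsub(" ", "_", cls), i))
      writeGrayPng(round(img), p)
      newRow <- row
      newRow$path <- p
      newRow$augmented <- 1L
      newRow$source <- row$path
      newRows[[k]] <- newRow
    }
  }
  if (length(newRows)) mf <- rbind(mf, do.call(rbind, newRows))
  rownames(mf) <- NULL
  mf
}
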