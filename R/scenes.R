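#' Render a synthetic seafloor-like background
#'
#' A correlated Gaussian noise field (white noise smoothed with a Gaussian
#' kernel of width \code{noiseSigma}, rescaled to \code{noiseAmplitude})
#' around \code{baseIntensity}, optionally darkened towards the corners by a
#' radial vignette — emulating the flash-lighting artifacts of deep-sea AUV
#' imagery. Draws from the current RNG; [generateDataset()] seeds it.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @return numeric matrix (height x width) with values in [0, 1].
#' @export
renderBackground <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  H <- config@imageHeight; W <- config@imageWidth
  field <- matrix(stats::rnorm(H * W), H, W)
  field <- smoothField(field, config@noiseSigma)
  s <- stats::sd(field)
  if (s > 0) field <- field / s * config@noiseAmplitude
  img <- config@baseIntensity + field
  if (config@vignetteStrength > 0) {
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    dy <- ((seq_len(H) - cy) / (H / 2))^2
    dx <- ((seq_len(W) - cx) / (W / 2))^2
    d2 <- outer(dy, dx, "+") / 2
    img <- img - config@vignetteStrength * d2
  }
  pmin(pmax(img, 0.01), 0.99)
}

#' Render an object sprite of a given appearance family
#'
#' Families span the robustness axes seen in benthic megafauna imagery:
#' \describe{
#'   \item{texture}{texture-uniform disc: high-contrast speckle everywhere,
#'     so the discriminative signal survives position shifts (analogue of
#'     taxa with a unique texture over the whole body).}
#'   \item{feature}{plain body with one bright, compact cue occupying less
#'     than 25 percent of the sprite at one end; shifting the crop can lose
#'     the cue (analogue of taxa with prototypical features at specific
#'     parts).}
#'   \item{faint}{low-contrast object, easily missed (false-negative-prone
#'     analogue).}
#'   \item{ring, dark, stripe}{generic well-contrasted families used to fill
#'     up the class inventory.}
#' }
#'
#' @param style one of the registered family names.
#' @param r object radius in pixels; the sprite is a square of side
#'   \code{round(2r)} that tightly contains the object.
#' @param baseIntensity scene background intensity (used to keep contrasts
#'   consistent).
#' @return list with \code{sprite} (numeric matrix, side \code{round(2r)}),
#'   \code{mask} (logical matrix: object pixels), and \code{cue} (logical
#'   matrix marking the discriminative cue region; all-FALSE for families
#'   without a localized cue).
#' @export
renderObject <- function(style, r, baseIntensity = 0.45) {
  if (!style %in% .spriteFamilies)
    stop("unknown object style '", style, "'; registered families: ",
         paste(.spriteFamilies, collapse = ", "))
  s <- max(2L, as.integer(round(2 * r)))
  ctr <- (s + 1) / 2
  yy <- matrix(seq_len(s) - ctr, s, s)
  xx <- t(yy)
  rad <- sqrt(xx^2 + yy^2)
  half <- s / 2
  sprite <- matrix(baseIntensity, s, s)
  cue <- matrix(FALSE, s, s)
  mask <- rad <= half
  if (style == "texture") {
    sprite[mask] <- stats::runif(sum(mask), 0.08, 0.92)
  } else if (style == "feature") {
    sprite[mask] <- 0.60 + stats::rnorm(sum(mask), 0, 0.02)
    cue <- sqrt(xx^2 + (yy + 0.55 * half)^2) <= 0.35 * half
    cue <- cue & mask
    sprite[cue] <- 0.97
  } else if (style == "faint") {
    sprite[mask] <- baseIntensity + 0.12 + stats::rnorm(sum(mask), 0, 0.01)
  } else if (style == "ring") {
    inner <- rad <= 0.55 * half
    sprite[mask] <- 0.30
    sprite[mask & !inner] <- 0.88
  } else if (style == "dark") {
    sprite[mask] <- 0.10 + stats::rnorm(sum(mask), 0, 0.02)
  } else if (style == "stripe") {
    mask <- matrix(TRUE, s, s)
    period <- max(4L, as.integer(round(s / 4)))
    stripes <- ((col(sprite) - 1) %/% (period %/% 2L)) %% 2L == 0L
    sprite[stripes] <- 0.80
    sprite[!stripes] <- 0.22
  }
  sprite <- pmin(pmax(sprite, 0), 1)
  list(sprite = sprite, mask = mask, cue = cue, side = s)
}

#' Generate a synthetic annotated image collection
#'
#' Renders \code{nImages} synthetic seafloor-like scenes with ground-truth
#' expert annotations. Per image, the number of objects is drawn uniformly
#' from \code{objectsPerImage}; each object's class follows
#' \code{classFrequencies}, its radius is uniform in \code{radiusRange}, and
#' its position is rejection-sampled so that the object square lies fully
#' inside the image and overlaps no previously placed object. If a placement
#' cannot be found within the attempt cap the object count for that image is
#' reduced with a warning. Ground truth is exact by construction: each
#' annotation's square tightly contains its rendered object. Fully
#' reproducible given \code{config@seed}.
#'
#' @param nImages number of images to generate.
#' @param config a \linkS4class{SceneConfig}.
#' @param maxAttempts placement attempts per object (default 200).
#' @return list with \code{images} (named list of matrices), \code{expert}
#'   (label-complete \linkS4class{AnnotationSet}, role expert_all),
#'   \code{meta} (\linkS4class{DatasetMeta}), and \code{config}.
#' @examples
#' cfg <- sceneConfig(imageWidth = 128, imageHeight = 128,
#'                    objectsPerImage = c(2, 4), radiusRange = c(6, 12),
#'                    seed = 11)
#' ds <- generateDataset(3, cfg)
#' ds$meta
#' @export
generateDataset <- function(nImages, config, maxAttempts = 200L) {
  stopifnot(is(config, "SceneConfig"), nImages >= 1)
  classes <- paste0("class_", config@classStyles)
  if (anyDuplicated(classes))
    classes <- make.unique(classes, sep = "_")
  withSeed(config@seed, {
    images <- vector("list", nImages)
    names(images) <- sprintf("img%04d", seq_len(nImages))
    annRows <- vector("list", nImages)
    for (i in seq_len(nImages)) {
      img <- renderBackground(config)
      H <- nrow(img); W <- ncol(img)
      nObj <- config@objectsPerImage[1] +
        sample.int(config@objectsPerImage[2] - config@objectsPerImage[1] + 1L,
                   1L) - 1L
      placed <- data.frame(x = numeric(), y = numeric(), r = numeric(),
                           label = character(), stringsAsFactors = FALSE)
      for (k in seq_len(nObj)) {
        cls <- sample.int(config@nClasses, 1, prob = config@classFrequencies)
        r <- stats::runif(1, config@radiusRange[1], config@radiusRange[2])
        ok <- FALSE
        for (att in seq_len(maxAttempts)) {
          x <- stats::runif(1, r, W - r)
          y <- stats::runif(1, r, H - r)
          if (!nrow(placed) ||
              all(pmax(abs(x - placed$x), abs(y - placed$y)) >
                  r + placed$r)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          warning("image ", names(images)[i], ": placed only ", k - 1L,
                  " of ", nObj, " objects (no non-overlapping slot found)")
          break
        }
        obj <- renderObject(config@classStyles[cls], r, config@baseIntensity)
        rows <- round(y - obj$side / 2) + seq_len(obj$side)
        cols <- round(x - obj$side / 2) + seq_len(obj$side)
        keep <- rows >= 1 & rows <= H
        keepC <- cols >= 1 & cols <= W
        sub <- img[rows[keep], cols[keepC], drop = FALSE]
        m <- obj$mask[keep, keepC, drop = FALSE]
        sp <- obj$sprite[keep, keepC, drop = FALSE]
        sub[m] <- sp[m]
        img[rows[keep], cols[keepC]] <- sub
        placed <- rbind(placed, data.frame(x = x, y = y, r = r,
                                           label = classes[cls],
                                           stringsAsFactors = FALSE))
      }
      images[[i]] <- img
      if (nrow(placed))
        annRows[[i]] <- cbind(data.frame(image_id = names(images)[i],
                                         stringsAsFactors = FALSE), placed)
    }
    df <- do.call(rbind, annRows)
    if (is.null(df))
      df <- data.frame(image_id = character(), x = numeric(), y = numeric(),
                       r = numeric(), label = character(),
                       stringsAsFactors = FALSE)
    expert <- AnnotationSet(df[, c("image_id", "x", "y", "r", "label")],
                            role = "expert_all", name = "A",
                            provenance = sprintf("synthetic scenes seed=%d",
                                                 config@seed))
    meta <- DatasetMeta(nImages = nImages, nAnnotations = nrow(df),
                        nClasses = config@nClasses,
                        imageWidth = config@imageWidth,
                        imageHeight = config@imageHeight)
    list(images = images, expert = expert, meta = meta, config = config)
  })
}

#' Write a grayscale image (or all images of a dataset) as PNG
#'
#' @param image numeric matrix in [0, 1], or a named list of such matrices.
#' @param path output file (single image) or directory (list).
#' @return written path(s), invisibly.
#' @export
writeImagePNG <- function(image, path) {
  if (is.list(image)) {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    out <- vapply(names(image), function(id) {
      f <- file.path(path, paste0(id, ".png"))
      png::writePNG(image[[id]], f)
      f
    }, character(1))
    return(invisible(out))
  }
  png::writePNG(image, path)
  invisible(path)
}

#' Read a PNG image as a grayscale matrix
#'
#' RGB(A) images are converted to grayscale by channel averaging.
#'
#' @param path PNG file.
#' @return numeric matrix in [0, 1].
#' @export
readImagePNG <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                      c(1, 2), mean)
  a
}

#' Produce a tiny committed-size fixture dataset
#'
#' Five 128 x 128 images plus their annotation CSV, written under \code{dir}.
#' Intended for continuous-integration smoke runs.
#'
#' @param dir output directory.
#' @param nImages number of images (default 5).
#' @param size image side in pixels (default 128).
#' @param seed integer seed.
#' @return the SceneConfig used, invisibly.
#' @export
makeFixtureDataset <- function(dir, nImages = 5L, size = 128L, seed = 1L) {
  cfg <- sceneConfig(imageWidth = size, imageHeight = size,
                     objectsPerImage = c(2L, 4L), radiusRange = c(6, 14),
                     seed = seed)
  ds <- generateDataset(nImages, cfg)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeImagePNG(ds$images, file.path(dir, "images"))
  saveAnnotations(ds$expert, file.path(dir, "annotations.csv"), "csv")
  invisible(cfg)
}
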