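#' @import methods
NULL

.validRoles <- c("expert_all", "train", "validation", "simulated", "cs_raw")

#' Reserved label for background (no object) patches
#' @export
BACKGROUND_LABEL <- "Background"

#' AnnotationSet: a collection of square image annotations
#'
#' The central container of the package. Each annotation is a square marker
#' (center \code{x}, \code{y}; \code{r} = half of the side length, all in
#' continuous pixel coordinates with the origin at the image top-left corner),
#' tied to an image by an opaque \code{image_id}, and optionally carrying a
#' categorical \code{label}. Citizen-science detections carry no label
#' (\code{NA}); the reserved label \code{"Background"} marks no-object patches.
#'
#' @slot annotations data.frame with columns \code{image_id} (character),
#'   \code{x}, \code{y}, \code{r} (numeric, \code{r > 0}), \code{label}
#'   (character, NA allowed). Simulated sets additionally carry a
#'   \code{source_id} column: the row index of the originating annotation in
#'   the source set (traceability).
#' @slot role one of \code{"expert_all"}, \code{"train"}, \code{"validation"},
#'   \code{"simulated"}, \code{"cs_raw"}. Train/validation sets must be
#'   label-complete.
#' @slot name short display name of the set (e.g. \code{"Cp87.5"}).
#' @slot provenance free-text provenance (source file, or simulator
#'   parameters and seed).
#' @export
setClass("AnnotationSet",
  representation(annotations = "data.frame", role = "character",
                 name = "character", provenance = "character"),
  prototype(annotations = data.frame(image_id = character(), x = numeric(),
                                     y = numeric(), r = numeric(),
                                     label = character(),
                                     stringsAsFactors = FALSE),
            role = "cs_raw", name = "", provenance = ""))

setValidity("AnnotationSet", function(object) {
  df <- object@annotations
  need <- c("image_id", "x", "y", "r", "label")
  if (!all(need %in% names(df)))
    return(paste("annotations must have columns:", paste(need, collapse = ", ")))
  if (nrow(df)) {
    if (!is.numeric(df$x) || !is.numeric(df$y) || !is.numeric(df$r))
      return("x, y, r must be numeric")
    if (any(!is.finite(df$r)) || any(df$r <= 0))
      return("all radii must be finite and > 0")
    if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
      return("all coordinates must be finite")
  }
  if (length(object@role) != 1L || !object@role %in% .validRoles)
    return(paste("role must be one of:", paste(.validRoles, collapse = ", ")))
  if (object@role %in% c("train", "validation") && nrow(df) &&
      anyNA(df$label))
    return(sprintf("a %s set must be label-complete", object@role))
  TRUE
})

#' Construct an AnnotationSet
#'
#' @param annotations data.frame with columns image_id, x, y, r, label
#'   (label may be omitted, in which case all labels are NA).
#' @param role set role tag.
#' @param name display name.
#' @param provenance provenance string.
#' @return an \linkS4class{AnnotationSet}.
#' @examples
#' a <- AnnotationSet(data.frame(image_id = "img1", x = 100, y = 80, r = 20,
#'                               label = "texture"), role = "expert_all")
#' nAnnotations(a)
#' @export
AnnotationSet <- function(annotations, role = "cs_raw", name = "",
                          provenance = "") {
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (!"label" %in% names(annotations)) annotations$label <- NA_character_
  annotations$image_id <- as.character(annotations$image_id)
  annotations$label <- as.character(annotations$label)
  rownames(annotations) <- NULL
  new("AnnotationSet", annotations = annotations, role = role, name = name,
      provenance = provenance)
}

#' DatasetMeta: summary counts of an annotated image collection
#'
#' @slot nImages number of images.
#' @slot nAnnotations number of expert annotations.
#' @slot nClasses number of distinct object classes.
#' @slot imageWidth,imageHeight image size in pixels.
#' @export
setClass("DatasetMeta",
  representation(nImages = "integer", nAnnotations = "integer",
                 nClasses = "integer", imageWidth = "integer",
                 imageHeight = "integer"))

setValidity("DatasetMeta", function(object) {
  v <- c(object@nImages, object@nAnnotations, object@nClasses,
         object@imageWidth, object@imageHeight)
  if (any(v < 0L)) return("all counts must be non-negative")
  TRUE
})

#' @rdname DatasetMeta-class
#' @param nImages,nAnnotations,nClasses,imageWidth,imageHeight counts.
#' @export
DatasetMeta <- function(nImages, nAnnotations, nClasses, imageWidth,
                        imageHeight) {
  new("DatasetMeta", nImages = as.integer(nImages),
      nAnnotations = as.integer(nAnnotations), nClasses = as.integer(nClasses),
      imageWidth = as.integer(imageWidth), imageHeight = as.integer(imageHeight))
}

#' MatchReport: assignment of a CS set against an expert set
#'
#' A citizen-science annotation is \emph{valid} iff it has nonzero area
#' overlap with at least one expert annotation on the same image; otherwise it
#' is a false positive. An expert annotation is \emph{found} iff at least one
#' CS annotation overlaps it; otherwise it is a false negative.
#'
#' @slot nCS,nValid,nFP,nExpert,nFound,nFN integer counts satisfying
#'   \code{nValid + nFP == nCS} and \code{nFound + nFN == nExpert}.
#' @slot pairs data.frame with one row per valid CS annotation: the CS
#'   coordinates (\code{cs_x, cs_y, cs_r}), the best-matching expert
#'   annotation's coordinates and label (\code{ex_x, ex_y, ex_r, ex_label}),
#'   the row indices into both sets (\code{cs_index, expert_index}), the
#'   \code{image_id}, and the \code{overlap} fraction of the expert square's
#'   area covered by the CS square.
#' @export
setClass("MatchReport",
  representation(nCS = "integer", nValid = "integer", nFP = "integer",
                 nExpert = "integer", nFound = "integer", nFN = "integer",
                 pairs = "data.frame"))

setValidity("MatchReport", function(object) {
  if (object@nValid + object@nFP != object@nCS)
    return("nValid + nFP must equal nCS")
  if (object@nFound + object@nFN != object@nExpert)
    return("nFound + nFN must equal nExpert")
  if (nrow(object@pairs) &&
      (any(object@pairs$overlap < 0) || any(object@pairs$overlap > 1)))
    return("overlap fractions must lie in [0, 1]")
  TRUE
})

#' GaussianDeviationModel: Gaussian model of CS annotation deviations
#'
#' Parametrizes radius-relative deviations of citizen-science annotations from
#' expert annotations: (x'-x)/r and (y'-y)/r are modelled as Gaussians, and the
#' relative radius r'/r as a third Gaussian. Fitted from observed deviation
#' records or supplied directly as configuration.
#'
#' @slot muDx,sigmaDx mean/sd of (x'-x)/r.
#' @slot muDy,sigmaDy mean/sd of (y'-y)/r.
#' @slot muRr,sigmaRr mean/sd of r'/r.
#' @export
setClass("GaussianDeviationModel",
  representation(muDx = "numeric", sigmaDx = "numeric", muDy = "numeric",
                 sigmaDy = "numeric", muRr = "numeric", sigmaRr = "numeric"))

setValidity("GaussianDeviationModel", function(object) {
  if (object@sigmaDx < 0 || object@sigmaDy < 0 || object@sigmaRr < 0)
    return("all sigmas must be >= 0")
  TRUE
})

#' @rdname GaussianDeviationModel-class
#' @param muDx,sigmaDx,muDy,sigmaDy,muRr,sigmaRr model parameters.
#' @export
gaussianDeviationModel <- function(muDx = 0, sigmaDx = 0.5, muDy = 0,
                                   sigmaDy = 0.5, muRr = 2, sigmaRr = 1) {
  new("GaussianDeviationModel", muDx = muDx, sigmaDx = sigmaDx, muDy = muDy,
      sigmaDy = sigmaDy, muRr = muRr, sigmaRr = sigmaRr)
}

#' AccuracyTable: per-class and averaged classification accuracy
#'
#' Per-class accuracy is the recall of the true class: correctly predicted /
#' total, per true label. The macro average is the unweighted mean over
#' classes; the weighted average weights each class by its support. When
#' Background patches are present their accuracy is also reported separately
#' as \code{backgroundAccuracy}.
#'
#' @slot perClass named numeric vector of per-class accuracies.
#' @slot support named numeric vector of per-class patch counts.
#' @slot macroAvg unweighted mean of perClass.
#' @slot weightedAvg support-weighted mean of perClass.
#' @slot backgroundAccuracy accuracy on Background patches (NA if absent).
#' @slot name evaluated set name (grid column id).
#' @export
setClass("AccuracyTable",
  representation(perClass = "numeric", support = "numeric",
                 macroAvg = "numeric", weightedAvg = "numeric",
                 backgroundAccuracy = "numeric", name = "character"))

setValidity("AccuracyTable", function(object) {
  acc <- c(object@perClass, object@macroAvg, object@weightedAvg)
  acc <- acc[!is.na(acc)]
  if (length(acc) && (any(acc < 0) || any(acc > 1)))
    return("accuracies must lie in [0, 1]")
  if (!identical(names(object@perClass), names(object@support)))
    return("perClass and support must share names")
  wa <- sum(object@perClass * object@support) / sum(object@support)
  if (is.finite(wa) && abs(wa - object@weightedAvg) > 1e-10)
    return("weightedAvg must equal the support-weighted mean of perClass")
  TRUE
})

#' PatchDataset: fixed-size patches with labels
#'
#' @slot patches list of numeric matrices, all of one spatial size.
#' @slot labels character vector of class labels (may include Background).
#' @slot source provenance string (annotation set role + extraction params).
#' @export
setClass("PatchDataset",
  representation(patches = "list", labels = "character", source = "character"))

setValidity("PatchDataset", function(object) {
  if (length(object@patches) != length(object@labels))
    return("patches and labels must have equal length")
  if (length(object@patches)) {
    dims <- vapply(object@patches, dim, integer(2))
    if (any(dims != dims[, 1])) return("all patches must share one size")
  }
  TRUE
})

#' PatchClassifier: a trained multi-class patch classifier
#'
#' Wraps a multinomial logistic model (glmnet) over pooled-intensity and
#' local-texture patch features. The backend is a contract: any model exposing
#' \code{predictLabels} would do; this desk-scale default is deliberately not
#' a deep network.
#'
#' @slot fit the fitted glmnet object.
#' @slot classes character vector: training label vocabulary.
#' @slot lambda regularization value used at prediction time.
#' @slot grid feature pooling grid (blocks per side).
#' @slot outSide patch side length the model expects.
#' @slot seed training seed echo.
#' @export
setClass("PatchClassifier",
  representation(fit = "ANY", classes = "character", lambda = "numeric",
                 grid = "integer", outSide = "integer", seed = "integer"))

## ---- simulator configs ----

#' IPConfig: inaccurate-position simulator configuration
#'
#' Positions are perturbed as x' = x + Zx*r, y' = y + Zy*r with Zx, Zy
#' independent uniforms on [-2(1-o), 2(1-o)]. The parameter \code{o} is the
#' minimum per-axis overlap retained with the source annotation, as a
#' fraction in (0, 1].
#'
#' @slot o minimum overlap fraction in (0, 1].
#' @slot nPerAnnotation simulated annotations per expert annotation.
#' @slot seed integer seed.
#' @export
setClass("IPConfig",
  representation(o = "numeric", nPerAnnotation = "integer", seed = "integer"))

setValidity("IPConfig", function(object) {
  if (object@o <= 0 || object@o > 1) return("o must lie in (0, 1]")
  if (object@nPerAnnotation < 1L) return("nPerAnnotation must be >= 1")
  TRUE
})

#' @rdname IPConfig-class
#' @param o minimum overlap fraction in (0, 1].
#' @param nPerAnnotation simulated annotations per expert annotation
#'   (default 4).
#' @param seed integer seed.
#' @export
ipConfig <- function(o, nPerAnnotation = 4L, seed = 1L) {
  new("IPConfig", o = o, nPerAnnotation = as.integer(nPerAnnotation),
      seed = as.integer(seed))
}

#' IRConfig: inaccurate-radius simulator configuration
#'
#' Radii are perturbed as r' = (1 + Zr)*r with Zr uniform on the interval
#' between 0 and \code{s}; positive \code{s} overestimates the radius by at
#' most s*100 percent, negative \code{s} underestimates it.
#'
#' @slot s signed maximum relative radius change, s > -1, s != 0.
#' @slot seed integer seed.
#' @export
setClass("IRConfig", representation(s = "numeric", seed = "integer"))

setValidity("IRConfig", function(object) {
  if (object@s <= -1) return("s must be > -1 (radius could reach 0)")
  if (object@s == 0) return("s must be nonzero")
  TRUE
})

#' @rdname IRConfig-class
#' @param s signed maximum relative radius change.
#' @param seed integer seed.
#' @export
irConfig <- function(s, seed = 1L) {
  new("IRConfig", s = s, seed = as.integer(seed))
}

#' FPConfig: background false-positive simulator configuration
#'
#' Per image, \code{perImage} background annotations of size
#' \code{patchSide} x \code{patchSide} are placed by rejection sampling such
#' that the Euclidean distance between the background center and every expert
#' annotation center (x, y, r) on that image exceeds r + exclusionSlack, and
#' the patch lies fully inside the image.
#'
#' @slot perImage background annotations per image.
#' @slot patchSide side length of the background patch in pixels; the stored
#'   radius is patchSide/2.
#' @slot exclusionSlack additive term (pixels) of the distance constraint.
#' @slot maxAttempts rejection-sampling cap per placement.
#' @slot seed integer seed.
#' @export
setClass("FPConfig",
  representation(perImage = "integer", patchSide = "numeric",
                 exclusionSlack = "numeric", maxAttempts = "integer",
                 seed = "integer"))

setValidity("FPConfig", function(object) {
  if (object@perImage < 0L) return("perImage must be >= 0")
  if (object@patchSide <= 0) return("patchSide must be > 0")
  if (object@maxAttempts < 1L) return("maxAttempts must be > 0")
  TRUE
})

#' @rdname FPConfig-class
#' @param perImage background annotations per image (default 2).
#' @param patchSide patch side length in pixels (default 64).
#' @param exclusionSlack additive distance slack in pixels (default 64).
#' @param maxAttempts rejection-sampling cap (default 10000).
#' @param seed integer seed.
#' @export
fpConfig <- function(perImage = 2L, patchSide = 64, exclusionSlack = 64,
                     maxAttempts = 10000L, seed = 1L) {
  new("FPConfig", perImage = as.integer(perImage), patchSide = patchSide,
      exclusionSlack = exclusionSlack, maxAttempts = as.integer(maxAttempts),
      seed = as.integer(seed))
}

#' SceneConfig: synthetic seafloor scene configuration
#'
#' Describes the synthetic image world: a correlated-noise seafloor-like
#' background with optional vignetting, plus small non-overlapping objects of
#' several appearance families placed at random. Defaults emulate the
#' statistical structure of AUV benthic imagery at desk scale: strong class
#' imbalance (two dominant classes hold >= 85 percent of the mass), small
#' objects (radius 8-32 px) on a cluttered background.
#'
#' @slot imageWidth,imageHeight image size in pixels.
#' @slot nClasses number of object classes.
#' @slot classFrequencies probability vector over classes (sums to 1).
#' @slot classStyles appearance family per class; registered families:
#'   \code{texture} (texture-uniform disc, discriminative signal spread
#'   evenly), \code{feature} (localized cue occupying < 25 percent of the
#'   sprite at one end), \code{faint} (low-contrast object), \code{ring},
#'   \code{dark}, \code{stripe} (generic families).
#' @slot objectsPerImage integer range (min, max) of objects per image.
#' @slot radiusRange numeric range (min, max) of object radii in pixels.
#' @slot baseIntensity mean background intensity in [0, 1].
#' @slot noiseSigma background noise correlation length in pixels.
#' @slot noiseAmplitude background noise standard deviation.
#' @slot vignetteStrength radial vignette depth (0 disables).
#' @slot seed integer seed.
#' @export
setClass("SceneConfig",
  representation(imageWidth = "integer", imageHeight = "integer",
                 nClasses = "integer", classFrequencies = "numeric",
                 classStyles = "character", objectsPerImage = "integer",
                 radiusRange = "numeric", baseIntensity = "numeric",
                 noiseSigma = "numeric", noiseAmplitude = "numeric",
                 vignetteStrength = "numeric", seed = "integer"))

setValidity("SceneConfig", function(object) {
  if (object@nClasses < 2L) return("nClasses must be >= 2")
  if (length(object@classFrequencies) != object@nClasses)
    return("classFrequencies must have length nClasses")
  if (abs(sum(object@classFrequencies) - 1) > 1e-8)
    return("classFrequencies must sum to 1")
  if (any(object@classFrequencies < 0))
    return("classFrequencies must be non-negative")
  if (length(object@classStyles) != object@nClasses)
    return("classStyles must have length nClasses")
  bad <- setdiff(object@classStyles, .spriteFamilies)
  if (length(bad))
    return(paste("unknown class style(s):", paste(bad, collapse = ", ")))
  if (any(object@radiusRange <= 0)) return("radiusRange must be positive")
  if (object@radiusRange[1] > object@radiusRange[2])
    return("radiusRange must be (min, max)")
  if (object@objectsPerImage[1] > object@objectsPerImage[2])
    return("objectsPerImage must be (min, max)")
  TRUE
})

.spriteFamilies <- c("texture", "feature", "faint", "ring", "dark", "stripe")

#' @rdname SceneConfig-class
#' @param imageWidth,imageHeight image size in pixels (default 512 x 512).
#' @param nClasses number of object classes (default 6).
#' @param classFrequencies probability vector; default concentrates 85
#'   percent of the mass on the first two classes.
#' @param classStyles appearance family per class.
#' @param objectsPerImage range of objects per image (default 3-8).
#' @param radiusRange range of object radii in pixels (default 8-32).
#' @param baseIntensity mean background intensity (default 0.45).
#' @param noiseSigma background correlation length in pixels (default 6).
#' @param noiseAmplitude background noise sd (default 0.06).
#' @param vignetteStrength vignette depth (default 0.15).
#' @param seed integer seed.
#' @export
sceneConfig <- function(imageWidth = 512L, imageHeight = 512L, nClasses = 6L,
                        classFrequencies = NULL, classStyles = NULL,
                        objectsPerImage = c(3L, 8L), radiusRange = c(8, 32),
                        baseIntensity = 0.45, noiseSigma = 6,
                        noiseAmplitude = 0.06, vignetteStrength = 0.15,
                        seed = 1L) {
  nClasses <- as.integer(nClasses)
  if (nClasses < 2L) stop("nClasses must be >= 2")
  if (is.null(classFrequencies)) {
    rest <- nClasses - 2L
    classFrequencies <- c(0.45, 0.40, rep(0.15 / rest, rest))
  }
  if (is.null(classStyles))
    classStyles <- rep_len(.spriteFamilies, nClasses)
  new("SceneConfig", imageWidth = as.integer(imageWidth),
      imageHeight = as.integer(imageHeight), nClasses = nClasses,
      classFrequencies = classFrequencies, classStyles = classStyles,
      objectsPerImage = as.integer(objectsPerImage),
      radiusRange = as.numeric(radiusRange), baseIntensity = baseIntensity,
      noiseSigma = noiseSigma, noiseAmplitude = noiseAmplitude,
      vignetteStrength = vignetteStrength, seed = as.integer(seed))
}
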