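#' Extract the annotation table from a container
#' @param x an object holding annotations.
#' @return a data.frame with one row per annotation.
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @describeIn AnnotationSet-class annotation data.frame accessor.
#' @param x an AnnotationSet.
#' @export
setMethod("annotations", "AnnotationSet", function(x) x@annotations)

#' Role tag of an annotation set
#' @param x an AnnotationSet.
#' @return character role tag.
#' @export
setGeneric("role", function(x) standardGeneric("role"))

#' @describeIn AnnotationSet-class role accessor.
#' @export
setMethod("role", "AnnotationSet", function(x) x@role)

#' Provenance string of an object
#' @param x an object with provenance.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @describeIn AnnotationSet-class provenance accessor.
#' @export
setMethod("provenance", "AnnotationSet", function(x) x@provenance)

#' Number of annotations in a set
#' @param x an AnnotationSet.
#' @return integer count.
#' @export
setGeneric("nAnnotations", function(x) standardGeneric("nAnnotations"))

#' @describeIn AnnotationSet-class number of annotations.
#' @export
setMethod("nAnnotations", "AnnotationSet", function(x) nrow(x@annotations))

#' Display name of a set or table
#' @param x object with a name slot.
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))

#' @describeIn AnnotationSet-class set name accessor.
#' @export
setMethod("setName", "AnnotationSet", function(x) x@name)

#' @describeIn AccuracyTable-class column name accessor.
#' @export
setMethod("setName", "AccuracyTable", function(x) x@name)

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet '%s' (role: %s) with %d annotation(s) on %d image(s)\n",
              object@name, object@role, nrow(object@annotations),
              length(unique(object@annotations$image_id))))
  if (nrow(object@annotations)) {
    labs <- object@annotations$label
    if (all(is.na(labs))) cat("  unlabeled (CS detections)\n")
    else cat("  labels:", paste(utils::head(sort(unique(stats::na.omit(labs))), 8),
                                collapse = ", "), "\n")
  }
  if (nzchar(object@provenance))
    cat("  provenance:", substr(object@provenance, 1, 70), "\n")
})

setMethod("show", "DatasetMeta", function(object) {
  cat(sprintf("DatasetMeta: %d images (%d x %d px), %d annotations, %d classes\n",
              object@nImages, object@imageWidth, object@imageHeight,
              object@nAnnotations, object@nClasses))
})

setMethod("show", "MatchReport", function(object) {
  cat("MatchReport\n")
  cat(sprintf("  CS:     %d total, %d valid, %d FP\n", object@nCS,
              object@nValid, object@nFP))
  cat(sprintf("  expert: %d total, %d found, %d FN\n", object@nExpert,
              object@nFound, object@nFN))
})

setMethod("show", "GaussianDeviationModel", function(object) {
  cat("GaussianDeviationModel\n")
  cat(sprintf("  (x'-x)/r ~ N(%.4g, %.4g^2)\n", object@muDx, object@sigmaDx))
  cat(sprintf("  (y'-y)/r ~ N(%.4g, %.4g^2)\n", object@muDy, object@sigmaDy))
  cat(sprintf("  r'/r     ~ N(%.4g, %.4g^2)\n", object@muRr, object@sigmaRr))
})

setMethod("show", "AccuracyTable", function(object) {
  cat(sprintf("AccuracyTable '%s'\n", object@name))
  df <- data.frame(class = names(object@perClass),
                   accuracy = round(object@perClass, 3),
                   support = object@support)
  print(df, row.names = FALSE)
  cat(sprintf("  Avg %.3f | Weighted Avg %.3f", object@macroAvg,
              object@weightedAvg))
  if (!is.na(object@backgroundAccuracy))
    cat(sprintf(" | Background %.3f", object@backgroundAccuracy))
  cat("\n")
})

setMethod("show", "PatchClassifier", function(object) {
  cat(sprintf("PatchClassifier (multinomial glmnet): %d classes, %dx%d patches, %dx%d pooling\n",
              length(object@classes), object@outSide, object@outSide,
              object@grid, object@grid))
  cat("  classes:", paste(object@classes, collapse = ", "), "\n")
})

#' Per-class accuracy of an AccuracyTable
#' @param x an AccuracyTable.
#' @return named numeric vector (per-class recall).
#' @export
setGeneric("perClassAccuracy", function(x) standardGeneric("perClassAccuracy"))

#' @describeIn AccuracyTable-class per-class accuracy accessor.
#' @param x an AccuracyTable.
#' @export
setMethod("perClassAccuracy", "AccuracyTable", function(x) x@perClass)

#' Macro-average accuracy
#' @param x an AccuracyTable.
#' @export
setGeneric("macroAccuracy", function(x) standardGeneric("macroAccuracy"))

#' @describeIn AccuracyTable-class macro average accessor.
#' @export
setMethod("macroAccuracy", "AccuracyTable", function(x) x@macroAvg)

#' Support-weighted average accuracy
#' @param x an AccuracyTable.
#' @export
setGeneric("weightedAccuracy", function(x) standardGeneric("weightedAccuracy"))

#' @describeIn AccuracyTable-class weighted average accessor.
#' @export
setMethod("weightedAccuracy", "AccuracyTable", function(x) x@weightedAvg)

#' Background-rejection accuracy
#' @param x an AccuracyTable.
#' @return fraction of Background patches classified Background, or NA.
#' @export
setGeneric("backgroundAccuracy", function(x) standardGeneric("backgroundAccuracy"))

#' @describeIn AccuracyTable-class background accuracy accessor.
#' @export
setMethod("backgroundAccuracy", "AccuracyTable", function(x) x@backgroundAccuracy)

#' Class support of an AccuracyTable
#' @param x an AccuracyTable.
#' @export
setGeneric("classSupport", function(x) standardGeneric("classSupport"))

#' @describeIn AccuracyTable-class per-class support accessor.
#' @export
setMethod("classSupport", "AccuracyTable", function(x) x@support)

#' Match counts of a MatchReport
#' @param x a MatchReport.
#' @return named integer vector of the six counts.
#' @export
setGeneric("matchCounts", function(x) standardGeneric("matchCounts"))

#' @describeIn MatchReport-class counts accessor.
#' @param x a MatchReport.
#' @export
setMethod("matchCounts", "MatchReport", function(x)
  c(n_cs = x@nCS, n_valid = x@nValid, n_fp = x@nFP, n_expert = x@nExpert,
    n_found = x@nFound, n_fn = x@nFN))

#' Matched pairs of a MatchReport
#' @param x a MatchReport.
#' @return data.frame of valid CS annotations and their matched experts.
#' @export
setGeneric("matchPairs", function(x) standardGeneric("matchPairs"))

#' @describeIn MatchReport-class pairs accessor.
#' @export
setMethod("matchPairs", "MatchReport", function(x) x@pairs)
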