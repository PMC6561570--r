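#' Extract a fixed-size patch for an annotation
#'
#' Crops the window \code{[x - r, x + r] x [y - r, y + r]} from the image,
#' rounded outward to whole pixels, pads any out-of-image region with the
#' image's mean intensity, and resizes the crop to
#' \code{outSide x outSide} with bilinear interpolation (exact when no
#' resampling is needed). An annotation whose window lies fully outside the
#' image is an error.
#'
#' @param image numeric matrix (grayscale, [0, 1]).
#' @param a a single annotation: 1-row data.frame or list with x, y, r.
#' @param outSide output patch side in pixels (default 64).
#' @return an \code{outSide x outSide} numeric matrix.
#' @export
extractPatch <- function(image, a, outSide = 64L) {
  H <- nrow(image); W <- ncol(image)
  x <- as.numeric(a$x); y <- as.numeric(a$y); r <- as.numeric(a$r)
  cLo <- floor(x - r) + 1L; cHi <- ceiling(x + r)
  rLo <- floor(y - r) + 1L; rHi <- ceiling(y + r)
  if (cHi < 1 || cLo > W || rHi < 1 || rLo > H)
    stop("annotation window lies fully outside the image")
  fill <- mean(image)
  crop <- matrix(fill, rHi - rLo + 1L, cHi - cLo + 1L)
  rIn <- max(rLo, 1L):min(rHi, H)
  cIn <- max(cLo, 1L):min(cHi, W)
  crop[rIn - rLo + 1L, cIn - cLo + 1L] <- image[rIn, cIn]
  bilinearResize(crop, outSide, outSide)
}

# pooled-intensity + local-texture features for one patch:
# grid x grid block means, block standard deviations, global mean/sd
patchFeatures <- function(patch, grid = 8L) {
  s <- nrow(patch)
  block <- s %/% grid
  idx <- rep(seq_len(grid), each = block)
  rs <- rowsum(patch[seq_len(grid * block), seq_len(grid * block)], idx)
  means <- t(rowsum(t(rs), idx)) / (block * block)
  sq <- rowsum(patch[seq_len(grid * block), seq_len(grid * block)]^2, idx)
  msq <- t(rowsum(t(sq), idx)) / (block * block)
  sds <- sqrt(pmax(msq - means^2, 0))
  c(as.vector(means), as.vector(sds), mean(patch), stats::sd(patch))
}

#' Build a patch dataset from an annotation set
#'
#' Extracts one fixed-size patch per annotation; labels are taken from the
#' set (which must be label-complete for training or evaluation use).
#'
#' @param images named list of image matrices.
#' @param set an \linkS4class{AnnotationSet}.
#' @param outSide patch side in pixels (default 64).
#' @return a \linkS4class{PatchDataset}.
#' @export
buildPatchDataset <- function(images, set, outSide = 64L) {
  df <- annotations(set)
  miss <- setdiff(unique(df$image_id), names(images))
  if (length(miss))
    stop("annotation set references unknown image(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  patches <- lapply(seq_len(nrow(df)), function(i)
    extractPatch(images[[df$image_id[i]]], df[i, ], outSide))
  new("PatchDataset", patches = patches, labels = df$label,
      source = sprintf("%s[%s] outSide=%d", setName(set), role(set),
                       as.integer(outSide)))
}

.featureMatrix <- function(pd, grid = 8L) {
  t(vapply(pd@patches, patchFeatures, numeric(2 * grid * grid + 2),
           grid = grid))
}

#' Train the multi-class patch classifier
#'
#' Fits a multinomial logistic model (glmnet, ridge-regularized) on pooled
#' intensity and local texture features of the training patches. The backend
#' is a contract — any model exposing [predictLabels()] would satisfy it; at
#' desk scale a linear model over these features is deliberate, not a deep
#' network. Training is deterministic given the data and seed.
#'
#' @param trainPatches a label-complete \linkS4class{PatchDataset} including
#'   object classes and (for background rejection) Background samples.
#' @param grid feature pooling grid (default 8 blocks per side).
#' @param lambda ridge penalty used at prediction time (default 1e-3).
#' @param seed integer seed echoed into the model.
#' @return a \linkS4class{PatchClassifier}.
#' @export
trainClassifier <- function(trainPatches, grid = 8L, lambda = 1e-3,
                            seed = 1L) {
  stopifnot(is(trainPatches, "PatchDataset"))
  labs <- trainPatches@labels
  if (anyNA(labs)) stop("training patches must be label-complete")
  classes <- sort(unique(labs))
  if (length(classes) < 2)
    stop("training requires at least 2 classes; got only: ",
         paste(classes, collapse = ", "))
  x <- .featureMatrix(trainPatches, grid)
  # the backend rejects classes observed once; duplicate singletons so rare
  # classes stay trainable (they are legitimately rare under class imbalance)
  single <- names(which(table(labs) == 1))
  if (length(single)) {
    dup <- which(labs %in% single)
    x <- rbind(x, x[dup, , drop = FALSE])
    labs <- c(labs, labs[dup])
  }
  outSide <- nrow(trainPatches@patches[[1]])
  # a geometric path down to the working lambda: glmnet's coordinate descent
  # needs the warm starts, a short path can stop far from the optimum
  path <- exp(seq(log(10), log(lambda), length.out = 30))
  fit <- withSeed(as.integer(seed), suppressWarnings(
    glmnet::glmnet(x, factor(labs, levels = classes), family = "multinomial",
                   alpha = 0, lambda = path, standardize = TRUE)))
  new("PatchClassifier", fit = fit, classes = classes, lambda = lambda,
      grid = as.integer(grid), outSide = as.integer(outSide),
      seed = as.integer(seed))
}

#' Predict class labels for patches
#'
#' @param model a \linkS4class{PatchClassifier}.
#' @param patches a \linkS4class{PatchDataset} (patch size must match the
#'   model's).
#' @return character vector of predicted labels.
#' @export
predictLabels <- function(model, patches) {
  stopifnot(is(model, "PatchClassifier"), is(patches, "PatchDataset"))
  if (!length(patches@patches)) return(character())
  if (nrow(patches@patches[[1]]) != model@outSide)
    stop("patch size ", nrow(patches@patches[[1]]),
         " does not match the model's expected ", model@outSide)
  x <- .featureMatrix(patches, model@grid)
  as.character(stats::predict(model@fit, newx = x, s = model@lambda,
                              type = "class"))
}

#' Evaluate a classifier on an annotation set
#'
#' Extracts patches for every annotation in the (label-complete) set,
#' predicts, and tabulates per-class accuracy (recall of the true class),
#' the unweighted macro average, and the support-weighted average. When
#' Background-labelled patches are present their accuracy is additionally
#' reported as \code{backgroundAccuracy}.
#'
#' @param model a \linkS4class{PatchClassifier}.
#' @param set a label-complete \linkS4class{AnnotationSet}.
#' @param images named list of image matrices.
#' @param outSide patch side in pixels (must match the model).
#' @return an \linkS4class{AccuracyTable}.
#' @export
evaluateSet <- function(model, set, images, outSide = 64L) {
  df <- annotations(set)
  if (anyNA(df$label)) stop("evaluation requires a label-complete set")
  unknown <- setdiff(unique(df$label), model@classes)
  if (length(unknown))
    stop("label(s) absent from the training vocabulary: ",
         paste(unknown, collapse = ", "))
  pd <- buildPatchDataset(images, set, outSide)
  pred <- predictLabels(model, pd)
  accuracyTable(truth = df$label, predicted = pred, name = setName(set))
}

#' Build an AccuracyTable from truth/prediction vectors
#'
#' @param truth,predicted character vectors of equal length.
#' @param name column name for the table.
#' @return an \linkS4class{AccuracyTable}.
#' @export
accuracyTable <- function(truth, predicted, name = "") {
  stopifnot(length(truth) == length(predicted))
  classes <- sort(unique(truth))
  per <- vapply(classes, function(cl) mean(predicted[truth == cl] == cl),
                numeric(1))
  sup <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  bg <- if (BACKGROUND_LABEL %in% classes) per[[BACKGROUND_LABEL]] else
    NA_real_
  new("AccuracyTable", perClass = per, support = sup,
      macroAvg = mean(per), weightedAvg = sum(per * sup) / sum(sup),
      backgroundAccuracy = bg, name = name)
}

#' Run the full simulated-citizen-scientist experiment grid
#'
#' Trains one classifier on the training annotations (augmented with
#' Background patches sampled from the training images under the
#' false-positive distance constraint, so the Background class is trainable),
#' then evaluates the unperturbed validation set V and every configured
#' simulated set against that single model. The default grid emits 10
#' columns: V, three inaccurate-position sets (o = 0.875, 0.75, 0.5, four
#' simulated annotations per source), four inaccurate-radius sets
#' (s = +0.1, -0.1, +0.25, -0.25), the Gaussian CSP-like set, and the
#' background set Cbg.
#'
#' @param train,val training and validation \linkS4class{AnnotationSet}s.
#' @param images named list of image matrices.
#' @param expert expert set used for background exclusion zones (defaults to
#'   the union of train and val annotations).
#' @param ipOs minimum-overlap values for the IP columns.
#' @param irSs signed maximum relative radius changes for the IR columns.
#' @param cspModel \linkS4class{GaussianDeviationModel} for the CSP-like
#'   column (NULL skips it).
#' @param fpCfg \linkS4class{FPConfig} for the Cbg column and the Background
#'   training patches (NULL skips background entirely).
#' @param outSide patch side in pixels.
#' @param nPerAnnotation IP multiplicity (default 4).
#' @param seed global seed; every stage draws from a named substream derived
#'   from it, so changing one stage leaves the others' draws unchanged.
#' @return list with \code{tables} (named list of
#'   \linkS4class{AccuracyTable}), \code{report} (data.frame, rows = classes
#'   plus Avg / Weighted Avg / Background, columns = sets), and \code{model}.
#' @export
runExperimentGrid <- function(train, val, images, expert = NULL,
                              ipOs = c(0.875, 0.75, 0.5),
                              irSs = c(0.1, -0.1, 0.25, -0.25),
                              cspModel = gaussianDeviationModel(),
                              fpCfg = fpConfig(), outSide = 64L,
                              nPerAnnotation = 4L, seed = 1L) {
  stopifnot(is(train, "AnnotationSet"), is(val, "AnnotationSet"))
  if (is.null(expert)) {
    expert <- AnnotationSet(rbind(annotations(train)[c("image_id", "x", "y",
                                                       "r", "label")],
                                  annotations(val)[c("image_id", "x", "y",
                                                     "r", "label")]),
                            role = "expert_all", name = "A")
  }
  trainSet <- train
  if (!is.null(fpCfg)) {
    bgTrainCfg <- fpCfg
    bgTrainCfg@seed <- deriveSeed(seed, "bg_train")
    bgTrain <- generateBackgroundFP(images, expert, bgTrainCfg)
    trainSet <- AnnotationSet(
      rbind(annotations(train)[c("image_id", "x", "y", "r", "label")],
            annotations(bgTrain)[c("image_id", "x", "y", "r", "label")]),
      role = "train", name = "T+bg", provenance = provenance(train))
  }
  pdTrain <- buildPatchDataset(images, trainSet, outSide)
  model <- trainClassifier(pdTrain, seed = deriveSeed(seed, "train"))

  cols <- list(V = val)
  for (o in ipOs) {
    cfg <- ipConfig(o, nPerAnnotation = nPerAnnotation,
                    seed = deriveSeed(seed, paste0("ip", o)))
    s <- generateIPSet(val, cfg)
    cols[[setName(s)]] <- s
  }
  for (sv in irSs) {
    cfg <- irConfig(sv, seed = deriveSeed(seed, paste0("ir", sv)))
    s <- generateIRSet(val, cfg)
    cols[[setName(s)]] <- s
  }
  if (!is.null(cspModel)) {
    s <- generateCSPLike(val, cspModel, seed = deriveSeed(seed, "csp"))
    cols[[setName(s)]] <- s
  }
  if (!is.null(fpCfg)) {
    bgValCfg <- fpCfg
    bgValCfg@seed <- deriveSeed(seed, "bg_val")
    valImages <- unique(annotations(val)$image_id)
    s <- generateBackgroundFP(images[valImages], expert, bgValCfg)
    cols[[setName(s)]] <- s
  }
  tables <- lapply(names(cols), function(nm) {
    tab <- evaluateSet(model, cols[[nm]], images, outSide)
    tab@name <- nm
    tab
  })
  names(tables) <- names(cols)
  list(tables = tables, report = gridReport(tables), model = model)
}

#' Assemble grid results into one report table
#'
#' @param tables named list of \linkS4class{AccuracyTable}.
#' @return data.frame: one row per class plus \code{Avg}, \code{Weighted
#'   Avg} and \code{Background}; one column per evaluated set.
#' @export
gridReport <- function(tables) {
  classes <- sort(unique(unlist(lapply(tables, function(t)
    names(perClassAccuracy(t))))))
  classes <- c(setdiff(classes, BACKGROUND_LABEL))
  rows <- c(classes, "Avg", "Weighted Avg", "Background")
  out <- data.frame(row.names = rows)
  for (nm in names(tables)) {
    t <- tables[[nm]]
    col <- rep(NA_real_, length(rows))
    names(col) <- rows
    pc <- perClassAccuracy(t)
    shared <- intersect(names(pc), classes)
    col[shared] <- pc[shared]
    col["Avg"] <- macroAccuracy(t)
    col["Weighted Avg"] <- weightedAccuracy(t)
    col["Background"] <- backgroundAccuracy(t)
    out[[nm]] <- col
  }
  out
}

#' Write a grid report to CSV and JSON
#'
#' @param report data.frame from [gridReport()].
#' @param csvPath,jsonPath output paths (NULL to skip either).
#' @return invisibly, the report.
#' @export
writeGridReport <- function(report, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath))
    utils::write.csv(cbind(row = rownames(report), report), csvPath,
                     row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(
      c(list(rows = rownames(report)), as.list(report)), jsonPath,
      digits = NA, na = "null")
  invisible(report)
}
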