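#' Read an annotation set from disk
#'
#' Two dialects are supported. \code{csv}: a UTF-8 table with header
#' \code{image_id,x,y,r,label} (label empty for unlabeled CS detections).
#' \code{coco_json}: a COCO-style JSON file in which each square marker is
#' encoded as \code{bbox = [x - r, y - r, 2r, 2r]} with a category id map in
#' the file. Coordinates are continuous pixel values in a top-left-origin
#' frame.
#'
#' @param path file to read.
#' @param dialect \code{"csv"} or \code{"coco_json"}.
#' @param role role tag for the returned set.
#' @param name display name for the returned set.
#' @return an \linkS4class{AnnotationSet}.
#' @seealso [saveAnnotations()]
#' @export
loadAnnotations <- function(path, dialect = c("csv", "coco_json"),
                            role = "cs_raw", name = "") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- switch(dialect,
    csv = .readAnnotationCsv(path),
    coco_json = .readAnnotationCoco(path))
  bad <- which(!is.finite(df$r) | df$r <= 0)
  if (length(bad))
    stop("invalid radius (r <= 0) in row(s): ", paste(bad, collapse = ", "))
  AnnotationSet(df, role = role, name = name, provenance = path)
}

.readAnnotationCsv <- function(path) {
  df <- tryCatch(
    # missing columns are reported below with a clearer message than the
    # colClasses warning read.csv would emit
    suppressWarnings(
      utils::read.csv(path, stringsAsFactors = FALSE,
                      colClasses = c(image_id = "character", x = "numeric",
                                     y = "numeric", r = "numeric",
                                     label = "character"))),
    error = function(e) stop("malformed CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  need <- c("image_id", "x", "y", "r", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  nn <- which(is.na(df$x) | is.na(df$y) | is.na(df$r))
  if (length(nn))
    stop("malformed row(s) (non-numeric coordinates): ",
         paste(nn, collapse = ", "))
  df$label[!is.na(df$label) & df$label == ""] <- NA_character_
  if ("source_id" %in% names(df)) df$source_id <- as.integer(df$source_id)
  df[, intersect(c(need, "source_id"), names(df)), drop = FALSE]
}

.readAnnotationCoco <- function(path) {
  js <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                 error = function(e) stop("malformed JSON '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  for (k in c("images", "annotations"))
    if (is.null(js[[k]])) stop("COCO file lacks '", k, "' section")
  imgs <- js$images
  imgMap <- stats::setNames(as.character(imgs$file_name), as.character(imgs$id))
  catMap <- character()
  if (!is.null(js$categories) && length(js$categories))
    catMap <- stats::setNames(as.character(js$categories$name),
                              as.character(js$categories$id))
  ann <- js$annotations
  if (is.null(ann) || !length(ann) || !NROW(ann)) {
    return(data.frame(image_id = character(), x = numeric(), y = numeric(),
                      r = numeric(), label = character(),
                      stringsAsFactors = FALSE))
  }
  bbox <- ann$bbox
  if (is.list(bbox)) bbox <- do.call(rbind, bbox)
  if (is.null(dim(bbox)) || ncol(bbox) != 4)
    stop("COCO annotations must carry 4-element bbox entries")
  w <- bbox[, 3]; h <- bbox[, 4]
  if (any(abs(w - h) > 1e-9))
    stop("non-square bbox encountered; only square markers are supported")
  r <- if (!is.null(ann$r)) ann$r else w / 2
  cx <- if (!is.null(ann$cx)) ann$cx else bbox[, 1] + r
  cy <- if (!is.null(ann$cy)) ann$cy else bbox[, 2] + r
  lab <- rep(NA_character_, NROW(bbox))
  if (!is.null(ann$category_id)) {
    cid <- as.character(ann$category_id)
    known <- !is.na(ann$category_id) & cid %in% names(catMap)
    lab[known] <- catMap[cid[known]]
  }
  df <- data.frame(image_id = unname(imgMap[as.character(ann$image_id)]),
                   x = cx, y = cy, r = r, label = lab,
                   stringsAsFactors = FALSE)
  if (!is.null(ann$source_id)) df$source_id <- as.integer(ann$source_id)
  df
}

#' Write an annotation set to disk
#'
#' Inverse of [loadAnnotations()]: a save/load round trip reproduces every
#' field bit-exactly (numerics are written with 17 significant digits).
#'
#' @param set an \linkS4class{AnnotationSet}.
#' @param path output file.
#' @param dialect \code{"csv"} or \code{"coco_json"}.
#' @return the path, invisibly.
#' @export
saveAnnotations <- function(set, path, dialect = c("csv", "coco_json")) {
  dialect <- match.arg(dialect)
  stopifnot(is(set, "AnnotationSet"))
  df <- set@annotations
  switch(dialect,
    csv = .writeAnnotationCsv(df, path),
    coco_json = .writeAnnotationCoco(df, path))
  invisible(path)
}

.writeAnnotationCsv <- function(df, path) {
  out <- data.frame(image_id = df$image_id, x = numToChr(df$x),
                    y = numToChr(df$y), r = numToChr(df$r),
                    label = ifelse(is.na(df$label), "", df$label),
                    stringsAsFactors = FALSE)
  if ("source_id" %in% names(df)) out$source_id <- df$source_id
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

.writeAnnotationCoco <- function(df, path) {
  imageIds <- unique(df$image_id)
  images <- data.frame(id = seq_along(imageIds), file_name = imageIds,
                       stringsAsFactors = FALSE)
  labs <- sort(unique(stats::na.omit(df$label)))
  categories <- data.frame(id = seq_along(labs), name = labs,
                           stringsAsFactors = FALSE)
  n <- nrow(df)
  # cx/cy/r are stored redundantly beside the bbox: recovering the center as
  # bbox[1] + bbox[3]/2 is not bit-exact in floating point, and round trips
  # must be lossless; COCO readers ignore the extra keys
  annotations <- data.frame(
    id = seq_len(n),
    image_id = match(df$image_id, imageIds),
    category_id = match(df$label, labs),
    cx = df$x, cy = df$y, r = df$r)
  if (n) {
    annotations$bbox <- lapply(seq_len(n), function(i)
      c(df$x[i] - df$r[i], df$y[i] - df$r[i], 2 * df$r[i], 2 * df$r[i]))
  } else {
    annotations$bbox <- list()
  }
  if ("source_id" %in% names(df)) annotations$source_id <- df$source_id
  jsonlite::write_json(
    list(images = images, categories = categories, annotations = annotations),
    path, digits = I(17), auto_unbox = FALSE, na = "null",
    dataframe = "rows")
}

#' Split an annotation set into training and validation sets
#'
#' Partitions a label-complete set A into a training set T and a validation
#' set V with T and V disjoint and their union equal to A. The split is over
#' annotations (not images) by default, mirroring the gold-standard protocol;
#' optional stratification by label or by image is available.
#'
#' @param set a label-complete \linkS4class{AnnotationSet}.
#' @param trainFraction fraction in (0, 1); \code{|T| = round(f * |A|)}
#'   (under \code{"label"} stratification the rounding is per class).
#' @param seed integer seed; the partition is deterministic given the seed.
#' @param stratify \code{"none"} (default, uniform random), \code{"label"}
#'   (per-class split), or \code{"image"} (whole images assigned to one side).
#' @return list with elements \code{train} and \code{validation}, both
#'   AnnotationSet objects.
#' @examples
#' df <- data.frame(image_id = "im", x = 1:20 * 10, y = 50, r = 5,
#'                  label = rep(c("a", "b"), 10))
#' sp <- splitTrainVal(AnnotationSet(df, role = "expert_all"), 0.9, seed = 7)
#' nAnnotations(sp$train); nAnnotations(sp$validation)
#' @export
splitTrainVal <- function(set, trainFraction = 0.9, seed = 1L,
                          stratify = c("none", "label", "image")) {
  stratify <- match.arg(stratify)
  stopifnot(is(set, "AnnotationSet"))
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly between 0 and 1")
  df <- set@annotations
  n <- nrow(df)
  if (n < 2) stop("cannot split a set with fewer than 2 annotations")
  if (anyNA(df$label)) stop("split requires a label-complete set")
  idx <- withSeed(seed, {
    switch(stratify,
      none = sample.int(n, round(trainFraction * n)),
      label = {
        unlist(lapply(split(seq_len(n), df$label), function(ii) {
          ii[sample.int(length(ii), round(trainFraction * length(ii)))]
        }), use.names = FALSE)
      },
      image = {
        ims <- unique(df$image_id)
        tIms <- ims[sample.int(length(ims),
                               max(1, round(trainFraction * length(ims))))]
        which(df$image_id %in% tIms)
      })
  })
  trainIdx <- sort(idx)
  valIdx <- setdiff(seq_len(n), trainIdx)
  prov <- sprintf("split of [%s]: fraction=%s stratify=%s seed=%d",
                  set@name, format(trainFraction), stratify, seed)
  list(
    train = AnnotationSet(df[trainIdx, , drop = FALSE], role = "train",
                          name = "T", provenance = prov),
    validation = AnnotationSet(df[valIdx, , drop = FALSE], role = "validation",
                               name = "V", provenance = prov))
}
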