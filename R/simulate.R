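#' Perturb annotation positions (inaccurate position, IP)
#'
#' Applies the IP error model to every annotation in the set:
#' \deqn{x' = x + Z_x r, \quad y' = y + Z_y r}
#' with \eqn{Z_x, Z_y} independent uniforms on
#' \eqn{[-2(1-o),\, 2(1-o)]}. The radius and label are unchanged. The bound
#' guarantees a per-axis overlap of at least \code{o} with the source square:
#' \eqn{1 - |x'-x|/(2r) \ge o}. At \code{o = 1} the interval degenerates to
#' \{0\} and the output equals the input exactly. Out-of-image centers are
#' permitted; crop-time padding handles them.
#'
#' Draws come from the current R RNG stream; wrap in [withSeed()] (or use
#' [generateIPSet()], which seeds from its config) for reproducibility.
#'
#' @param set an \linkS4class{AnnotationSet} (or data.frame with x, y, r).
#' @param cfg an \linkS4class{IPConfig}.
#' @return an object of the same class with perturbed positions.
#' @export
perturbPosition <- function(set, cfg) {
  stopifnot(is(cfg, "IPConfig"))
  df <- if (is(set, "AnnotationSet")) set@annotations else set
  half <- 2 * (1 - cfg@o)
  n <- nrow(df)
  zx <- stats::runif(n, -half, half)
  zy <- stats::runif(n, -half, half)
  df$x <- df$x + zx * df$r
  df$y <- df$y + zy * df$r
  if (is(set, "AnnotationSet")) {
    out <- set
    out@annotations <- df
    out
  } else df
}

#' Perturb annotation radii (inaccurate radius, IR)
#'
#' Applies the IR error model to every annotation in the set:
#' \deqn{r' = (1 + Z_r) r, \quad Z_r \sim U(0, s)}
#' where \eqn{U(0, s)} is the uniform distribution on the interval between 0
#' and \code{s} regardless of sign, so a positive \code{s} overestimates the
#' radius by at most \code{s*100} percent and a negative \code{s}
#' underestimates it. Positions and labels are unchanged.
#'
#' @inheritParams perturbPosition
#' @param cfg an \linkS4class{IRConfig}.
#' @return same class as \code{set}, with perturbed radii.
#' @export
perturbRadius <- function(set, cfg) {
  stopifnot(is(cfg, "IRConfig"))
  df <- if (is(set, "AnnotationSet")) set@annotations else set
  zr <- stats::runif(nrow(df), min(0, cfg@s), max(0, cfg@s))
  df$r <- (1 + zr) * df$r
  if (is(set, "AnnotationSet")) {
    out <- set
    out@annotations <- df
    out
  } else df
}

#' Generate a simulated inaccurate-position set (Cp_o)
#'
#' For each expert annotation in the validation set, draws
#' \code{cfg@nPerAnnotation} independent IP-perturbed copies (default 4).
#' Only the validation set is used, to prevent leakage between training and
#' evaluation positions. Each output row carries a \code{source_id} column:
#' the row index of its source annotation in \code{V}.
#'
#' @param V the validation \linkS4class{AnnotationSet}.
#' @param cfg an \linkS4class{IPConfig} (supplies o, multiplicity and seed).
#' @return a simulated \linkS4class{AnnotationSet} named \code{Cp<o*100>}.
#' @examples
#' df <- data.frame(image_id = "im", x = c(100, 300), y = 100, r = 20,
#'                  label = "a")
#' V <- AnnotationSet(df, role = "validation", name = "V")
#' cp <- generateIPSet(V, ipConfig(o = 0.75, seed = 3))
#' nAnnotations(cp)  # 4 per source annotation
#' @export
generateIPSet <- function(V, cfg) {
  stopifnot(is(V, "AnnotationSet"), is(cfg, "IPConfig"))
  if (role(V) != "validation")
    warning("IP simulation is defined on the validation set; got role '",
            role(V), "'")
  df <- V@annotations
  if (!nrow(df)) {
    warning("empty validation set: returning an empty simulated set")
    rep <- df
  } else {
    rep <- df[rep(seq_len(nrow(df)), times = cfg@nPerAnnotation), ,
              drop = FALSE]
    rep$source_id <- rep(seq_len(nrow(df)), times = cfg@nPerAnnotation)
    rep <- withSeed(cfg@seed, perturbPosition(rep, cfg))
  }
  nm <- sprintf("Cp%s", format(cfg@o * 100))
  AnnotationSet(rep, role = "simulated", name = nm,
                provenance = sprintf("IP o=%s nPerAnnotation=%d seed=%d",
                                     format(cfg@o), cfg@nPerAnnotation,
                                     cfg@seed))
}

#' Generate a simulated inaccurate-radius set (Cr_s)
#'
#' One IR-perturbed copy per member of the validation set (multiplicity 1);
#' positions are preserved. Output rows carry a \code{source_id} column.
#'
#' @param V the validation \linkS4class{AnnotationSet}.
#' @param cfg an \linkS4class{IRConfig}.
#' @return a simulated \linkS4class{AnnotationSet} named \code{Cr<s>}.
#' @export
generateIRSet <- function(V, cfg) {
  stopifnot(is(V, "AnnotationSet"), is(cfg, "IRConfig"))
  df <- V@annotations
  if (!nrow(df)) warning("empty validation set: returning an empty simulated set")
  df$source_id <- seq_len(nrow(df))
  df <- withSeed(cfg@seed, perturbRadius(df, cfg))
  AnnotationSet(df, role = "simulated", name = sprintf("Cr%s", format(cfg@s)),
                provenance = sprintf("IR s=%s seed=%d", format(cfg@s),
                                     cfg@seed))
}

# normalize an image index: named list of matrices, or a data.frame
# (image_id, width, height) -> data.frame of extents
imageExtents <- function(images) {
  if (is.data.frame(images)) {
    stopifnot(all(c("image_id", "width", "height") %in% names(images)))
    return(images[, c("image_id", "width", "height")])
  }
  stopifnot(is.list(images), !is.null(names(images)))
  data.frame(image_id = names(images),
             width = vapply(images, ncol, integer(1)),
             height = vapply(images, nrow, integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate background false-positive annotations (Cbg)
#'
#' Places \code{cfg@perImage} background annotations per image (label
#' \code{"Background"}, patch size \code{cfg@patchSide} square, stored radius
#' \code{patchSide/2}) by rejection sampling, such that the patch lies fully
#' inside the image and the Euclidean distance from the background center to
#' every expert annotation center (x, y, r) on that image satisfies
#' \deqn{d((x_b, y_b), (x, y)) > r + \mathrm{exclusionSlack}.}
#'
#' @param images image index: a named list of image matrices, or a data.frame
#'   with columns image_id, width, height.
#' @param expert the expert \linkS4class{AnnotationSet} defining exclusion
#'   zones.
#' @param cfg an \linkS4class{FPConfig}.
#' @return a simulated \linkS4class{AnnotationSet} named \code{"Cbg"} with
#'   all labels \code{"Background"}.
#' @export
generateBackgroundFP <- function(images, expert, cfg) {
  stopifnot(is(expert, "AnnotationSet"), is(cfg, "FPConfig"))
  ext <- imageExtents(images)
  ex <- expert@annotations
  r0 <- cfg@patchSide / 2
  withSeed(cfg@seed, {
    rows <- lapply(seq_len(nrow(ext)), function(i) {
      id <- ext$image_id[i]
      W <- ext$width[i]; H <- ext$height[i]
      if (W < cfg@patchSide || H < cfg@patchSide)
        stop("image '", id, "' is smaller than the background patch")
      exi <- ex[ex$image_id == id, , drop = FALSE]
      xb <- numeric(cfg@perImage); yb <- numeric(cfg@perImage)
      for (k in seq_len(cfg@perImage)) {
        ok <- FALSE
        for (att in seq_len(cfg@maxAttempts)) {
          px <- stats::runif(1, r0, W - r0)
          py <- stats::runif(1, r0, H - r0)
          if (!nrow(exi) ||
              all(sqrt((px - exi$x)^2 + (py - exi$y)^2) >
                  exi$r + cfg@exclusionSlack)) {
            xb[k] <- px; yb[k] <- py; ok <- TRUE
            break
          }
        }
        if (!ok)
          stop("could not place a background annotation on image '", id,
               "' after ", cfg@maxAttempts, " attempts (image too crowded)")
      }
      if (cfg@perImage == 0L) return(NULL)
      data.frame(image_id = id, x = xb, y = yb, r = r0,
                 label = BACKGROUND_LABEL, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    if (is.null(df))
      df <- data.frame(image_id = character(), x = numeric(), y = numeric(),
                       r = numeric(), label = character(),
                       stringsAsFactors = FALSE)
    AnnotationSet(df, role = "simulated", name = "Cbg",
                  provenance = sprintf(
                    "FP perImage=%d patchSide=%s slack=%s seed=%d",
                    cfg@perImage, format(cfg@patchSide),
                    format(cfg@exclusionSlack), cfg@seed))
  })
}

#' Generate a CSP-like simulated set with Gaussian deviations (C_CSP)
#'
#' Emulates the behaviour observed in a small citizen-science primer
#' experiment by drawing radius-relative Gaussian deviations: per annotation,
#' \deqn{x' = x + D_x r, \quad y' = y + D_y r, \quad r' = R_r r}
#' with \eqn{D_x \sim N(\mu_{dx}, \sigma_{dx}^2)}, \eqn{D_y} analogous and
#' \eqn{R_r \sim N(\mu_{rr}, \sigma_{rr}^2)}. Sampled radii are kept strictly
#' positive: by default non-positive draws of \eqn{R_r} are clamped to
#' \code{clampFloor}; with \code{resample = TRUE} they are redrawn instead.
#'
#' @param V the validation \linkS4class{AnnotationSet}.
#' @param model a fitted or configured \linkS4class{GaussianDeviationModel}.
#' @param seed integer seed.
#' @param clampFloor positive floor for r'/r (default 0.05).
#' @param resample redraw instead of clamping non-positive radii.
#' @return a simulated \linkS4class{AnnotationSet} named \code{"CCSP"}.
#' @export
generateCSPLike <- function(V, model, seed = 1L, clampFloor = 0.05,
                            resample = FALSE) {
  stopifnot(is(V, "AnnotationSet"))
  if (missing(model) || is.null(model))
    stop("a GaussianDeviationModel must be supplied (fit one with ",
         "fitGaussianDeviationModel or configure it directly)")
  stopifnot(is(model, "GaussianDeviationModel"), clampFloor > 0)
  df <- V@annotations
  n <- nrow(df)
  df$source_id <- seq_len(n)
  withSeed(as.integer(seed), {
    dx <- stats::rnorm(n, model@muDx, model@sigmaDx)
    dy <- stats::rnorm(n, model@muDy, model@sigmaDy)
    rr <- stats::rnorm(n, model@muRr, model@sigmaRr)
    if (resample) {
      while (any(bad <- rr < clampFloor))
        rr[bad] <- stats::rnorm(sum(bad), model@muRr, model@sigmaRr)
    } else {
      rr <- pmax(rr, clampFloor)
    }
    df$x <- df$x + dx * df$r
    df$y <- df$y + dy * df$r
    df$r <- rr * df$r
  })
  AnnotationSet(df, role = "simulated", name = "CCSP",
                provenance = sprintf(
                  "CSP-like Gaussian dx~N(%g,%g) dy~N(%g,%g) rr~N(%g,%g) seed=%d",
                  model@muDx, model@sigmaDx, model@muDy, model@sigmaDy,
                  model@muRr, model@sigmaRr, as.integer(seed)))
}
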