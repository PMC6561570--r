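# independent oracles used across tests; deliberately written from first
# principles, not via the package's own geometry helpers

# random annotation data.frame spread over a virtual image collection
randomAnnotationDF <- function(n, nImages = 3, width = 500, height = 400,
                               rMax = 40, labels = c("a", "b", "c")) {
  data.frame(
    image_id = sample(sprintf("im%02d", seq_len(nImages)), n, replace = TRUE),
    x = runif(n, 0, width), y = runif(n, 0, height),
    r = runif(n, 1, rMax),
    label = sample(labels, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# all-pairs brute-force matcher: loops over every (cs, expert) pair and uses
# interval arithmetic written out longhand
bruteForceMatch <- function(cs, ex) {
  nValid <- 0L
  foundE <- rep(FALSE, nrow(ex))
  for (i in seq_len(nrow(cs))) {
    hitAny <- FALSE
    for (j in seq_len(nrow(ex))) {
      if (cs$image_id[i] != ex$image_id[j]) next
      xo <- min(cs$x[i] + cs$r[i], ex$x[j] + ex$r[j]) -
            max(cs$x[i] - cs$r[i], ex$x[j] - ex$r[j])
      yo <- min(cs$y[i] + cs$r[i], ex$y[j] + ex$r[j]) -
            max(cs$y[i] - cs$r[i], ex$y[j] - ex$r[j])
      if (xo > 0 && yo > 0) {
        hitAny <- TRUE
        foundE[j] <- TRUE
      }
    }
    if (hitAny) nValid <- nValid + 1L
  }
  list(n_cs = nrow(cs), n_valid = nValid, n_fp = nrow(cs) - nValid,
       n_expert = nrow(ex), n_found = sum(foundE),
       n_fn = nrow(ex) - sum(foundE))
}

# pixel-rasterization overlap oracle: samples a fine grid over the expert
# square and counts the fraction of sample points inside the cs square
rasterOverlap <- function(ex, cs, gridN = 400) {
  xs <- seq(ex$x - ex$r, ex$x + ex$r, length.out = gridN)
  ys <- seq(ex$y - ex$r, ex$y + ex$r, length.out = gridN)
  inX <- xs >= cs$x - cs$r & xs <= cs$x + cs$r
  inY <- ys >= cs$y - cs$r & ys <= cs$y + cs$r
  mean(inX) * mean(inY)
}

# small scene configuration used where full-size default scenes would waste
# test time
tinySceneConfig <- function(seed, size = 160L, nObj = c(2L, 4L),
                            rads = c(6, 14)) {
  sceneConfig(imageWidth = size, imageHeight = size, objectsPerImage = nObj,
              radiusRange = rads, seed = seed)
}

expectSetsEqual <- function(a, b) {
  expect_equal(annotations(a), annotations(b))
}
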