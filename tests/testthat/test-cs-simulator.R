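# simulated citizen-scientist generators: inaccurate position (IP),
# inaccurate radius (IR), background false positives (FP), Gaussian CSP-like

test_that("IP perturbation obeys the uniform shift law x' = x + Zx*r", {
  a <- AnnotationSet(data.frame(image_id = "im", x = 100, y = 100, r = 20,
                                label = "a"), role = "validation")
  # o = 1: interval degenerates to {0}, identity holds exactly
  out <- withSeed(1, perturbPosition(a, ipConfig(o = 1)))
  expect_identical(annotations(out)$x, 100)
  expect_identical(annotations(out)$y, 100)
  # o = 0.5, r = 20: 2(1-o)*r = 20, so x', y' stay within [80, 120]
  many <- annotations(a)[rep(1, 5000), ]
  out <- withSeed(2, perturbPosition(many, ipConfig(o = 0.5)))
  expect_true(all(out$x >= 80 & out$x <= 120))
  expect_true(all(out$y >= 80 & out$y <= 120))
  expect_identical(out$r, many$r)  # radius unchanged
})

test_that("IP per-axis overlap bound 1 - |dx|/(2r) >= o holds empirically", {
  a <- data.frame(image_id = "im", x = 0, y = 0, r = 10, label = "a")
  for (o in c(0.875, 0.75, 0.5)) {
    draws <- withSeed(100 + round(1000 * o),
                      perturbPosition(a[rep(1, 20000), ], ipConfig(o = o)))
    ovX <- 1 - abs(draws$x - a$x) / (2 * a$r)
    ovY <- 1 - abs(draws$y - a$y) / (2 * a$r)
    expect_true(all(ovX >= o) && all(ovY >= o))
    expect_lt(min(ovX) - o, 0.01)  # empirical minimum approaches the bound
  }
})

test_that("IR perturbation obeys r' = (1 + Zr)r with Zr ~ U(0, s)", {
  a <- data.frame(image_id = "im", x = 0, y = 0, r = 40, label = "a")
  many <- a[rep(1, 20000), ]
  up <- withSeed(3, perturbRadius(many, irConfig(0.25)))
  expect_true(all(up$r >= 40 & up$r <= 50))
  dn <- withSeed(4, perturbRadius(many, irConfig(-0.25)))
  expect_true(all(dn$r >= 30 & dn$r <= 40))
  expect_identical(dn$x, many$x)  # position unchanged
  # distributional check: (r'/r - 1)/s uniform on [0, 1]
  z <- (up$r / 40 - 1) / 0.25
  expect_gt(suppressWarnings(stats::ks.test(z, "punif")$p.value), 0.01)
  # config guards
  expect_error(irConfig(-1), "> -1")
  expect_error(irConfig(0), "nonzero")
})

test_that("generateIPSet draws four annotations per validation annotation", {
  set.seed(10)
  V <- AnnotationSet(randomAnnotationDF(100), role = "validation", name = "V")
  cp <- generateIPSet(V, ipConfig(o = 0.75, seed = 5))
  expect_equal(nAnnotations(cp), 400L)
  expect_identical(role(cp), "simulated")
  expect_identical(setName(cp), "Cp75")
  # traceability: labels and radii preserved per source
  df <- annotations(cp)
  src <- annotations(V)[df$source_id, ]
  expect_identical(df$label, src$label)
  expect_identical(df$r, src$r)
  expect_identical(df$image_id, src$image_id)
  # o = 1 with multiplicity 1 reproduces V's positions
  same <- generateIPSet(V, ipConfig(o = 1, nPerAnnotation = 1, seed = 5))
  expect_identical(annotations(same)$x, annotations(V)$x)
  # empty validation set -> empty set with warning
  emptyV <- AnnotationSet(annotations(V)[0, ], role = "validation")
  expect_warning(e <- generateIPSet(emptyV, ipConfig(o = 0.5)), "empty")
  expect_equal(nAnnotations(e), 0L)
})

test_that("generateIRSet has multiplicity 1 and bounded radius ratios", {
  set.seed(11)
  V <- AnnotationSet(randomAnnotationDF(100), role = "validation", name = "V")
  for (s in c(0.1, -0.1, 0.25, -0.25)) {
    cr <- generateIRSet(V, irConfig(s, seed = 6))
    expect_equal(nAnnotations(cr), 100L)
    ratio <- annotations(cr)$r / annotations(V)$r
    expect_true(all(ratio >= 1 + min(0, s) - 1e-12))
    expect_true(all(ratio <= 1 + max(0, s) + 1e-12))
    expect_identical(annotations(cr)$x, annotations(V)$x)
  }
})

test_that("background FP placement satisfies the distance constraint", {
  set.seed(12)
  idx <- data.frame(image_id = sprintf("im%02d", 1:10), width = 500,
                    height = 500)
  ex <- AnnotationSet(randomAnnotationDF(20, nImages = 10, width = 500,
                                         height = 500, rMax = 25),
                      role = "expert_all")
  cfg <- fpConfig(perImage = 2, seed = 7)
  bg <- generateBackgroundFP(idx, ex, cfg)
  expect_equal(nAnnotations(bg), 20L)  # exact per-image counts
  expect_true(all(annotations(bg)$label == BACKGROUND_LABEL))
  expect_true(all(annotations(bg)$r == 32))  # patchSide/2
  df <- annotations(bg); ed <- annotations(ex)
  perImage <- table(df$image_id)
  expect_true(all(perImage == 2))
  # brute-force constraint verification: d > r + 64 for every expert pair
  for (i in seq_len(nrow(df))) {
    e <- ed[ed$image_id == df$image_id[i], ]
    if (!nrow(e)) next
    d <- sqrt((df$x[i] - e$x)^2 + (df$y[i] - e$y)^2)
    expect_true(all(d > e$r + 64))
  }
  # patch fully inside the image
  expect_true(all(df$x >= 32 & df$x <= 468 & df$y >= 32 & df$y <= 468))
})

test_that("FP placement is vacuous without experts and fails when crowded", {
  idx <- data.frame(image_id = "im", width = 100, height = 100)
  none <- AnnotationSet(randomAnnotationDF(0))
  bg <- generateBackgroundFP(idx, none, fpConfig(perImage = 3, seed = 1))
  expect_equal(nAnnotations(bg), 3L)
  # an expert dead-center of a small image excludes every legal position
  crowd <- AnnotationSet(data.frame(image_id = "im", x = 50, y = 50, r = 30,
                                    label = "a"))
  expect_error(
    generateBackgroundFP(idx, crowd, fpConfig(perImage = 1, maxAttempts = 50,
                                              seed = 1)),
    "im")
})

test_that("CSP-like generator follows the Gaussian deviation model", {
  set.seed(13)
  V <- AnnotationSet(randomAnnotationDF(100), role = "validation", name = "V")
  # degenerate model (all sigmas 0, means (0,0,1)) reproduces V exactly
  degen <- gaussianDeviationModel(muDx = 0, sigmaDx = 0, muDy = 0,
                                  sigmaDy = 0, muRr = 1, sigmaRr = 0)
  out <- generateCSPLike(V, degen, seed = 3)
  expect_identical(annotations(out)$x, annotations(V)$x)
  expect_identical(annotations(out)$r, annotations(V)$r)
  # law of large numbers: sample means recover model means within 3 SE
  mod <- gaussianDeviationModel(muDx = 0.1, sigmaDx = 0.3, muDy = -0.05,
                                sigmaDy = 0.3, muRr = 1.2, sigmaRr = 0.2)
  Vbig <- AnnotationSet(randomAnnotationDF(10000), role = "validation")
  big <- generateCSPLike(Vbig, mod, seed = 4)
  dev <- pairDeviations(big, Vbig)
  expect_lt(abs(mean(dev$dx_rel) - 0.1), 3 * 0.3 / 100)
  expect_lt(abs(mean(dev$dy_rel) + 0.05), 3 * 0.3 / 100)
  expect_lt(abs(mean(dev$rel_radius) - 1.2), 3 * 0.2 / 100)
  # a heavy-tailed radius model can exceed 10x the expert radius
  wild <- gaussianDeviationModel(muRr = 8, sigmaRr = 4)
  ratios <- pairDeviations(generateCSPLike(Vbig, wild, seed = 5),
                           Vbig)$rel_radius
  expect_gt(max(ratios), 10)
  expect_true(all(ratios >= 0.05 - 1e-9))  # clamp floor (fp rounding slack)
  # missing model is a config error
  expect_error(generateCSPLike(V, NULL), "GaussianDeviationModel")
})

test_that("generators are reproducible per seed and never mutate inputs", {
  set.seed(14)
  V <- AnnotationSet(randomAnnotationDF(50), role = "validation", name = "V")
  before <- annotations(V)
  reps <- list(
    function() generateIPSet(V, ipConfig(0.75, seed = 21)),
    function() generateIRSet(V, irConfig(0.25, seed = 22)),
    function() generateCSPLike(V, gaussianDeviationModel(), seed = 23))
  for (f in reps) {
    expect_identical(annotations(f()), annotations(f()))
  }
  idx <- data.frame(image_id = unique(before$image_id), width = 600,
                    height = 600)
  bg1 <- generateBackgroundFP(idx, V, fpConfig(seed = 24))
  bg2 <- generateBackgroundFP(idx, V, fpConfig(seed = 24))
  expect_identical(annotations(bg1), annotations(bg2))
  expect_identical(annotations(V), before)
})
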