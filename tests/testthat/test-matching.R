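# matching CS annotations to expert annotations and quality statistics

test_that("overlapAreaFraction agrees with geometry and rasterization", {
  ex <- list(image_id = "im", x = 0, y = 0, r = 32)
  expect_equal(overlapAreaFraction(ex, ex), 1.0)
  cs <- list(image_id = "im", x = 32, y = 0, r = 32)
  expect_equal(overlapAreaFraction(ex, cs), 0.5)
  expect_equal(rasterOverlap(ex, cs), 0.5, tolerance = 0.01)
  # disjoint on one axis
  far <- list(image_id = "im", x = 64.5, y = 0, r = 32)
  expect_equal(overlapAreaFraction(ex, far), 0)
  # different images are a domain error
  other <- list(image_id = "im2", x = 0, y = 0, r = 32)
  expect_error(overlapAreaFraction(ex, other), "different images")
  # randomized pairs agree with the rasterization oracle
  set.seed(20)
  for (i in 1:25) {
    e <- list(image_id = "im", x = runif(1, 0, 50), y = runif(1, 0, 50),
              r = runif(1, 2, 20))
    c2 <- list(image_id = "im", x = runif(1, 0, 50), y = runif(1, 0, 50),
               r = runif(1, 2, 20))
    expect_equal(overlapAreaFraction(e, c2), rasterOverlap(e, c2),
                 tolerance = 0.02)
    # symmetry up to reference area
    expect_equal(overlapAreaFraction(e, c2) * (2 * e$r)^2,
                 overlapAreaFraction(c2, e) * (2 * c2$r)^2,
                 tolerance = 1e-9)
  }
})

test_that("matcher handles the degenerate extremes", {
  set.seed(21)
  ex <- AnnotationSet(randomAnnotationDF(30), role = "expert_all")
  copy <- AnnotationSet(annotations(ex))
  rep <- matchCSToExpert(copy, ex)
  expect_equal(rep@nValid, 30L)
  expect_equal(rep@nFP, 0L)
  expect_equal(rep@nFN, 0L)
  expect_true(all(matchPairs(rep)$overlap == 1))
  # shifted fully off all expert squares
  off <- annotations(ex)
  off$x <- off$x + 1000
  rep2 <- matchCSToExpert(AnnotationSet(off), ex)
  expect_equal(rep2@nValid, 0L)
  expect_equal(rep2@nFP, 30L)
  expect_equal(rep2@nFN, 30L)
})

test_that("matcher counts equal the all-pairs brute-force oracle", {
  set.seed(22)
  for (i in 1:30) {
    ex <- randomAnnotationDF(25, nImages = 2, width = 300, height = 300,
                             rMax = 30)
    cs <- randomAnnotationDF(25, nImages = 2, width = 300, height = 300,
                             rMax = 30)
    got <- matchCounts(matchCSToExpert(AnnotationSet(cs),
                                       AnnotationSet(ex)))
    want <- bruteForceMatch(cs, ex)
    expect_equal(as.list(got), want, info = paste("scene", i))
  }
})

test_that("ties go to the expert annotation with smaller center distance", {
  ex <- AnnotationSet(data.frame(image_id = "im", x = c(0, 30), y = 0,
                                 r = c(10, 10), label = c("L", "R")))
  # cs overlaps both with equal area but is nearer the right expert
  cs <- AnnotationSet(data.frame(image_id = "im", x = 18, y = 0, r = 10,
                                 label = NA))
  p <- matchPairs(matchCSToExpert(cs, ex))
  expect_equal(p$ex_label, "R")
})

test_that("deviation records use the matched expert as reference", {
  ex <- AnnotationSet(data.frame(image_id = "im", x = 100, y = 100, r = 10,
                                 label = "a"))
  same <- matchCSToExpert(AnnotationSet(annotations(ex)), ex)
  expect_equal(unlist(deviationStats(same)), c(dx_rel = 0, dy_rel = 0,
                                               rel_radius = 1, overlap = 1))
  shift <- AnnotationSet(data.frame(image_id = "im", x = 110, y = 100,
                                    r = 10, label = NA))
  expect_equal(deviationStats(matchCSToExpert(shift, ex))$dx_rel, 1)
  # the CSP extreme: a CS radius 12x the expert radius
  huge <- AnnotationSet(data.frame(image_id = "im", x = 100, y = 100,
                                   r = 120, label = NA))
  d <- deviationStats(matchCSToExpert(huge, ex))
  expect_equal(d$rel_radius, 12)
  expect_gt(d$rel_radius, 10)
  # empty pairs give an empty collection
  none <- matchCSToExpert(AnnotationSet(randomAnnotationDF(0)), ex)
  expect_equal(nrow(deviationStats(none)), 0L)
})

test_that("Gaussian model fitting removes outliers and recovers parameters", {
  rec0 <- data.frame(dx_rel = rep(0.2, 5), dy_rel = rep(-0.1, 5),
                     rel_radius = rep(1.5, 5), overlap = 1)
  m <- fitGaussianDeviationModel(rec0)
  expect_equal(c(m@muDx, m@sigmaDx, m@muDy, m@muRr), c(0.2, 0, -0.1, 1.5))
  # threshold Inf removes nothing; finite threshold drops outliers
  rec <- rbind(rec0, data.frame(dx_rel = 50, dy_rel = 0, rel_radius = 1,
                                overlap = 0))
  mAll <- fitGaussianDeviationModel(rec, outlierThreshold = Inf)
  expect_gt(mAll@sigmaDx, 1)
  mTrim <- fitGaussianDeviationModel(rec, outlierThreshold = 2)
  expect_equal(mTrim@sigmaDx, 0)
  expect_error(fitGaussianDeviationModel(rec0[1:2, ]), "fewer than 3")
  # parameter recovery from 1e4 Gaussian records within 5 percent
  set.seed(23)
  sim <- data.frame(dx_rel = rnorm(1e4, 0, 0.3), dy_rel = rnorm(1e4, 0, 0.3),
                    rel_radius = rnorm(1e4, 1.2, 0.2), overlap = 0.5)
  fit <- fitGaussianDeviationModel(sim, outlierThreshold = Inf)
  expect_equal(fit@sigmaDx, 0.3, tolerance = 0.05)
  expect_equal(fit@sigmaDy, 0.3, tolerance = 0.05)
  expect_equal(fit@muRr, 1.2, tolerance = 0.05)
  expect_equal(fit@sigmaRr, 0.2, tolerance = 0.05)
})

test_that("count summary reproduces the published percentage arithmetic", {
  # primer-experiment shape: 228 CS annotations, 82 valid
  csp <- new("MatchReport", nCS = 228L, nValid = 82L, nFP = 146L,
             nExpert = 42L, nFound = 21L, nFN = 21L, pairs = data.frame())
  p <- summarizeCounts(csp)$percent
  expect_equal(unname(p[c("valid", "fp", "found", "fn")]), c(36, 64, 50, 50))
  # main-study shape: 108 expert annotations, 70 found
  css <- new("MatchReport", nCS = 804L, nValid = 366L, nFP = 438L,
             nExpert = 108L, nFound = 70L, nFN = 38L, pairs = data.frame())
  p2 <- summarizeCounts(css)$percent
  expect_equal(unname(p2), c(46, 54, 65, 35))
  # empty CS set: valid/FP undefined, FN 100
  ex <- AnnotationSet(randomAnnotationDF(5))
  none <- matchCSToExpert(AnnotationSet(randomAnnotationDF(0)), ex)
  p3 <- summarizeCounts(none)$percent
  expect_true(is.na(p3["valid"]) && is.na(p3["fp"]))
  expect_equal(unname(p3["fn"]), 100)
})

test_that("IP deviation records keep unit radius and the per-axis bound", {
  set.seed(24)
  V <- AnnotationSet(randomAnnotationDF(80, nImages = 8, width = 2000,
                                        height = 2000, rMax = 20),
                     role = "validation", name = "V")
  o <- 0.75
  cp <- generateIPSet(V, ipConfig(o, seed = 31))
  dev <- pairDeviations(cp, V)
  expect_true(all(dev$rel_radius == 1))
  expect_true(all(abs(dev$dx_rel) <= 2 * (1 - o) + 1e-12))
  expect_true(all(abs(dev$dy_rel) <= 2 * (1 - o) + 1e-12))
})

test_that("simulate-then-fit closes: fitted model matches the generator", {
  set.seed(25)
  V <- AnnotationSet(randomAnnotationDF(5000, nImages = 10, width = 5000,
                                        height = 5000, rMax = 30),
                     role = "validation", name = "V")
  mod <- gaussianDeviationModel(muDx = 0.05, sigmaDx = 0.25, muDy = -0.02,
                                sigmaDy = 0.3, muRr = 1.3, sigmaRr = 0.15)
  sim <- generateCSPLike(V, mod, seed = 32)
  fit <- fitGaussianDeviationModel(pairDeviations(sim, V),
                                   outlierThreshold = Inf)
  expect_equal(fit@muDx, mod@muDx, tolerance = 0.2)
  expect_equal(fit@sigmaDx, mod@sigmaDx, tolerance = 0.03)
  expect_equal(fit@muRr, mod@muRr, tolerance = 0.02)
  expect_equal(fit@sigmaRr, mod@sigmaRr, tolerance = 0.03)
})

test_that("match reports export to CSV and JSON", {
  set.seed(26)
  ex <- AnnotationSet(randomAnnotationDF(20))
  cs <- AnnotationSet(randomAnnotationDF(20))
  rep <- matchCSToExpert(cs, ex)
  csvF <- withr::local_tempfile(fileext = ".csv")
  jsF <- withr::local_tempfile(fileext = ".json")
  exportMatchReport(rep, csvF, jsF)
  expect_equal(nrow(utils::read.csv(csvF)), rep@nValid)
  js <- jsonlite::fromJSON(jsF)
  expect_equal(js$counts$n_cs, 20)
})
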