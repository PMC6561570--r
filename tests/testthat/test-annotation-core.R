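# annotation data model, file I/O, and the train/validation split protocol

test_that("CSV load preserves records and validates radii", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("image_id,x,y,r,label",
               "im1,100.5,80.25,20,coral",
               "im1,40,60,5,",
               "im2,10,10,3,sponge"), f)
  s <- loadAnnotations(f, "csv")
  expect_equal(nAnnotations(s), 3L)
  expect_identical(annotations(s)$label, c("coral", NA, "sponge"))
  expect_equal(annotations(s)$x, c(100.5, 40, 10))

  writeLines(c("image_id,x,y,r,label", "im1,10,10,0,a"), f)
  expect_error(loadAnnotations(f, "csv"), "radius")
  writeLines(c("image_id,x,y,label", "im1,10,10,a"), f)
  expect_error(loadAnnotations(f, "csv"), "missing required column")
  writeLines(c("image_id,x,y,r,label", "im1,10,notanumber,4,a"), f)
  expect_error(loadAnnotations(f, "csv"))
  expect_error(loadAnnotations("no/such/file.csv", "csv"), "exist")
})

test_that("empty and single-annotation sets survive a save/load round trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  empty <- AnnotationSet(data.frame(image_id = character(), x = numeric(),
                                    y = numeric(), r = numeric(),
                                    label = character()))
  saveAnnotations(empty, f, "csv")
  expect_equal(nAnnotations(loadAnnotations(f, "csv")), 0L)

  one <- AnnotationSet(data.frame(image_id = "im", x = 1.25, y = 2.5, r = 3,
                                  label = "a"))
  for (dialect in c("csv", "coco_json")) {
    saveAnnotations(one, f, dialect)
    expect_equal(annotations(loadAnnotations(f, dialect)), annotations(one))
  }
})

test_that("round-trip I/O is lossless for both dialects on randomized sets", {
  f <- withr::local_tempfile(fileext = ".dat")
  set.seed(42)
  for (i in 1:50) {
    df <- randomAnnotationDF(sample(1:40, 1))
    if (i %% 3 == 0) df$label <- NA_character_  # unlabeled CS detections
    s <- AnnotationSet(df)
    dialect <- if (i %% 2 == 0) "csv" else "coco_json"
    saveAnnotations(s, f, dialect)
    back <- loadAnnotations(f, dialect)
    expect_equal(annotations(back), annotations(s),
                 info = sprintf("case %d (%s)", i, dialect))
  }
  # a larger set, both dialects, exact equality including full precision
  big <- AnnotationSet(randomAnnotationDF(1000))
  for (dialect in c("csv", "coco_json")) {
    saveAnnotations(big, f, dialect)
    expect_identical(annotations(loadAnnotations(f, dialect))$x,
                     annotations(big)$x)
    expect_equal(annotations(loadAnnotations(f, dialect)), annotations(big))
  }
})

test_that("COCO dialect encodes square markers as bbox [x-r, y-r, 2r, 2r]", {
  f <- withr::local_tempfile(fileext = ".json")
  s <- AnnotationSet(data.frame(image_id = "im", x = 100, y = 50, r = 20,
                                label = "a"))
  saveAnnotations(s, f, "coco_json")
  js <- jsonlite::fromJSON(f)
  expect_equal(unlist(js$annotations$bbox), c(80, 30, 40, 40))
  expect_equal(js$categories$name, "a")
})

test_that("validity rules catch bad sets", {
  expect_error(AnnotationSet(data.frame(image_id = "im", x = 1, y = 1, r = -2,
                                        label = "a")), "radii")
  expect_error(AnnotationSet(data.frame(image_id = "im", x = 1, y = 1, r = 2,
                                        label = NA_character_),
                             role = "train"), "label-complete")
  expect_error(AnnotationSet(data.frame(image_id = "im", x = 1, y = 1, r = 2,
                                        label = "a"), role = "bogus"), "role")
})

test_that("90/10 split produces |T| = round(0.9 |A|) with T, V a partition", {
  set.seed(1)
  A <- AnnotationSet(randomAnnotationDF(1000), role = "expert_all")
  sp <- splitTrainVal(A, 0.9, seed = 7)
  expect_equal(nAnnotations(sp$train), 900L)
  expect_equal(nAnnotations(sp$validation), 100L)
  expect_identical(role(sp$train), "train")
  expect_identical(role(sp$validation), "validation")
  # same seed -> identical partition
  sp2 <- splitTrainVal(A, 0.9, seed = 7)
  expect_equal(annotations(sp2$train), annotations(sp$train))
  # different seeds -> different partitions (sanity, |A| large)
  sp3 <- splitTrainVal(A, 0.9, seed = 8)
  expect_false(identical(annotations(sp3$train), annotations(sp$train)))
})

test_that("split conserves annotations and is disjoint over random sets", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(2:60, 1)
    A <- AnnotationSet(randomAnnotationDF(n), role = "expert_all")
    frac <- runif(1, 0.2, 0.95)
    sp <- splitTrainVal(A, frac, seed = i)
    expect_equal(nAnnotations(sp$train) + nAnnotations(sp$validation), n)
    expect_equal(nAnnotations(sp$train), round(frac * n))
    both <- rbind(annotations(sp$train), annotations(sp$validation))
    reord <- both[order(both$image_id, both$x, both$y, both$r), ]
    orig <- annotations(A)
    orig <- orig[order(orig$image_id, orig$x, orig$y, orig$r), ]
    rownames(reord) <- rownames(orig) <- NULL
    expect_equal(reord, orig)
  }
})

test_that("split guards: degenerate sets, bad fractions, stratified modes", {
  A1 <- AnnotationSet(data.frame(image_id = "im", x = 1, y = 1, r = 2,
                                 label = "a"), role = "expert_all")
  expect_error(splitTrainVal(A1, 0.9), "fewer than 2")
  A <- AnnotationSet(randomAnnotationDF(100), role = "expert_all")
  expect_error(splitTrainVal(A, 1.0), "strictly between")
  expect_error(splitTrainVal(A, 0), "strictly between")
  unl <- AnnotationSet(data.frame(image_id = "im", x = 1:3, y = 1, r = 2,
                                  label = NA_character_))
  expect_error(splitTrainVal(unl, 0.5), "label-complete")

  spL <- splitTrainVal(A, 0.8, seed = 1, stratify = "label")
  tl <- table(annotations(spL$train)$label)
  al <- table(annotations(A)$label)
  expect_equal(as.numeric(tl), round(0.8 * as.numeric(al)))
  spI <- splitTrainVal(A, 0.7, seed = 1, stratify = "image")
  expect_length(intersect(unique(annotations(spI$train)$image_id),
                          unique(annotations(spI$validation)$image_id)), 0)
})
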