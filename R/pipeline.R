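#' Default run configuration
#'
#' One nested list holding every stage's parameters plus a single global
#' seed; each stage's own seed is derived deterministically from the global
#' seed via a named substream ([deriveSeed()]), so changing one stage's
#' parameters does not shift another stage's draws.
#'
#' @param seed global integer seed.
#' @param outDir output directory.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(seed = 1L, outDir = "csannosim_out") {
  list(
    seed = as.integer(seed),
    outDir = outDir,
    scene = list(nImages = 100L, imageWidth = 512L, imageHeight = 512L,
                 nClasses = 6L, objectsPerImage = c(3L, 8L),
                 radiusRange = c(8, 32)),
    split = list(trainFraction = 0.9, stratify = "none"),
    ip = list(os = c(0.875, 0.75, 0.5), nPerAnnotation = 4L),
    ir = list(ss = c(0.1, -0.1, 0.25, -0.25)),
    fp = list(perImage = 2L, patchSide = 64, exclusionSlack = 64),
    csp = list(muDx = 0, sigmaDx = 0.5, muDy = 0, sigmaDy = 0.5,
               muRr = 2, sigmaRr = 1),
    classifier = list(outSide = 64L))
}

#' Read a run configuration from a YAML file
#'
#' Values present in the file override the defaults; everything else keeps
#' its default.
#'
#' @param path YAML file (NULL for pure defaults).
#' @param seed optional global seed override.
#' @return nested configuration list.
#' @export
readRunConfig <- function(path = NULL, seed = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

.sceneConfigFrom <- function(cfg) {
  s <- cfg$scene
  sceneConfig(imageWidth = s$imageWidth, imageHeight = s$imageHeight,
              nClasses = s$nClasses,
              objectsPerImage = as.integer(s$objectsPerImage),
              radiusRange = as.numeric(s$radiusRange),
              seed = deriveSeed(cfg$seed, "scene"))
}

.cspModelFrom <- function(cfg) {
  m <- cfg$csp
  gaussianDeviationModel(muDx = m$muDx, sigmaDx = m$sigmaDx, muDy = m$muDy,
                         sigmaDy = m$sigmaDy, muRr = m$muRr,
                         sigmaRr = m$sigmaRr)
}

# short content hash for manifests (no cryptographic ambition)
.configHash <- function(x) {
  s <- yaml::as.yaml(x)
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the complete pipeline
#'
#' Generates the synthetic dataset, splits it 90/10 (by default), runs the
#' simulated-citizen-scientist experiment grid, and writes all artifacts
#' (annotation CSVs, the grid report as CSV and JSON, and a manifest
#' recording the configuration hash, seed and package version) under
#' \code{cfg$outDir}.
#'
#' @param cfg configuration list from [readRunConfig()] or
#'   [defaultRunConfig()].
#' @param writeImages also write the rendered PNGs (default FALSE; they can
#'   always be re-rendered from the manifest).
#' @return invisibly, a list with the dataset, the split, and the grid
#'   result.
#' @export
runPipeline <- function(cfg = defaultRunConfig(), writeImages = FALSE) {
  t0 <- Sys.time()
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  logLine <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(fmt, ...))
    cat(msg, "\n", file = file.path(cfg$outDir, "run.log"), append = TRUE)
    message(msg)
  }
  logLine("synth: %d images", cfg$scene$nImages)
  ds <- generateDataset(cfg$scene$nImages, .sceneConfigFrom(cfg))
  saveAnnotations(ds$expert, file.path(cfg$outDir, "expert.csv"), "csv")
  if (writeImages) writeImagePNG(ds$images, file.path(cfg$outDir, "images"))
  logLine("split: fraction %.2f", cfg$split$trainFraction)
  sp <- splitTrainVal(ds$expert, cfg$split$trainFraction,
                      seed = deriveSeed(cfg$seed, "split"),
                      stratify = cfg$split$stratify)
  saveAnnotations(sp$train, file.path(cfg$outDir, "train.csv"), "csv")
  saveAnnotations(sp$validation, file.path(cfg$outDir, "validation.csv"),
                  "csv")
  logLine("grid: training + %d IP + %d IR + CSP + Cbg columns",
          length(cfg$ip$os), length(cfg$ir$ss))
  grid <- runExperimentGrid(
    sp$train, sp$validation, ds$images, expert = ds$expert,
    ipOs = cfg$ip$os, irSs = cfg$ir$ss, cspModel = .cspModelFrom(cfg),
    fpCfg = fpConfig(perImage = cfg$fp$perImage,
                     patchSide = cfg$fp$patchSide,
                     exclusionSlack = cfg$fp$exclusionSlack),
    outSide = cfg$classifier$outSide,
    nPerAnnotation = cfg$ip$nPerAnnotation, seed = cfg$seed)
  writeGridReport(grid$report, file.path(cfg$outDir, "grid_report.csv"),
                  file.path(cfg$outDir, "grid_report.json"))
  manifest <- list(config = cfg, configHash = .configHash(cfg),
                   seed = cfg$seed,
                   package = as.character(utils::packageVersion("csannosim")),
                   rVersion = R.version.string,
                   elapsedSec = as.numeric(difftime(Sys.time(), t0,
                                                    units = "secs")))
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  logLine("done in %.1f s", manifest$elapsedSec)
  invisible(list(dataset = ds, split = sp, grid = grid))
}

## ---- command line ----

.parseCliArgs <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      opts[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  opts
}

.loadImagesDir <- function(dir) {
  files <- list.files(dir, pattern = "\\.png$", full.names = TRUE)
  if (!length(files)) stop("no PNG images found in ", dir)
  imgs <- lapply(files, readImagePNG)
  names(imgs) <- sub("\\.png$", "", basename(files))
  imgs
}

#' Command-line entry point
#'
#' Thin dispatcher over the package's exported functions; the installed
#' script \code{inst/scripts/csannosim-cli} forwards \code{commandArgs(TRUE)}
#' here. Subcommands: \code{synth}, \code{split}, \code{simulate},
#' \code{match}, \code{stats}, \code{train}, \code{evaluate}, \code{grid},
#' \code{fixtures}. Returns the exit status (0 success, 1 stage failure,
#' 2 usage error) instead of quitting, so it is testable in-process.
#'
#' @param args character vector of command-line arguments; the first element
#'   is the subcommand, the rest \code{--key value} options.
#' @return integer exit status.
#' @export
cliMain <- function(args) {
  usage <- function() {
    cat("usage: csannosim-cli <command> [--key value ...]\n",
        "commands: synth split simulate match stats train evaluate grid fixtures\n")
    2L
  }
  if (!length(args)) return(usage())
  cmd <- args[[1]]
  known <- c("synth", "split", "simulate", "match", "stats", "train",
             "evaluate", "grid", "fixtures")
  if (!cmd %in% known) {
    message("unknown command: ", cmd)
    return(usage())
  }
  opts <- tryCatch(.parseCliArgs(args[-1]),
                   error = function(e) {
                     message(conditionMessage(e)); NULL
                   })
  if (is.null(opts)) return(2L)
  num <- function(k, d = NULL) if (!is.null(opts[[k]]))
    as.numeric(opts[[k]]) else d
  chr <- function(k, d = NULL) if (!is.null(opts[[k]]))
    as.character(opts[[k]]) else d
  status <- tryCatch({
    switch(cmd,
      synth = {
        out <- chr("out", "synth_out")
        cfg <- sceneConfig(imageWidth = as.integer(num("size", 512)),
                           imageHeight = as.integer(num("size", 512)),
                           seed = as.integer(num("seed", 1)))
        ds <- generateDataset(as.integer(num("n", 10)), cfg)
        writeImagePNG(ds$images, file.path(out, "images"))
        saveAnnotations(ds$expert, file.path(out, "annotations.csv"), "csv")
        show(ds$meta)
      },
      split = {
        set <- loadAnnotations(chr("annotations"), "csv", role = "expert_all")
        sp <- splitTrainVal(set, num("fraction", 0.9),
                            seed = as.integer(num("seed", 1)))
        out <- chr("out", dirname(chr("annotations")))
        saveAnnotations(sp$train, file.path(out, "train.csv"), "csv")
        saveAnnotations(sp$validation, file.path(out, "validation.csv"),
                        "csv")
      },
      simulate = {
        kind <- chr("kind")
        V <- loadAnnotations(chr("annotations"), "csv", role = "validation",
                             name = "V")
        seed <- as.integer(num("seed", 1))
        set <- switch(kind,
          ip = generateIPSet(V, ipConfig(num("o"), seed = seed)),
          ir = generateIRSet(V, irConfig(num("s"), seed = seed)),
          fp = generateBackgroundFP(.loadImagesDir(chr("images")), V,
                                    fpConfig(seed = seed)),
          csp = generateCSPLike(V, gaussianDeviationModel(), seed = seed),
          stop("unknown --kind: ", kind))
        saveAnnotations(set, chr("out", "simulated.csv"), "csv")
      },
      match = ,
      stats = {
        cs <- loadAnnotations(chr("cs"), "csv", name = "CS")
        expert <- loadAnnotations(chr("expert"), "csv", role = "expert_all",
                                  name = "A")
        rep <- matchCSToExpert(cs, expert)
        if (cmd == "match") {
          out <- chr("out", ".")
          dir.create(out, showWarnings = FALSE, recursive = TRUE)
          exportMatchReport(rep, file.path(out, "pairs.csv"),
                            file.path(out, "summary.json"))
        }
        show(rep)
      },
      train = {
        imgs <- .loadImagesDir(chr("images"))
        set <- loadAnnotations(chr("annotations"), "csv", role = "train",
                               name = "T")
        pd <- buildPatchDataset(imgs, set, as.integer(num("patch", 64)))
        model <- trainClassifier(pd, seed = as.integer(num("seed", 1)))
        saveRDS(model, chr("out", "model.rds"))
        show(model)
      },
      evaluate = {
        model <- readRDS(chr("model"))
        imgs <- .loadImagesDir(chr("images"))
        set <- loadAnnotations(chr("annotations"), "csv", role = "validation",
                               name = chr("name", "V"))
        tab <- evaluateSet(model, set, imgs, model@outSide)
        show(tab)
        if (!is.null(opts$out))
          jsonlite::write_json(list(perClass = as.list(perClassAccuracy(tab)),
                                    macroAvg = macroAccuracy(tab),
                                    weightedAvg = weightedAccuracy(tab)),
                               chr("out"), auto_unbox = TRUE, digits = NA)
      },
      grid = {
        cfg <- readRunConfig(chr("config"), seed = num("seed"))
        if (!is.null(opts$out)) cfg$outDir <- chr("out")
        runPipeline(cfg)
      },
      fixtures = {
        makeFixtureDataset(chr("out", "fixtures"),
                           seed = as.integer(num("seed", 1)))
      })
    0L
  }, error = function(e) {
    message("stage failure: ", conditionMessage(e))
    1L
  })
  status
}
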