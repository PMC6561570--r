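#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{code} with the global random number generator seeded to
#' \code{seed}, then restores the previous RNG state so callers are not
#' perturbed. All stochastic operations in this package funnel through this
#' helper, which is what makes every generator bitwise reproducible given
#' (config, seed).
#'
#' @param seed integer seed, or NULL to run against the current RNG state.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @export
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific seed from a global seed
#'
#' Deterministic fan-out of one global seed into named substreams, so changing
#' one stage's parameters never shifts another stage's draws. The result is
#' always a valid 32-bit integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed below 2^31.
#' @export
deriveSeed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483647
  h <- 17
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% m
  as.integer((h + (as.numeric(seed) %% m) * 48271) %% m)
}

# bilinear resize of a numeric matrix to outH x outW; exact identity when the
# size is unchanged (needed so an unperturbed crop round-trips bit-exactly)
bilinearResize <- function(mat, outH, outW) {
  h <- nrow(mat); w <- ncol(mat)
  if (h == outH && w == outW) return(mat)
  posR <- (seq_len(outH) - 0.5) * (h / outH) - 0.5
  posC <- (seq_len(outW) - 0.5) * (w / outW) - 0.5
  r0 <- pmin(pmax(floor(posR), 0), h - 1); fr <- pmin(pmax(posR - r0, 0), 1)
  c0 <- pmin(pmax(floor(posC), 0), w - 1); fc <- pmin(pmax(posC - c0, 0), 1)
  r1 <- pmin(r0 + 1, h - 1); c1 <- pmin(c0 + 1, w - 1)
  m00 <- mat[r0 + 1, c0 + 1, drop = FALSE]
  m01 <- mat[r0 + 1, c1 + 1, drop = FALSE]
  m10 <- mat[r1 + 1, c0 + 1, drop = FALSE]
  m11 <- mat[r1 + 1, c1 + 1, drop = FALSE]
  wr <- matrix(fr, outH, outW)
  wc <- matrix(fc, outH, outW, byrow = TRUE)
  m00 * (1 - wr) * (1 - wc) + m01 * (1 - wr) * wc +
    m10 * wr * (1 - wc) + m11 * wr * wc
}

# circular Gaussian smoothing of a matrix via FFT (separable kernel);
# sigma in pixels is the correlation length of the smoothed field
smoothField <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  h <- nrow(mat); w <- ncol(mat)
  ky <- circKernel(h, sigma); kx <- circKernel(w, sigma)
  fk <- Re(stats::fft(ky)) %o% Re(stats::fft(kx))
  Re(stats::fft(stats::fft(mat) * fk, inverse = TRUE)) / (h * w)
}

circKernel <- function(n, sigma) {
  d <- 0:(n - 1)
  d <- pmin(d, n - d)
  k <- exp(-0.5 * (d / sigma)^2)
  k / sum(k)
}

# full-precision numeric formatting for text round-trips
numToChr <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  gsub(" ", "", out)
}
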