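#' Area overlap of two square annotations
#'
#' Fraction of the \emph{expert} square's area covered by the CS square
#' (axis-aligned intersection over the expert area; 0 if disjoint). The
#' expert square is the reference because citizen-science squares are often
#' much larger, and near-complete overlap of generous CS markers is only
#' coherent with the expert square as denominator. The symmetric identity
#' \code{overlap(a,b) * area(a) == overlap(b,a) * area(b)} holds.
#'
#' @param expert,cs single annotations: 1-row data.frames or lists with
#'   \code{x}, \code{y}, \code{r}, \code{image_id}.
#' @return overlap fraction in [0, 1].
#' @examples
#' a <- list(image_id = "im", x = 0, y = 0, r = 32)
#' b <- list(image_id = "im", x = 32, y = 0, r = 32)
#' overlapAreaFraction(a, b)  # 0.5
#' @export
overlapAreaFraction <- function(expert, cs) {
  if (!identical(as.character(expert$image_id), as.character(cs$image_id)))
    stop("annotations lie on different images: '", expert$image_id, "' vs '",
         cs$image_id, "'")
  .overlapVec(expert$x, expert$y, expert$r, cs$x, cs$y, cs$r)
}

# vectorized square-intersection overlap, expert area as denominator
.overlapVec <- function(ex, ey, er, cx, cy, cr) {
  w <- pmax(0, pmin(ex + er, cx + cr) - pmax(ex - er, cx - cr))
  h <- pmax(0, pmin(ey + er, cy + cr) - pmax(ey - er, cy - cr))
  pmin(w * h / (4 * er * er), 1)
}

#' Match citizen-science annotations against expert annotations
#'
#' A CS annotation is \emph{valid} iff its area overlap with at least one
#' expert annotation on the same image is > 0, otherwise it is a false
#' positive. Each valid CS annotation is paired with the expert annotation of
#' maximal overlap (ties broken by smaller center distance, then stable input
#' order). An expert annotation is \emph{found} iff at least one CS
#' annotation overlaps it (many-to-one matching is allowed: several CS
#' annotations may be valid against the same expert annotation). The
#' remaining expert annotations are false negatives.
#'
#' @param cs the citizen-science (or simulated) \linkS4class{AnnotationSet}.
#' @param expert the expert \linkS4class{AnnotationSet}.
#' @return a \linkS4class{MatchReport}.
#' @export
matchCSToExpert <- function(cs, expert) {
  stopifnot(is(cs, "AnnotationSet"), is(expert, "AnnotationSet"))
  cdf <- cs@annotations
  edf <- expert@annotations
  nC <- nrow(cdf); nE <- nrow(edf)
  foundE <- logical(nE)
  pairRows <- vector("list", nC)
  valid <- logical(nC)
  eByImage <- split(seq_len(nE), edf$image_id)
  for (i in seq_len(nC)) {
    eIdx <- eByImage[[cdf$image_id[i]]]
    if (is.null(eIdx)) next
    ov <- .overlapVec(edf$x[eIdx], edf$y[eIdx], edf$r[eIdx],
                      cdf$x[i], cdf$y[i], cdf$r[i])
    hit <- ov > 0
    if (!any(hit)) next
    valid[i] <- TRUE
    foundE[eIdx[hit]] <- TRUE
    best <- which(ov == max(ov))
    if (length(best) > 1) {
      d2 <- (edf$x[eIdx[best]] - cdf$x[i])^2 + (edf$y[eIdx[best]] - cdf$y[i])^2
      best <- best[which(d2 == min(d2))]
      best <- best[1]  # stable input order on residual tie
    }
    j <- eIdx[best]
    pairRows[[i]] <- data.frame(
      cs_index = i, expert_index = j, image_id = cdf$image_id[i],
      cs_x = cdf$x[i], cs_y = cdf$y[i], cs_r = cdf$r[i],
      ex_x = edf$x[j], ex_y = edf$y[j], ex_r = edf$r[j],
      ex_label = edf$label[j], overlap = ov[best],
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairRows[valid])
  if (is.null(pairs))
    pairs <- data.frame(cs_index = integer(), expert_index = integer(),
                        image_id = character(), cs_x = numeric(),
                        cs_y = numeric(), cs_r = numeric(), ex_x = numeric(),
                        ex_y = numeric(), ex_r = numeric(),
                        ex_label = character(), overlap = numeric(),
                        stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  new("MatchReport", nCS = nC, nValid = sum(valid), nFP = nC - sum(valid),
      nExpert = nE, nFound = sum(foundE), nFN = nE - sum(foundE),
      pairs = pairs)
}

#' Per-match deviation records
#'
#' One record per matched pair, using the matched expert annotation as
#' reference: \code{dx_rel = (x'-x)/r}, \code{dy_rel = (y'-y)/r},
#' \code{rel_radius = r'/r}, and the area \code{overlap} fraction.
#'
#' @param report a \linkS4class{MatchReport} with at least one pair (an empty
#'   report yields an empty data.frame).
#' @return data.frame with columns dx_rel, dy_rel, rel_radius, overlap.
#' @export
deviationStats <- function(report) {
  stopifnot(is(report, "MatchReport"))
  p <- report@pairs
  data.frame(dx_rel = (p$cs_x - p$ex_x) / p$ex_r,
             dy_rel = (p$cs_y - p$ex_y) / p$ex_r,
             rel_radius = p$cs_r / p$ex_r,
             overlap = p$overlap)
}

#' Deviation records via simulator traceability
#'
#' Simulated sets carry a \code{source_id} column naming the source row in
#' the set they were generated from. This pairs each simulated annotation
#' with its true source directly, bypassing the overlap matcher — useful when
#' closing the simulate-then-fit loop, where occasional nearest-neighbour
#' mismatches would otherwise contaminate parameter recovery.
#'
#' @param cs a simulated \linkS4class{AnnotationSet} with a source_id column.
#' @param source the set it was generated from.
#' @return data.frame with columns dx_rel, dy_rel, rel_radius, overlap.
#' @export
pairDeviations <- function(cs, source) {
  stopifnot(is(cs, "AnnotationSet"), is(source, "AnnotationSet"))
  cdf <- cs@annotations
  if (!"source_id" %in% names(cdf))
    stop("the simulated set carries no source_id column")
  sdf <- source@annotations[cdf$source_id, , drop = FALSE]
  data.frame(dx_rel = (cdf$x - sdf$x) / sdf$r,
             dy_rel = (cdf$y - sdf$y) / sdf$r,
             rel_radius = cdf$r / sdf$r,
             overlap = .overlapVec(sdf$x, sdf$y, sdf$r, cdf$x, cdf$y, cdf$r))
}

#' Fit a Gaussian deviation model from observed deviation records
#'
#' Removes outlier records whose absolute relative position deviation on
#' either axis exceeds \code{outlierThreshold}, then summarizes the surviving
#' dx_rel, dy_rel and rel_radius each by sample mean and sample standard
#' deviation.
#'
#' @param records data.frame of deviation records (from [deviationStats()] or
#'   [pairDeviations()]).
#' @param outlierThreshold absolute threshold on |dx_rel| and |dy_rel|
#'   (default 2; use \code{Inf} to keep everything).
#' @return a \linkS4class{GaussianDeviationModel}.
#' @export
fitGaussianDeviationModel <- function(records, outlierThreshold = 2) {
  keep <- abs(records$dx_rel) <= outlierThreshold &
          abs(records$dy_rel) <= outlierThreshold
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) < 3)
    stop("fewer than 3 records survive outlier removal; cannot fit")
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  new("GaussianDeviationModel",
      muDx = mean(rec$dx_rel), sigmaDx = sd0(rec$dx_rel),
      muDy = mean(rec$dy_rel), sigmaDy = sd0(rec$dy_rel),
      muRr = mean(rec$rel_radius), sigmaRr = sd0(rec$rel_radius))
}

#' Summarize match counts as percentages
#'
#' Valid and false-positive percentages use the CS total as denominator;
#' found and false-negative percentages use the expert total. With a zero
#' denominator the corresponding entries are \code{NA} (undefined), not
#' division failures. Percentages are rounded for display only; the raw
#' counts are included.
#'
#' @param report a \linkS4class{MatchReport}.
#' @param digits rounding for the display percentages (default 0).
#' @return a list with \code{counts} (named integer vector) and
#'   \code{percent} (named numeric vector: valid, fp, found, fn).
#' @examples
#' r <- new("MatchReport", nCS = 228L, nValid = 82L, nFP = 146L,
#'          nExpert = 42L, nFound = 21L, nFN = 21L, pairs = data.frame())
#' summarizeCounts(r)$percent  # valid 36, fp 64, found 50, fn 50
#' @export
summarizeCounts <- function(report, digits = 0) {
  stopifnot(is(report, "MatchReport"))
  pct <- function(num, den) if (den == 0) NA_real_ else
    round(100 * num / den, digits)
  list(counts = matchCounts(report),
       percent = c(valid = pct(report@nValid, report@nCS),
                   fp = pct(report@nFP, report@nCS),
                   found = pct(report@nFound, report@nExpert),
                   fn = pct(report@nFN, report@nExpert)))
}

#' Export a match report to CSV / JSON
#'
#' Writes the matched pairs (with their deviation records) as CSV and the
#' count summary as JSON.
#'
#' @param report a \linkS4class{MatchReport}.
#' @param pairsPath CSV output for the pairs (NULL to skip).
#' @param summaryPath JSON output for the summary (NULL to skip).
#' @return invisibly, the summary list.
#' @export
exportMatchReport <- function(report, pairsPath = NULL, summaryPath = NULL) {
  if (!is.null(pairsPath)) {
    out <- cbind(report@pairs, deviationStats(report)[
      c("dx_rel", "dy_rel", "rel_radius")])
    utils::write.csv(out, pairsPath, row.names = FALSE)
  }
  summ <- summarizeCounts(report)
  if (!is.null(summaryPath))
    jsonlite::write_json(lapply(summ, as.list), summaryPath,
                         auto_unbox = TRUE, digits = NA, na = "null")
  invisible(summ)
}
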