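#' Floor low signals
#'
#' Raw fluorescence values below `floor` (default 5 units) are raised to
#' the floor before any normalization, so the log transform is defined
#' and near-background noise does not dominate the low end of the
#' normalization curve.
#'
#' @param x an [IntensityExperiment-class].
#' @param floor positive floor, linear units.
#' @return the experiment with floored `signal`.
#' @export
floorSignal <- function(x, floor = 5) {
  stopifnot(is(x, "IntensityExperiment"))
  if (!is.numeric(floor) || floor <= 0) configError("'floor' must be > 0")
  sig <- SummarizedExperiment::assay(x, "signal")
  SummarizedExperiment::assay(x, "signal") <- pmax(sig, floor)
  S4Vectors::metadata(x)$floor <- floor
  x
}

#' Select the baseline array
#'
#' The baseline is the array whose per-array median signal is the median
#' of all per-array medians; with an even number of arrays the
#' lower-median array is taken, and residual ties resolve to the lowest
#' array index.
#'
#' @param x an [IntensityExperiment-class] or a numeric matrix with one
#'   column per array.
#' @return the baseline array id (column name).
#' @export
selectBaselineArray <- function(x) {
  m <- if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "signal") else as.matrix(x)
  if (ncol(m) < 1L) usageError("no arrays to choose a baseline from")
  meds <- apply(m, 2L, stats::median)
  k <- floor((length(meds) + 1) / 2)  # lower median for even counts
  target <- meds[order(meds)[k]]
  colnames(m)[min(which(meds == target))]
}

#' Rank-invariant probe selection between two arrays
#'
#' Iterative scheme for finding probes whose intensity rank is (nearly)
#' the same on a target and a baseline array, and which can therefore be
#' presumed unregulated and used to anchor a normalization curve.
#' Starting from all features, each round ranks the current set on both
#' arrays (ties to average rank) and retains features whose absolute
#' rank difference is at most `thresholdFraction` times the current set
#' size, stopping at a fixed point or after `maxIter` rounds.  The
#' iteration also stops, returning the last admissible set, rather than
#' contracting below `minSize` features; with noisy replicates the pure
#' rank-band iteration otherwise contracts geometrically toward the
#' empty set (re-ranking within the surviving subset does not shrink the
#' relative rank jitter).  Set `minSize = 1` to run the unguarded
#' scheme, which errors if the set would become empty.
#'
#' @param target,baseline named numeric vectors of (log2) signals over a
#'   common feature universe.
#' @param thresholdFraction rank-band half width as a fraction of the
#'   current set size (default 0.02).
#' @param maxIter maximum number of refinement rounds.
#' @param minSize smallest set the iteration may return; default
#'   `max(50, ceiling(0.05 * n))`, capped at `n`.
#' @return character vector of invariant feature names.
#' @export
rankInvariantProbes <- function(target, baseline, thresholdFraction = 0.02,
                                maxIter = 30L, minSize = NULL) {
  if (is.null(names(target)) || is.null(names(baseline)))
    usageError("target and baseline must be named vectors")
  common <- intersect(names(target), names(baseline))
  if (!length(common)) usageError("no common features")
  if (is.null(minSize))
    minSize <- min(length(common), max(50L, ceiling(0.05 * length(common))))
  s <- common
  for (iter in seq_len(maxIter)) {
    rt <- rank(target[s], ties.method = "average")
    rb <- rank(baseline[s], ties.method = "average")
    keep <- abs(rt - rb) <= thresholdFraction * length(s)
    news <- s[keep]
    if (length(news) == 0L && minSize <= 1L)
      usageError(paste("rank-invariant set is empty;",
                       "increase thresholdFraction"))
    if (length(news) < minSize) break      # floor: keep the current set
    if (length(news) == length(s)) { s <- news; break }  # fixed point
    s <- news
  }
  s
}

#' Fit a piecewise-linear running-median normalization curve
#'
#' Pairs of (target, baseline) log2 signals from the rank-invariant set
#' are sorted by target value; the control points are the target values
#' against a centered running median (window `window`) of the baseline
#' values, made monotone non-decreasing by a cumulative maximum.
#' Evaluation interpolates linearly between control points and extends
#' linearly beyond the fitted range using the terminal segment slopes.
#'
#' @param target,baseline numeric vectors (log2) of equal length.
#' @param window odd window size; default `min(101, ceiling(n/10))`
#'   rounded up to odd.
#' @return a data frame of control points with columns `x` and `y`.
#' @export
fitNormalizationCurve <- function(target, baseline, window = NULL) {
  n <- length(target)
  if (n != length(baseline)) usageError("target/baseline length mismatch")
  if (is.null(window)) {
    window <- min(101L, ceiling(n / 10))
    if (window %% 2L == 0L) window <- window + 1L
  }
  if (n < window)
    usageError("need at least %d pairs for window %d", window, window)
  ord <- order(target)
  xs <- target[ord]
  ys <- baseline[ord]
  med <- if (window == 1L) ys else
    as.numeric(stats::runmed(ys, window, endrule = "median"))
  # collapse duplicated x so control-point x is strictly increasing
  if (anyDuplicated(xs)) {
    agg <- vapply(split(med, xs), mean, numeric(1))
    xs <- as.numeric(names(agg))
    med <- unname(agg)
    ord2 <- order(xs)
    xs <- xs[ord2]; med <- med[ord2]
  }
  data.frame(x = xs, y = cummax(med))
}

# evaluate a control-point curve at x: linear interpolation inside the
# range, linear extension with the terminal segment slope outside
evalCurve <- function(curve, x) {
  cx <- curve$x; cy <- curve$y
  n <- length(cx)
  if (n == 1L) return(rep(cy, length(x)))
  y <- stats::approx(cx, cy, xout = x, ties = "ordered")$y
  lo <- x < cx[1L]; hi <- x > cx[n]
  if (any(lo)) {
    s <- (cy[2L] - cy[1L]) / (cx[2L] - cx[1L])
    y[lo] <- cy[1L] + s * (x[lo] - cx[1L])
  }
  if (any(hi)) {
    s <- (cy[n] - cy[n - 1L]) / (cx[n] - cx[n - 1L])
    y[hi] <- cy[n] + s * (x[hi] - cx[n])
  }
  y
}

#' Fit the full normalization model for an experiment
#'
#' Selects the baseline array, finds the rank-invariant feature set of
#' every other array against the baseline (saturated instances on either
#' array are excluded from fitting), and fits one running-median curve
#' per array in log2 space.
#'
#' @param x a floored [IntensityExperiment-class].
#' @param thresholdFraction,maxIter,minSize passed to
#'   [rankInvariantProbes()].
#' @param window passed to [fitNormalizationCurve()].
#' @return a [NormalizationModel-class].
#' @export
fitNormalization <- function(x, thresholdFraction = 0.02, maxIter = 30L,
                             minSize = NULL, window = NULL) {
  stopifnot(is(x, "IntensityExperiment"))
  sig <- log2(SummarizedExperiment::assay(x, "signal"))
  sat <- SummarizedExperiment::assay(x, "saturated")
  base_id <- selectBaselineArray(x)
  others <- setdiff(colnames(sig), base_id)
  curves <- list()
  invariant <- list()
  for (aid in others) {
    ok <- !sat[, aid] & !sat[, base_id]
    tgt <- sig[ok, aid]
    bas <- sig[ok, base_id]
    names(tgt) <- names(bas) <- rownames(sig)[ok]
    inv <- rankInvariantProbes(tgt, bas, thresholdFraction, maxIter, minSize)
    invariant[[aid]] <- inv
    curves[[aid]] <- fitNormalizationCurve(tgt[inv], bas[inv], window)
  }
  new("NormalizationModel", baseline = base_id, curves = curves,
      invariant = invariant,
      params = list(thresholdFraction = thresholdFraction,
                    maxIter = maxIter, window = window))
}

#' @rdname NormalizationModel-class
#' @export
setMethod("baselineArray", "NormalizationModel", function(x) x@baseline)

#' @rdname NormalizationModel-class
#' @export
setMethod("normalizationCurves", "NormalizationModel", function(x) x@curves)

#' @rdname NormalizationModel-class
#' @export
setMethod("invariantProbes", "NormalizationModel", function(x) x@invariant)

setMethod("show", "NormalizationModel", function(object) {
  sizes <- lengths(object@invariant)
  cat(sprintf("NormalizationModel: baseline '%s'; %d arrays normalized\n",
              object@baseline, length(object@curves)))
  if (length(sizes))
    cat(sprintf("  invariant set sizes: %d-%d (median %d)\n",
                min(sizes), max(sizes), as.integer(stats::median(sizes))))
})

#' Normalize arrays to the baseline
#'
#' Maps every non-baseline array through its fitted curve in log2 space;
#' the baseline array is a fixed point of the transformation.  Adds the
#' `normlog2` and `normsignal` (linear) assays.
#'
#' @param x a floored [IntensityExperiment-class].
#' @param model a [NormalizationModel-class] fitted on `x`.
#' @return the experiment with normalized assays.
#' @export
normalizeArrays <- function(x, model) {
  stopifnot(is(x, "IntensityExperiment"), is(model, "NormalizationModel"))
  sig <- log2(SummarizedExperiment::assay(x, "signal"))
  missing_arrays <- setdiff(colnames(sig),
                            c(model@baseline, names(model@curves)))
  if (length(missing_arrays))
    usageError("array(s) missing from normalization model: %s",
               paste(missing_arrays, collapse = ", "))
  norm <- sig
  for (aid in setdiff(colnames(sig), model@baseline))
    norm[, aid] <- evalCurve(model@curves[[aid]], sig[, aid])
  SummarizedExperiment::assay(x, "normlog2") <- norm
  SummarizedExperiment::assay(x, "normsignal") <- 2^norm
  S4Vectors::metadata(x)$baseline <- model@baseline
  x
}

#' Average duplicate spots into a probe-level matrix
#'
#' Arithmetic mean over a probe's spot instances on the (normalized)
#' linear scale, per array.  The per-probe QC flags are aggregated
#' across every instance (all arrays and spots): `any_saturated` records
#' saturation in any instance, `any_above_background` an above-background
#' signal in at least one instance.
#'
#' @param x an [IntensityExperiment-class]; uses the `normsignal` assay
#'   when present, otherwise raw `signal`.
#' @return a [SummarizedExperiment::SummarizedExperiment] with one row
#'   per probe (assay `signal`, linear scale) and the aggregated flags in
#'   `rowData`.
#' @export
averageDuplicates <- function(x) {
  stopifnot(is(x, "IntensityExperiment"))
  anames <- SummarizedExperiment::assayNames(x)
  sig <- SummarizedExperiment::assay(
    x, if ("normsignal" %in% anames) "normsignal" else "signal")
  sat <- SummarizedExperiment::assay(x, "saturated")
  abv <- SummarizedExperiment::assay(x, "above_background")
  pid <- SummarizedExperiment::rowData(x)$probe_id
  f <- factor(pid, levels = unique(pid))
  nspot <- as.vector(table(f))
  mean_sig <- rowsum(sig, f, reorder = FALSE) / nspot
  any_sat <- rowsum(sat + 0, f, reorder = FALSE) > 0
  any_abv <- rowsum(abv + 0, f, reorder = FALSE) > 0
  rd <- S4Vectors::DataFrame(
    probe_id = levels(f),
    any_saturated = rowSums(any_sat) > 0,
    any_above_background = rowSums(any_abv) > 0
  )
  rownames(mean_sig) <- levels(f)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = mean_sig),
    rowData = rd,
    colData = SummarizedExperiment::colData(x),
    metadata = S4Vectors::metadata(x))
}

#' Filter probes on saturation and background flags
#'
#' Probes saturated in any instance among the arrays and duplicate spots
#' are removed first; of the remainder, probes whose signal was above
#' background in no instance are removed.  A probe above background in
#' even a single instance is retained.
#'
#' @param x a probe-level `SummarizedExperiment` from
#'   [averageDuplicates()].
#' @return list with `matrix` (the filtered experiment) and `report`
#'   (a [QCReport-class]).
#' @export
qcFilterProbes <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!all(c("any_saturated", "any_above_background") %in% colnames(rd)))
    usageError("rowData must carry any_saturated and any_above_background")
  sat <- rd$any_saturated
  bg <- !sat & !rd$any_above_background  # saturation counted first
  keep <- !sat & !bg
  report <- new("QCReport",
                nInput = nrow(x), nSaturated = sum(sat),
                nBackground = sum(bg), nRetained = sum(keep))
  list(matrix = x[keep, ], report = report)
}

#' @rdname QCReport-class
#' @export
setMethod("qcCounts", "QCReport", function(x) {
  c(input = x@nInput, removed_saturated = x@nSaturated,
    removed_background = x@nBackground, retained = x@nRetained)
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf(paste0("QCReport: %d probes in; removed %d saturated, ",
                     "%d never above background; %d retained\n"),
              object@nInput, object@nSaturated, object@nBackground,
              object@nRetained))
})
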