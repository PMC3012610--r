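#' Fit a plasmid standard curve
#'
#' Least-squares fit of Ct on log10(copies) over the serial dilutions of
#' a plasmid carrying the amplicon.  Amplification efficiency is derived
#' from the slope as `E = 10^(-1/slope) - 1`; a slope of -3.3219 (i.e.
#' -1/log10(2)) corresponds to perfect doubling, `E = 1`.
#'
#' @param standards data frame with columns `copies` and `Ct` (at least
#'   3 distinct dilution levels), or a numeric `copies` vector with `Ct`
#'   supplied separately.
#' @param Ct optional Ct vector when `standards` is a copies vector.
#' @return object of class `standard_curve`: slope, intercept, r
#'   squared, efficiency, and the calibrated Ct range.
#' @examples
#' std <- data.frame(copies = 10^(1:5), Ct = 40 - 3.3219 * (1:5))
#' fitStandardCurve(std)$efficiency   # 1
#' @export
fitStandardCurve <- function(standards, Ct = NULL) {
  if (is.data.frame(standards)) {
    if (!all(c("copies", "Ct") %in% colnames(standards)))
      usageError("standards must have columns copies and Ct")
    copies <- standards$copies
    ct <- standards$Ct
  } else {
    copies <- standards
    ct <- Ct
  }
  if (any(copies <= 0))
    stop2("cypwaves_domain_error", "standard copy numbers must be positive")
  if (length(unique(copies)) < 3L)
    stop2("cypwaves_calibration_error",
          "need at least 3 distinct dilution levels")
  fit <- stats::lm(ct ~ log10(copies))
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (slope >= 0)
    stop2("cypwaves_calibration_error",
          "fitted slope is non-negative; Ct must decrease with copies")
  structure(list(
    slope = slope,
    intercept = intercept,
    r_squared = suppressWarnings(summary(fit)$r.squared),
    efficiency = 10^(-1 / slope) - 1,
    ct_range = range(ct)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: slope %.4f, intercept %.3f, R2 %.4f, efficiency %.1f%%\n",
              x$slope, x$intercept, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Absolute molecule counts from Ct values
#'
#' Inverts the standard curve: `copies = 10^((Ct - intercept) / slope)`.
#' Ct values outside the calibrated range are converted anyway but
#' flagged as extrapolated (low-expressed transcripts near the detection
#' limit routinely fall below the last standard).
#'
#' @param curve a fitted `standard_curve`.
#' @param Ct numeric Ct values.
#' @return numeric copy numbers with a logical `extrapolated` attribute.
#' @export
moleculeCount <- function(curve, Ct) {
  stopifnot(inherits(curve, "standard_curve"))
  copies <- 10^((Ct - curve$intercept) / curve$slope)
  tol <- 1e-8 * diff(curve$ct_range)  # boundary Cts are calibrated
  attr(copies, "extrapolated") <-
    Ct < curve$ct_range[1L] - tol | Ct > curve$ct_range[2L] + tol
  copies
}

#' Normalize molecule counts to a reference transcript
#'
#' Divides each gene's molecule count by the reference gene's count in
#' the same sample (default ARNT2, which varies far less across
#' development than beta-actin), then summarizes the ratios per gene as
#' mean and standard deviation across the biological replicates.
#'
#' @param counts data frame with columns `gene`, `sample`, `count`.
#' @param referenceGene reference transcript name (default `"ARNT2"`).
#' @return list with `ratios` (per gene x sample) and `summary`
#'   (per-gene mean and SD across samples).
#' @export
normalizeToReference <- function(counts, referenceGene = "ARNT2") {
  need <- c("gene", "sample", "count")
  if (!all(need %in% colnames(counts)))
    usageError("counts must have columns gene, sample, count")
  ref <- counts[counts$gene == referenceGene, ]
  if (!nrow(ref))
    usageError("reference gene '%s' not present", referenceGene)
  refmap <- stats::setNames(ref$count, ref$sample)
  tgt <- counts[counts$gene != referenceGene, ]
  missing_ref <- setdiff(unique(tgt$sample), names(refmap))
  if (length(missing_ref))
    usageError("no reference counts for sample(s): %s",
               paste(missing_ref, collapse = ", "))
  rc <- refmap[tgt$sample]
  if (any(rc == 0))
    stop2("cypwaves_domain_error",
          "reference count is zero for sample(s): %s",
          paste(unique(tgt$sample[rc == 0]), collapse = ", "))
  ratios <- data.frame(gene = tgt$gene, sample = tgt$sample,
                       ratio = tgt$count / rc)
  spl <- split(ratios$ratio, ratios$gene)
  summary <- data.frame(
    gene = names(spl),
    mean = vapply(spl, mean, numeric(1)),
    sd = vapply(spl, stats::sd, numeric(1)),
    row.names = NULL)
  list(ratios = ratios, summary = summary)
}

#' Concordance between microarray and qPCR measurements
#'
#' Per gene, correlates the reference-normalized microarray values with
#' the reference-normalized qPCR molecule counts across timepoints and
#' reports the linear fit; genes with correlation at or above
#' `threshold` are flagged concordant.  Genes with a constant series on
#' either platform get an undefined correlation and are flagged
#' non-concordant.
#'
#' @param arrayValues,qpcrValues numeric matrices, genes x timepoints,
#'   with matching dimnames.
#' @param threshold Pearson correlation needed to call a gene
#'   concordant (default 0.9).
#' @return data frame with `gene`, `r`, `slope`, `intercept`,
#'   `concordant`.
#' @export
platformConcordance <- function(arrayValues, qpcrValues, threshold = 0.9) {
  arrayValues <- as.matrix(arrayValues)
  qpcrValues <- as.matrix(qpcrValues)
  if (!identical(dim(arrayValues), dim(qpcrValues)))
    usageError("matrices must have identical dimensions")
  if (ncol(arrayValues) < 3L)
    usageError("need at least 3 paired timepoints")
  genes <- rownames(arrayValues)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(arrayValues)))
  res <- lapply(seq_len(nrow(arrayValues)), function(i) {
    a <- arrayValues[i, ]
    q <- qpcrValues[i, ]
    if (stats::sd(a) == 0 || stats::sd(q) == 0)
      return(data.frame(gene = genes[i], r = NA_real_, slope = NA_real_,
                        intercept = NA_real_, concordant = FALSE))
    fit <- stats::lm(q ~ a)
    data.frame(gene = genes[i], r = stats::cor(a, q),
               slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               concordant = stats::cor(a, q) >= threshold)
  })
  do.call(rbind, res)
}
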