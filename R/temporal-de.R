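#' Log-transform and median-center a probe matrix
#'
#' Takes the probe x array expression values to log2 and subtracts each
#' probe's median, producing the scale on which the temporal
#' differential-expression model operates.
#'
#' @param x a probe-level `SummarizedExperiment` (from
#'   [averageDuplicates()]/[qcFilterProbes()]) or a positive numeric
#'   matrix; column metadata `timepoint_hpf` and `replicate` are carried
#'   through.
#' @return a `SummarizedExperiment` with assay `centered`.
#' @export
logMedianCenter <- function(x) {
  se <- if (is(x, "SummarizedExperiment")) x else
    SummarizedExperiment::SummarizedExperiment(assays = list(signal = as.matrix(x)))
  m <- SummarizedExperiment::assay(se, "signal")
  if (any(m <= 0))
    usageError("all signals must be positive before log transform")
  lg <- log2(m)
  centered <- lg - apply(lg, 1L, stats::median)
  SummarizedExperiment::assay(se, "centered") <- centered
  se
}

# balanced-design bookkeeping shared by the DE functions
timecourseLayout <- function(se) {
  cd <- SummarizedExperiment::colData(se)
  if (!all(c("timepoint_hpf", "replicate") %in% colnames(cd)))
    usageError("colData must contain timepoint_hpf and replicate")
  tp <- cd$timepoint_hpf
  tab <- table(tp)
  if (length(tab) < 2L) usageError("need at least 2 timepoints")
  if (length(unique(as.vector(tab))) != 1L)
    usageError("complete balanced design required")
  if (min(tab) < 2L) usageError("need at least 2 replicates per timepoint")
  list(tp = tp, levels = sort(unique(tp)), n_rep = as.integer(tab[1L]))
}

#' Posterior probability of temporal differential expression
#'
#' Empirical-Bayes score for replicated time series in the spirit of
#' Bayesian estimation of temporal regulation: per probe, the vector of
#' timepoint mean differences relative to the reference (first)
#' timepoint is modeled as a two-component multivariate-normal mixture.
#' Under the null the differences carry only replicate noise, with a
#' per-probe covariance moderated by shrinking the probe's residual
#' variance toward the pooled value (weight `lambda`); under the
#' alternative an additional signal covariance, shared across probes and
#' free to encode temporal autocorrelation, is added.  The mixture
#' weight and signal covariance are estimated by expectation-
#' maximization; the returned value is each probe's posterior
#' probability of the alternative.  Probes with zero residual variance
#' get `NA` (the probability is undefined without a noise estimate).
#'
#' @param se a `SummarizedExperiment` with assay `centered` from
#'   [logMedianCenter()] and `timepoint_hpf`/`replicate` column data.
#' @param lambda shrinkage weight toward the pooled residual variance.
#' @param tol EM convergence tolerance.
#' @param maxIter maximum EM iterations.
#' @return named numeric vector of posterior probabilities in \[0, 1\].
#' @export
betrProbability <- function(se, lambda = 0.1, tol = 1e-6, maxIter = 200L) {
  lay <- timecourseLayout(se)
  x <- SummarizedExperiment::assay(se, "centered")
  tpf <- factor(lay$tp, levels = lay$levels)
  nt <- length(lay$levels)
  n <- lay$n_rep

  # timepoint means and pooled residual variance per probe
  M <- t(rowsum(t(x), tpf) / n)                      # probes x timepoints
  resid <- x - M[, as.integer(tpf), drop = FALSE]
  s2 <- rowSums(resid^2) / (ncol(x) - nt)
  degenerate <- s2 <= 0 | !is.finite(s2)

  d <- M[, -1L, drop = FALSE] - M[, 1L]              # diffs vs reference
  post <- rep(NA_real_, nrow(x))
  names(post) <- rownames(x)
  use <- which(!degenerate)
  if (!length(use)) return(post)

  s2s <- (1 - lambda) * s2[use] + lambda * mean(s2[use])
  sigma2 <- s2s / n                                  # variance of a mean

  # Cov0 = sigma2_i * (I + J): whiten with A = (I+J)^{-1/2} so the null
  # covariance is spherical and the mixture can be eigen-decomposed once
  # per EM step
  k <- nt - 1L
  Mstr <- diag(k) + matrix(1, k, k)
  eM <- eigen(Mstr, symmetric = TRUE)
  A <- eM$vectors %*% diag(1 / sqrt(eM$values), k) %*% t(eM$vectors)
  V <- d[use, , drop = FALSE] %*% A                  # whitened diffs

  projectPSD <- function(S) {
    eS <- eigen((S + t(S)) / 2, symmetric = TRUE)
    vals <- pmax(eS$values, 0)
    eS$vectors %*% diag(vals, length(vals)) %*% t(eS$vectors)
  }

  ng <- length(use)
  B <- projectPSD(crossprod(V) / ng - mean(sigma2) * diag(k))
  if (sum(diag(B)) < 1e-12) B <- diag(1e-8, k)
  p <- 0.3

  loglikNull <- function() {
    -0.5 * (k * log(2 * pi * sigma2) + rowSums(V^2) / sigma2)
  }
  ll0 <- loglikNull()
  r <- NULL
  for (iter in seq_len(maxIter)) {
    eB <- eigen(B, symmetric = TRUE)
    lamB <- pmax(eB$values, 0)
    W <- V %*% eB$vectors
    denom <- outer(sigma2, lamB, `+`)                # ng x k
    ll1 <- -0.5 * (rowSums(log(2 * pi * denom)) + rowSums(W^2 / denom))
    a <- log(p) + ll1
    b <- log(1 - p) + ll0
    mx <- pmax(a, b)
    r <- exp(a - mx) / (exp(a - mx) + exp(b - mx))

    p_new <- min(max(mean(r), 1e-8), 1 - 1e-8)
    wsum <- sum(r)
    if (wsum > 1e-12) {
      S1 <- crossprod(V * sqrt(r / wsum))
      B_new <- projectPSD(S1 - (sum(r * sigma2) / wsum) * diag(k))
    } else {
      B_new <- diag(1e-8, k)
    }
    delta <- abs(p_new - p) + max(abs(B_new - B))
    p <- p_new
    B <- B_new
    if (delta < tol) break
  }
  post[use] <- r
  post
}

#' Per-probe one-way ANOVA across timepoints
#'
#' The naive comparator to the temporal posterior: a fixed-effects
#' one-way ANOVA of each probe's values across the sampling times,
#' ignoring temporal autocorrelation.
#'
#' @param se a `SummarizedExperiment` with assay `centered` (or
#'   `signal`) and `timepoint_hpf` column data.
#' @return named numeric vector of p-values; probes with no variance at
#'   all get `NA`.
#' @export
anovaPvalue <- function(se) {
  lay <- timecourseLayout(se)
  anames <- SummarizedExperiment::assayNames(se)
  x <- SummarizedExperiment::assay(
    se, if ("centered" %in% anames) "centered" else "signal")
  g <- factor(lay$tp)
  p <- vapply(seq_len(nrow(x)), function(i) {
    v <- x[i, ]
    out <- tryCatch(
      stats::oneway.test(v ~ g, var.equal = TRUE)$p.value,
      error = function(e) NA_real_)
    if (!is.finite(out)) NA_real_ else out
  }, numeric(1))
  names(p) <- rownames(x)
  p
}

#' Call significantly regulated probes
#'
#' A probe is significant when `1 - posterior < alpha` (the posterior
#' scale analogue of a p-value threshold).
#'
#' @param posterior numeric vector of posterior probabilities.
#' @param alpha significance criterion in (0, 1); default 0.01.
#' @return list with the logical `significant` vector, `n_significant`
#'   and `fraction` (of non-missing probes).
#' @export
callSignificant <- function(posterior, alpha = 0.01) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    usageError("alpha must be in (0, 1)")
  sig <- (1 - posterior) < alpha
  n_ok <- sum(!is.na(posterior))
  list(significant = sig,
       n_significant = sum(sig, na.rm = TRUE),
       fraction = if (n_ok) sum(sig, na.rm = TRUE) / n_ok else NA_real_)
}

#' Temporal differential expression, posterior and ANOVA together
#'
#' Convenience wrapper running [betrProbability()] and [anovaPvalue()]
#' on the same centered matrix and applying the significance criterion.
#'
#' @param se output of [logMedianCenter()].
#' @param alpha significance criterion.
#' @param adjust p-value adjustment for the ANOVA column (see
#'   [stats::p.adjust()]); default `"none"`, matching a raw threshold.
#' @param ... passed to [betrProbability()].
#' @return a [S4Vectors::DataFrame] with `probe_id`, `posterior`,
#'   `anova_p` and `significant`.
#' @export
temporalDE <- function(se, alpha = 0.01, adjust = "none", ...) {
  post <- betrProbability(se, ...)
  ap <- stats::p.adjust(anovaPvalue(se), method = adjust)
  calls <- callSignificant(post, alpha)
  S4Vectors::DataFrame(
    probe_id = rownames(se),
    posterior = unname(post),
    anova_p = unname(ap),
    significant = unname(calls$significant))
}
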