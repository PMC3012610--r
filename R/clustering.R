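#' Per-timepoint mean expression profiles
#'
#' Averages the log2 (normalized) expression over the biological
#' replicates of each timepoint, producing the probe x timepoint profile
#' matrix that the clustering operations consume.
#'
#' @param se a probe-level `SummarizedExperiment` with assay `signal`
#'   (linear) or `centered`/`normlog2`, and `timepoint_hpf` column data.
#' @param log2Transform take log2 of the `signal` assay first (ignored
#'   when a log-scale assay is used).
#' @return numeric matrix, probes x timepoints (columns named by hpf).
#' @export
timepointMeans <- function(se, log2Transform = TRUE) {
  cd <- SummarizedExperiment::colData(se)
  if (!"timepoint_hpf" %in% colnames(cd))
    usageError("colData must contain timepoint_hpf")
  anames <- SummarizedExperiment::assayNames(se)
  if ("centered" %in% anames) {
    m <- SummarizedExperiment::assay(se, "centered")
  } else {
    m <- SummarizedExperiment::assay(se, "signal")
    if (log2Transform) m <- log2(m)
  }
  tpf <- factor(cd$timepoint_hpf, levels = sort(unique(cd$timepoint_hpf)))
  out <- t(rowsum(t(m), tpf) / as.vector(table(tpf)))
  colnames(out) <- levels(tpf)
  out
}

#' Within-gene z-normalization
#'
#' Per row, subtracts the mean and divides by the population standard
#' deviation, so every non-constant profile has mean 0 and SD 1 and the
#' temporal shape, not the absolute level, drives clustering.  Constant
#' rows become all zeros and are flagged degenerate.
#'
#' @param m numeric matrix, genes/probes x timepoints (>= 2 columns).
#' @return the z-normalized matrix, with a logical `degenerate`
#'   attribute marking constant rows.
#' @export
zNormalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) usageError("need at least 2 timepoints")
  mu <- rowMeans(m)
  sdv <- sqrt(rowMeans((m - mu)^2))
  degenerate <- sdv == 0
  z <- (m - mu) / ifelse(degenerate, 1, sdv)
  z[degenerate, ] <- 0
  attr(z, "degenerate") <- degenerate
  attr(z, "z_normalized") <- TRUE
  z
}

# correlation-based distance with constant rows treated as uncorrelated
corDistance <- function(m) {
  cc <- suppressWarnings(stats::cor(t(m)))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  stats::as.dist(1 - cc)
}

#' Hierarchically initialized K-means clustering
#'
#' The MeV-style "hierarchical K-means": centroids are initialized from
#' average-linkage hierarchical clustering (correlation distance) cut at
#' `K`, then refined by standard K-means to convergence.  The
#' initialization makes the result deterministic for a given input.
#'
#' @param m profile matrix (rows clustered), typically z-normalized.
#' @param K number of clusters (default 10).
#' @param iterMax maximum K-means iterations.
#' @return list with `assignment` (named integer vector), `centers`,
#'   `method` and `K`.
#' @export
kmeansClusters <- function(m, K = 10L, iterMax = 300L) {
  m <- as.matrix(m)
  if (K > nrow(m)) usageError("K (%d) exceeds the number of rows (%d)", K,
                              nrow(m))
  if (K == 1L) {
    assignment <- stats::setNames(rep(1L, nrow(m)), rownames(m))
    return(list(assignment = assignment,
                centers = matrix(colMeans(m), 1L,
                                 dimnames = list(NULL, colnames(m))),
                method = "kmeans", K = 1L))
  }
  hc <- stats::hclust(corDistance(m), method = "average")
  init <- stats::cutree(hc, k = K)
  centers <- rowsum(m, init) / as.vector(table(init))
  km <- tryCatch(
    stats::kmeans(m, centers = centers, iter.max = iterMax),
    error = function(e) NULL)
  if (is.null(km)) {  # e.g. duplicated initial centers on tied data
    assignment <- stats::setNames(as.integer(init), rownames(m))
    return(list(assignment = assignment, centers = centers,
                method = "kmeans", K = K))
  }
  list(assignment = stats::setNames(km$cluster, rownames(m)),
       centers = km$centers, method = "kmeans", K = K)
}

# pairwise affinity on the 0-1 scale: (Pearson r + 1) / 2
affinityMatrix <- function(m) {
  cc <- suppressWarnings(stats::cor(t(m)))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  (cc + 1) / 2
}

#' Cluster Affinity Search Technique (CAST)
#'
#' Greedy graph-based clustering on the pairwise affinity
#' `(Pearson r + 1) / 2` (0-1 scale).  A cluster opens with the
#' highest-connectivity unassigned gene, then alternates between adding
#' the unassigned gene with the highest mean affinity to the cluster
#' when that affinity meets `affinity`, and removing the member with the
#' lowest mean affinity when it falls below, until stable; the cluster
#' closes and the search repeats on the remaining genes.  Ties break by
#' input order.
#'
#' @param m profile matrix with >= 2 columns.
#' @param affinity affinity threshold on the 0-1 scale (default 0.7).
#' @param rawCorrelation use raw Pearson r instead of the 0-1 mapping
#'   (threshold then lives on \[-1, 1\]).
#' @return list with `assignment` (named integer vector, clusters
#'   numbered in creation order), `affinity`, and `method`.
#' @export
castClusters <- function(m, affinity = 0.7, rawCorrelation = FALSE) {
  m <- as.matrix(m)
  if (nrow(m) < 1L) usageError("need at least one row")
  if (ncol(m) < 2L) usageError("correlation undefined for < 2 timepoints")
  S <- affinityMatrix(m)
  if (rawCorrelation) S <- 2 * S - 1
  n <- nrow(m)
  assignment <- rep(NA_integer_, n)
  unassigned <- rep(TRUE, n)
  cl <- 0L
  guard <- 0L
  while (any(unassigned)) {
    cl <- cl + 1L
    cand <- which(unassigned)
    # seed: highest total affinity to the other unassigned genes
    conn <- rowSums(S[cand, cand, drop = FALSE]) - 1
    seed <- cand[which.max(conn)]
    members <- seed
    unassigned[seed] <- FALSE
    repeat {
      guard <- guard + 1L
      if (guard > 100L * n + 100L) break  # safety against add/remove cycles
      changed <- FALSE
      # add phase
      repeat {
        out <- which(unassigned)
        if (!length(out)) break
        aff <- rowMeans(S[out, members, drop = FALSE])
        best <- which.max(aff)
        if (aff[best] >= affinity) {
          g <- out[best]
          members <- c(members, g)
          unassigned[g] <- FALSE
          changed <- TRUE
        } else break
      }
      # remove phase (a member's affinity excludes itself)
      repeat {
        if (length(members) <= 1L) break
        aff <- (rowSums(S[members, members, drop = FALSE]) - 1) /
          (length(members) - 1)
        worst <- which.min(aff)
        if (aff[worst] < affinity) {
          g <- members[worst]
          members <- members[-worst]
          unassigned[g] <- TRUE
          changed <- TRUE
        } else break
      }
      if (!changed) break
    }
    assignment[members] <- cl
  }
  names(assignment) <- rownames(m)
  list(assignment = assignment, affinity = affinity, method = "cast")
}

#' Affinity search against a seed profile
#'
#' Returns the genes whose affinity `(r + 1) / 2` to a seed profile
#' meets the threshold.  The default seed is the maternal template: a
#' z-normalized, strictly decreasing ramp peaking at the first
#' timepoint, so genes with decaying maternal transcript match it.
#'
#' @param m profile matrix, genes x timepoints.
#' @param seedProfile numeric vector of length `ncol(m)`; default the
#'   maternal decreasing ramp.
#' @param affinity threshold on the 0-1 scale (default 0.7).
#' @return character vector of matching gene names (possibly empty).
#' @export
affinitySearch <- function(m, seedProfile = NULL, affinity = 0.7) {
  m <- as.matrix(m)
  if (is.null(seedProfile))
    seedProfile <- as.vector(zNormalize(
      matrix(rev(seq_len(ncol(m))), nrow = 1L)))
  if (length(seedProfile) != ncol(m))
    usageError("seedProfile length must equal the number of timepoints")
  aff <- (apply(m, 1L, safeCor, y = seedProfile) + 1) / 2
  rownames(m)[aff >= affinity]
}

#' Classify the temporal modality of a z-normalized profile
#'
#' Local maxima above +0.5 z decide the call: qualifying maxima at both
#' the first and last timepoints give `bimodal`; a single qualifying
#' maximum at the first timepoint gives `peak_at_start`, elsewhere
#' `unimodal` with its peak time; profiles with no qualifying maximum
#' (including degenerate constant profiles) are `flat`.
#'
#' @param z z-normalized matrix (genes x timepoints) or a single profile
#'   vector.
#' @param threshold z-score a local maximum must exceed (default 0.5).
#' @return data frame with `class` and `peak_timepoint` (column name of
#'   the highest qualifying maximum, `NA` for flat).
#' @export
classifyModality <- function(z, threshold = 0.5) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  z <- as.matrix(z)
  nt <- ncol(z)
  tp_names <- colnames(z)
  if (is.null(tp_names)) tp_names <- as.character(seq_len(nt))
  one <- function(v) {
    is_max <- vapply(seq_len(nt), function(i) {
      left <- if (i == 1L) TRUE else v[i] > v[i - 1L]
      right <- if (i == nt) TRUE else v[i] > v[i + 1L]
      left && right
    }, logical(1))
    qual <- which(is_max & v > threshold)
    if (!length(qual)) return(c("flat", NA_character_))
    if (1L %in% qual && nt %in% qual)
      return(c("bimodal", tp_names[qual[which.max(v[qual])]]))
    peak <- qual[which.max(v[qual])]
    if (peak == 1L) return(c("peak_at_start", tp_names[1L]))
    c("unimodal", tp_names[peak])
  }
  res <- t(apply(z, 1L, one))
  data.frame(class = res[, 1L], peak_timepoint = res[, 2L],
             row.names = rownames(z), stringsAsFactors = FALSE)
}
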