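# shared fixtures and small oracles, all built in code

suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(S4Vectors)
})

# write a registry data.frame to a temp TSV and return the path
writeRegistryTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a minimal valid registry data.frame builder
miniRegistry <- function(gene_name, family, subfamily, chromosome,
                         tx_start, tx_end, strand = 1L, exon_count = 9L,
                         flags = "on_array") {
  data.frame(gene_name = gene_name, family = family, subfamily = subfamily,
             chromosome = chromosome, tx_start = tx_start, tx_end = tx_end,
             strand = strand, exon_count = exon_count, flags = flags,
             stringsAsFactors = FALSE)
}

# hand-build a tiny IntensityExperiment from a probe x array signal matrix
makeIntensity <- function(signal, spots = 1L,
                          timepoints = c(3, 6, 12, 24, 36, 48),
                          replicates = c("A", "B"),
                          saturated = NULL, above = NULL) {
  signal <- as.matrix(signal)
  na <- length(timepoints) * length(replicates)
  stopifnot(ncol(signal) == na)
  np <- nrow(signal) / spots
  aid <- as.vector(outer(sprintf("hpf%02d", timepoints), replicates,
                         paste, sep = "_"))
  colnames(signal) <- aid
  if (is.null(saturated)) saturated <- matrix(FALSE, nrow(signal), na)
  if (is.null(above)) above <- matrix(TRUE, nrow(signal), na)
  dimnames(saturated) <- dimnames(above) <- dimnames(signal)
  rd <- DataFrame(probe_id = rep(sprintf("P%03d", seq_len(np)), each = spots),
                  spot_index = rep(seq_len(spots), times = np))
  cd <- DataFrame(array_id = aid,
                  timepoint_hpf = rep(timepoints, times = length(replicates)),
                  replicate = rep(replicates, each = length(timepoints)))
  rownames(cd) <- aid
  rownames(signal) <- paste(rd$probe_id, rd$spot_index, sep = "_")
  new("IntensityExperiment",
      SummarizedExperiment(assays = list(signal = signal,
                                         saturated = saturated,
                                         above_background = above),
                           rowData = rd, colData = cd))
}

# simulate, average duplicates and center in one step (identity warp by
# default so the DE operating characteristics are probed in isolation)
quickTimecourse <- function(nProbes, mix, seed, sigmaRep = 0.25,
                            sigmaSpot = 0.10, identityWarp = TRUE, ...) {
  args <- list(design = arrayDesign(nProbes = nProbes, spotsPerProbe = 1L),
               mix = mix, sigmaRep = sigmaRep, sigmaSpot = sigmaSpot,
               seed = seed, ...)
  if (identityWarp) {
    args$warpSlopeRange <- c(1, 1)
    args$warpInterceptRange <- c(0, 0)
  }
  sim <- do.call(simulateTimecourse, args)
  list(tc = logMedianCenter(averageDuplicates(sim$intensities)),
       truth = sim$truth)
}

jaccard <- function(a, b) {
  a[is.na(a)] <- FALSE
  b[is.na(b)] <- FALSE
  if (!sum(a | b)) return(NA_real_)
  sum(a & b) / sum(a | b)
}

# independently coded rank-invariant iteration (the brute-force oracle)
rankInvariantOracle <- function(target, baseline, f, maxIter = 30L) {
  s <- intersect(names(target), names(baseline))
  for (i in seq_len(maxIter)) {
    rt <- rank(target[s], ties.method = "average")
    rb <- rank(baseline[s], ties.method = "average")
    ok <- abs(rt - rb) <= f * length(s)
    if (all(ok)) break
    s <- s[ok]
    if (!length(s)) stop("oracle: empty set")
  }
  s
}

# four well-separated wave archetypes used for clustering recovery
waveRecoverySim <- function(nProbes, sigmaRep, seed) {
  sim <- simulateTimecourse(
    arrayDesign(nProbes = nProbes, spotsPerProbe = 1L),
    mix = archetypeMix(0, 1, 0, 0, 0),
    sigmaRep = sigmaRep, sigmaSpot = 0,
    warpSlopeRange = c(1, 1), warpInterceptRange = c(0, 0),
    waveCenters = c(6, 18, 30, 42), seed = seed)
  z <- zNormalize(timepointMeans(averageDuplicates(sim$intensities)))
  list(z = z, labels = sim$truth$probes$cluster_id)
}

# mean within-cluster affinity of each member, self excluded
castMemberAffinities <- function(z, assignment) {
  cc <- suppressWarnings(cor(t(z)))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  S <- (cc + 1) / 2
  unlist(lapply(split(seq_along(assignment), assignment), function(idx) {
    if (length(idx) == 1L) return(1)
    (rowSums(S[idx, idx, drop = FALSE]) - 1) / (length(idx) - 1)
  }))
}
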