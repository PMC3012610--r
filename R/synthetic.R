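#' Construct a microarray time-course design
#'
#' Defaults mirror the embryo study layout: sampling at 3, 6, 12, 24, 36
#' and 48 hours post-fertilization, four independently maintained dishes
#' as biological replicates, and every probe printed in duplicate.
#'
#' @param timepoints ordered sampling times in hpf.
#' @param replicates biological replicate labels.
#' @param spotsPerProbe duplicate spots per probe.
#' @param nProbes number of probes.
#' @return an [ArrayDesign-class].
#' @export
arrayDesign <- function(timepoints = c(3, 6, 12, 24, 36, 48),
                        replicates = c("A", "B", "C", "D"),
                        spotsPerProbe = 2L, nProbes = 2000L) {
  new("ArrayDesign", timepoints = as.numeric(timepoints),
      replicates = as.character(replicates),
      spotsPerProbe = as.integer(spotsPerProbe),
      nProbes = as.integer(nProbes))
}

setMethod("show", "ArrayDesign", function(object) {
  cat(sprintf("ArrayDesign: %d probes x %d spots; %d timepoints (%s hpf) x %d replicates\n",
              object@nProbes, object@spotsPerProbe,
              length(object@timepoints),
              paste(object@timepoints, collapse = ","),
              length(object@replicates)))
})

ARCHETYPES <- c("maternal_decay", "unimodal_wave", "bimodal", "flat",
                "below_background")

#' Archetype mixture for the simulator
#'
#' Proportions of the five temporal archetypes planted by
#' [simulateTimecourse()].  Defaults reflect an embryo transcriptome in
#' which most expressed probes change over development: a maternal-decay
#' fraction, a dominant set of unimodal waves, a small bimodal set, a
#' temporally flat set, and a small never-above-background set.
#'
#' @param maternal_decay,unimodal_wave,bimodal,flat,below_background
#'   proportions; must sum to 1 (tolerance 1e-9).
#' @return a named numeric vector.
#' @export
archetypeMix <- function(maternal_decay = 0.15, unimodal_wave = 0.40,
                         bimodal = 0.10, flat = 0.30,
                         below_background = 0.05) {
  mix <- c(maternal_decay = maternal_decay, unimodal_wave = unimodal_wave,
           bimodal = bimodal, flat = flat,
           below_background = below_background)
  if (any(mix < 0)) configError("archetype proportions must be non-negative")
  if (abs(sum(mix) - 1) > 1e-9)
    configError("archetype proportions must sum to 1 (got %.12f)", sum(mix))
  mix
}

# largest-remainder allocation of n items to proportions p
allocateCounts <- function(n, p) {
  raw <- n * p
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  as.integer(cnt)
}

arrayIds <- function(design) {
  as.vector(outer(sprintf("hpf%02d", design@timepoints), design@replicates,
                  paste, sep = "_"))
}

buildIntensityExperiment <- function(design, signal, saturated, above) {
  nspot <- design@spotsPerProbe
  probes <- sprintf("P%05d", seq_len(design@nProbes))
  rd <- S4Vectors::DataFrame(
    probe_id = rep(probes, each = nspot),
    spot_index = rep(seq_len(nspot), times = design@nProbes)
  )
  aid <- arrayIds(design)
  cd <- S4Vectors::DataFrame(
    array_id = aid,
    timepoint_hpf = rep(design@timepoints, times = length(design@replicates)),
    replicate = rep(design@replicates, each = length(design@timepoints))
  )
  rownames(cd) <- aid
  dimnames(signal) <- list(paste(rd$probe_id, rd$spot_index, sep = "_"), aid)
  dimnames(saturated) <- dimnames(signal)
  dimnames(above) <- dimnames(signal)
  new("IntensityExperiment", SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = signal, saturated = saturated,
                  above_background = above),
    rowData = rd, colData = cd))
}

#' Simulate a single-color microarray time course with known truth
#'
#' Generates spot-level intensities for the full timepoint x replicate
#' design.  Each probe draws a log2 baseline from Normal(8, 2) and an
#' archetype effect added in log2 space: maternal decay is a linear
#' decline from the first timepoint (default slope -0.15 log2/h);
#' unimodal waves are Gaussian bumps (amplitude uniform on
#' `waveAmplitude`, width `waveWidth` hours, center uniform over the
#' timepoint range unless `waveCenters` pins discrete wave components);
#' bimodal probes carry bumps at both the first and last timepoints.
#' Replicate noise (per probe x array) and spot noise (per spot) are
#' normal in log2, i.e. multiplicative on the linear scale.  Each array
#' is then distorted by a monotone affine warp `y = a + b*x` in log2
#' with `b` uniform on `warpSlopeRange`, the linear signal is clipped at
#' `satCeiling` (16-bit scanner) with a saturation flag, and
#' below-background probes are drawn on the linear scale from
#' Normal(4, 1) truncated at 0 with `above_background = FALSE`.
#'
#' @param design an [ArrayDesign-class].
#' @param mix archetype proportions from [archetypeMix()].
#' @param sigmaRep,sigmaSpot replicate and spot noise SD (log2 units).
#' @param warpSlopeRange range for the warp slope `b`; use `c(1, 1)`
#'   together with `warpInterceptRange = c(0, 0)` for identity warps.
#' @param warpInterceptRange range for the centered warp intercept.
#' @param decaySlope maternal decay slope (log2 per hour, negative).
#' @param waveAmplitude range (or single value) of wave amplitudes, log2.
#' @param waveWidth Gaussian wave width, hours.
#' @param waveCenters optional discrete wave centers (hpf); when given,
#'   each unimodal probe is assigned one and the truth records it as a
#'   planted cluster label.
#' @param satCeiling scanner saturation ceiling, linear units.
#' @param seed integer seed (required; the generator is fully seeded).
#' @return a list with `intensities` (an [IntensityExperiment-class])
#'   and `truth` (a list with per-probe archetype labels and parameters,
#'   per-array warp parameters, and the planted DE flags).
#' @examples
#' sim <- simulateTimecourse(arrayDesign(nProbes = 50), seed = 1)
#' table(sim$truth$probes$archetype)
#' @export
simulateTimecourse <- function(design = arrayDesign(),
                               mix = archetypeMix(),
                               sigmaRep = 0.25, sigmaSpot = 0.10,
                               warpSlopeRange = c(0.8, 1.25),
                               warpInterceptRange = c(-0.3, 0.3),
                               decaySlope = -0.15,
                               waveAmplitude = c(1, 3.5),
                               waveWidth = 6,
                               waveCenters = NULL,
                               satCeiling = 65535,
                               seed) {
  if (missing(seed) || is.null(seed))
    configError("simulateTimecourse: 'seed' is required")
  mix <- mix[ARCHETYPES]
  if (anyNA(mix)) configError("mix must name all five archetypes")
  if (abs(sum(mix) - 1) > 1e-9)
    configError("archetype proportions must sum to 1")
  tp <- design@timepoints
  if (!is.null(waveCenters) &&
      (any(waveCenters < min(tp)) || any(waveCenters > max(tp))))
    configError("waveCenters must lie within the timepoint range")

  withSeed(seed, {
    np <- design@nProbes
    nt <- length(tp)
    nr <- length(design@replicates)
    ns <- design@spotsPerProbe
    na <- nt * nr

    counts <- allocateCounts(np, mix)
    archetype <- sample(rep(ARCHETYPES, times = counts))

    baseline <- stats::rnorm(np, mean = 8, sd = 2)
    amp <- ifelse(archetype == "unimodal_wave",
                  stats::runif(np, min(waveAmplitude), max(waveAmplitude)),
                  NA_real_)
    center <- rep(NA_real_, np)
    is_wave <- archetype == "unimodal_wave"
    if (is.null(waveCenters)) {
      center[is_wave] <- stats::runif(sum(is_wave), min(tp), max(tp))
    } else {
      center[is_wave] <- waveCenters[
        sample.int(length(waveCenters), sum(is_wave), replace = TRUE)]
    }
    amp1 <- ifelse(archetype == "bimodal",
                   stats::runif(np, min(waveAmplitude), max(waveAmplitude)),
                   NA_real_)
    amp2 <- ifelse(archetype == "bimodal",
                   stats::runif(np, min(waveAmplitude), max(waveAmplitude)),
                   NA_real_)

    # probe x timepoint archetype effect, log2 units
    effect <- matrix(0, np, nt)
    effect[archetype == "maternal_decay", ] <-
      outer(rep(decaySlope, sum(archetype == "maternal_decay")), tp - tp[1L])
    if (any(is_wave)) {
      effect[is_wave, ] <- amp[is_wave] *
        exp(-outer(center[is_wave], tp, function(cc, t)
          (t - cc)^2) / (2 * waveWidth^2))
    }
    is_bi <- archetype == "bimodal"
    if (any(is_bi)) {
      effect[is_bi, ] <-
        amp1[is_bi] * exp(-outer(rep(tp[1L], sum(is_bi)), tp,
                                 function(cc, t) (t - cc)^2) / (2 * waveWidth^2)) +
        amp2[is_bi] * exp(-outer(rep(tp[nt], sum(is_bi)), tp,
                                 function(cc, t) (t - cc)^2) / (2 * waveWidth^2))
    }

    tp_of_array <- rep(seq_len(nt), times = nr)
    rep_noise <- matrix(stats::rnorm(np * na, 0, sigmaRep), np, na)
    # per-probe log2 mean on each array
    mu <- baseline + effect[, tp_of_array, drop = FALSE] + rep_noise

    warp_b <- stats::runif(na, min(warpSlopeRange), max(warpSlopeRange))
    warp_a <- stats::runif(na, min(warpInterceptRange),
                           max(warpInterceptRange)) + 8 * (1 - warp_b)

    nrows <- np * ns
    spot_noise <- matrix(stats::rnorm(nrows * na, 0, sigmaSpot), nrows, na)
    y <- mu[rep(seq_len(np), each = ns), , drop = FALSE] + spot_noise
    y <- sweep(sweep(y, 2L, warp_b, `*`), 2L, warp_a, `+`)
    linear <- 2^y
    saturated <- linear >= satCeiling
    linear[saturated] <- satCeiling
    above <- matrix(TRUE, nrows, na)

    bg_probe <- archetype == "below_background"
    if (any(bg_probe)) {
      bg_rows <- rep(bg_probe, each = ns)
      nbg <- sum(bg_rows)
      draw <- matrix(stats::rnorm(nbg * na, 4, 1), nbg, na)
      draw[draw < 0] <- 0
      linear[bg_rows, ] <- draw
      saturated[bg_rows, ] <- FALSE
      above[bg_rows, ] <- FALSE
    }

    ie <- buildIntensityExperiment(design, linear, saturated, above)
    cluster_id <- archetype
    cluster_id[is_wave] <- if (is.null(waveCenters)) "unimodal_wave" else
      sprintf("unimodal_c%g", center[is_wave])
    truth <- list(
      probes = S4Vectors::DataFrame(
        probe_id = sprintf("P%05d", seq_len(np)),
        archetype = archetype,
        de = archetype %in% c("maternal_decay", "unimodal_wave", "bimodal"),
        cluster_id = cluster_id,
        baseline_log2 = baseline,
        amplitude = amp, amplitude2 = amp2, center = center,
        width = ifelse(is_wave | is_bi, waveWidth, NA_real_),
        slope = ifelse(archetype == "maternal_decay", decaySlope, NA_real_)
      ),
      arrays = S4Vectors::DataFrame(
        array_id = arrayIds(design), warp_a = warp_a, warp_b = warp_b
      ),
      params = list(mix = mix, sigmaRep = sigmaRep, sigmaSpot = sigmaSpot,
                    satCeiling = satCeiling, seed = seed)
    )
    list(intensities = ie, truth = truth)
  })
}

#' Simulate the probe-QC worked-example profile
#'
#' Builds a full-size flag fixture for the probe quality filter: a flat
#' array profile at the production scale (default 21893 probes, printed
#' in duplicate over 24 arrays) in which exactly `nSaturated` probes are
#' saturated in at least one instance and exactly `nBackground` further
#' probes are never above background.  With the defaults the filter
#' retains 21801 probes.
#'
#' @param seed integer seed.
#' @param design an [ArrayDesign-class]; default 21893 probes.
#' @param nSaturated number of planted any-instance-saturated probes.
#' @param nBackground number of planted never-above-background probes.
#' @param satCeiling saturation ceiling.
#' @return a list with `intensities` and `truth` (the planted probe-id
#'   sets).
#' @export
simulateQcProfile <- function(seed,
                              design = arrayDesign(nProbes = 21893L),
                              nSaturated = 10L, nBackground = 82L,
                              satCeiling = 65535) {
  if (missing(seed) || is.null(seed))
    configError("simulateQcProfile: 'seed' is required")
  if (nSaturated + nBackground > design@nProbes)
    configError("planted counts exceed the number of probes")
  withSeed(seed, {
    np <- design@nProbes
    ns <- design@spotsPerProbe
    na <- length(design@timepoints) * length(design@replicates)
    nrows <- np * ns
    y <- stats::rnorm(np, 8, 1)[rep(seq_len(np), each = ns)] +
      matrix(stats::rnorm(nrows * na, 0, 0.27), nrows, na)
    linear <- 2^y
    linear[linear >= satCeiling] <- satCeiling - 1  # keep clean probes clean
    saturated <- matrix(FALSE, nrows, na)
    above <- matrix(TRUE, nrows, na)

    planted <- sample(np, nSaturated + nBackground)
    sat_probes <- planted[seq_len(nSaturated)]
    bg_probes <- setdiff(planted, sat_probes)
    for (p in sat_probes) {
      row <- (p - 1L) * ns + sample(ns, 1L)
      col <- sample(na, 1L)
      linear[row, col] <- satCeiling
      saturated[row, col] <- TRUE
    }
    bg_rows <- rep(seq_len(np) %in% bg_probes, each = ns)
    nbg <- sum(bg_rows)
    draw <- matrix(stats::rnorm(nbg * na, 4, 1), nbg, na)
    draw[draw < 0] <- 0
    linear[bg_rows, ] <- draw
    above[bg_rows, ] <- FALSE

    ie <- buildIntensityExperiment(design, linear, saturated, above)
    probes <- sprintf("P%05d", seq_len(np))
    list(intensities = ie,
         truth = list(saturated_probes = probes[sat_probes],
                      background_probes = probes[bg_probes]))
  })
}

#' Simulate a qPCR panel with serial-dilution standards
#'
#' Standards span 10-fold dilutions from 10 to 1e7 copies in triplicate;
#' every Ct follows `intercept + slope * log10(copies)` plus
#' Normal(0, `sigmaCt`) noise.
#'
#' @param trueCounts data frame with columns `gene`, `sample`, `copies`
#'   (copies must be positive).
#' @param slope standard-curve slope, Ct per log10(copies); must be
#'   negative (-3.3219 corresponds to 100% amplification efficiency).
#' @param intercept Ct at one copy.
#' @param sigmaCt Ct measurement noise SD.
#' @param dilutions copy numbers of the plasmid standards.
#' @param nStandardReplicates technical replicates per standard level.
#' @param seed integer seed.
#' @return list with `standards` (gene, copies, replicate, Ct) and
#'   `samples` (gene, sample, Ct) data frames.
#' @export
simulateQpcrPanel <- function(trueCounts, slope = -3.3219, intercept = 40,
                              sigmaCt = 0.15, dilutions = 10^(1:7),
                              nStandardReplicates = 3L, seed) {
  if (missing(seed) || is.null(seed))
    configError("simulateQpcrPanel: 'seed' is required")
  if (slope >= 0) configError("standard-curve slope must be negative")
  need <- c("gene", "sample", "copies")
  if (!all(need %in% colnames(trueCounts)))
    configError("trueCounts must have columns gene, sample, copies")
  if (any(trueCounts$copies <= 0))
    stop2("cypwaves_domain_error", "copy numbers must be positive")
  withSeed(seed, {
    genes <- unique(trueCounts$gene)
    std <- expand.grid(replicate = seq_len(nStandardReplicates),
                       copies = dilutions, gene = genes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    std <- std[, c("gene", "copies", "replicate")]
    std$Ct <- intercept + slope * log10(std$copies) +
      stats::rnorm(nrow(std), 0, sigmaCt)
    smp <- trueCounts[, c("gene", "sample")]
    smp$Ct <- intercept + slope * log10(trueCounts$copies) +
      stats::rnorm(nrow(smp), 0, sigmaCt)
    list(standards = std, samples = smp)
  })
}

#' Simulate unfertilized-egg (oocyte) qPCR samples
#'
#' Emulates the maternal-transcript assay: eggs from `nFemales` females,
#' with genes in `maternalSet` carrying deposited transcript (true copy
#' numbers around `maternalCopies`) and all other targets near zero.
#' The reference gene (default ARNT2) is present in every sample.
#'
#' @param genes character vector of target genes.
#' @param maternalSet subset of `genes` with maternal transcript.
#' @param maternalCopies geometric-mean copy number for maternal genes.
#' @param bioSd biological log2 SD of true copies between females (0 for
#'   exact planted counts).
#' @param nFemales number of females (biological replicates).
#' @param referenceGene reference transcript name.
#' @param referenceCopies copies of the reference per sample.
#' @param sigmaCt Ct noise SD, passed to [simulateQpcrPanel()].
#' @param seed integer seed.
#' @return list with `standards`, `samples` and `truth` (the planted
#'   per-gene, per-sample copy numbers).
#' @export
simulateOocytePanel <- function(genes, maternalSet = character(),
                                maternalCopies = 1000, bioSd = 0.25,
                                nFemales = 3L, referenceGene = "ARNT2",
                                referenceCopies = 5000,
                                sigmaCt = 0.15, seed) {
  if (missing(seed) || is.null(seed))
    configError("simulateOocytePanel: 'seed' is required")
  if (!all(maternalSet %in% genes))
    configError("maternalSet must be a subset of genes")
  withSeed(seed, {
    samples <- sprintf("egg%d", seq_len(nFemales))
    all_genes <- unique(c(genes, referenceGene))
    grid <- expand.grid(gene = all_genes, sample = samples,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    copies <- numeric(nrow(grid))
    maternal <- grid$gene %in% maternalSet
    refrow <- grid$gene == referenceGene
    copies[maternal] <- maternalCopies *
      2^stats::rnorm(sum(maternal), 0, bioSd)
    copies[refrow] <- referenceCopies * 2^stats::rnorm(sum(refrow), 0, bioSd)
    rest <- !maternal & !refrow
    copies[rest] <- stats::runif(sum(rest), 0.5, 2)  # effectively absent
    grid$copies <- copies
    panel <- simulateQpcrPanel(grid, sigmaCt = sigmaCt,
                               seed = sample.int(.Machine$integer.max, 1L))
    list(standards = panel$standards, samples = panel$samples, truth = grid)
  })
}
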