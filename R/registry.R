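#' Path to the packaged CYP gene registry
#'
#' The registry table ships with the package: 96 genomic records covering
#' the 94 distinct zebrafish CYP genes in 18 families (two genes are
#' present twice as exact assembly copies, suffixed `c1`/`c2`).
#'
#' @return path to the tab-separated registry file.
#' @export
cypRegistryFile <- function() {
  system.file("extdata", "cyp_registry.tsv", package = "cypwaves",
              mustWork = TRUE)
}

#' Load a CYP gene registry
#'
#' Reads a tab-separated registry table (one row per genomic locus) and
#' validates it: coordinates must satisfy `tx_start <= tx_end`, strand
#' must be +1/-1, the CYP family number must match the one parsed from
#' the gene symbol, and coordinates must be absent exactly for loci
#' flagged `missing_from_assembly`.
#'
#' @param path path to a registry TSV; defaults to the packaged table.
#' @return a [CypRegistry-class] object.
#' @examples
#' reg <- loadRegistry()
#' countGenes(reg)        # 94 distinct genes
#' countFamilies(reg)     # 18 CYP families
#' @export
loadRegistry <- function(path = cypRegistryFile()) {
  if (!file.exists(path)) schemaError("registry file not found: %s", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           na.strings = NULL, check.names = FALSE)
  missing_cols <- setdiff(REQUIRED_REGISTRY_COLUMNS, colnames(raw))
  if (length(missing_cols))
    schemaError("registry schema error: missing column(s) %s",
                paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L)
    schemaError("registry schema error: no data rows in %s", path)

  asIntOrNA <- function(x, what) {
    x[!nzchar(x)] <- NA_character_
    out <- suppressWarnings(as.integer(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad))
      validationError("row %d (%s): invalid %s value '%s'",
                      bad[1L], raw$gene_name[bad[1L]], what, x[bad[1L]])
    out
  }
  tx_start <- asIntOrNA(raw$tx_start, "tx_start")
  tx_end   <- asIntOrNA(raw$tx_end, "tx_end")
  exon     <- asIntOrNA(raw$exon_count, "exon_count")
  strand   <- asIntOrNA(sub("^\\+", "", raw$strand), "strand")
  bad_strand <- which(!is.na(strand) & !(strand %in% c(-1L, 1L)))
  if (length(bad_strand))
    validationError("row %d (%s): strand '%s' outside {+1, -1}",
                    bad_strand[1L], raw$gene_name[bad_strand[1L]],
                    raw$strand[bad_strand[1L]])
  family <- asIntOrNA(raw$family, "family")
  if (anyNA(family)) validationError("family must be an integer for all rows")

  flags <- strsplit(raw$flags, ",", fixed = TRUE)
  flags <- lapply(flags, function(f) f[nzchar(f)])
  unknown <- setdiff(unlist(flags), KNOWN_FLAGS)
  if (length(unknown))
    validationError("unknown flag(s): %s", paste(unknown, collapse = ", "))

  bad_coord <- which(!is.na(tx_start) & !is.na(tx_end) & tx_start > tx_end)
  if (length(bad_coord))
    validationError("row %d (%s): tx_start %d > tx_end %d",
                    bad_coord[1L], raw$gene_name[bad_coord[1L]],
                    tx_start[bad_coord[1L]], tx_end[bad_coord[1L]])

  fam_from_name <- suppressWarnings(
    as.integer(sub("^CYP([0-9]+).*$", "\\1", raw$gene_name)))
  mism <- which(is.na(fam_from_name) | fam_from_name != family)
  if (length(mism))
    validationError("row %d (%s): family %d does not match the gene name",
                    mism[1L], raw$gene_name[mism[1L]], family[mism[1L]])
  dup <- which(duplicated(raw$gene_name))
  if (length(dup))
    validationError("duplicated gene name: %s", raw$gene_name[dup[1L]])

  chrom <- raw$chromosome
  chrom[!nzchar(chrom)] <- NA_character_
  rec <- S4Vectors::DataFrame(
    gene_name  = raw$gene_name,
    family     = family,
    subfamily  = raw$subfamily,
    chromosome = chrom,
    tx_start   = tx_start,
    tx_end     = tx_end,
    strand     = strand,
    exon_count = exon,
    flags      = IRanges::CharacterList(flags)
  )
  tryCatch(
    new("CypRegistry", records = rec,
        provenance = c(source = path,
                       version = as.character(utils::packageVersion("cypwaves")))),
    error = function(e)
      validationError("invalid registry: %s", conditionMessage(e)))
}

#' @rdname CypRegistry-class
#' @export
setMethod("registryTable", "CypRegistry", function(x) x@records)

#' @rdname CypRegistry-class
#' @export
setMethod("registryProvenance", "CypRegistry", function(x) x@provenance)

setMethod("show", "CypRegistry", function(object) {
  rec <- object@records
  cat(sprintf("CypRegistry: %d records, %d distinct genes, %d families\n",
              nrow(rec), countGenes(object), countFamilies(object)))
  cat("  source:", unname(object@provenance["source"]), "\n")
})

#' @describeIn CypRegistry-class number of records.
#' @export
setMethod("length", "CypRegistry", function(x) nrow(x@records))

hasFlag <- function(rec, flag) {
  vapply(rec$flags, function(f) flag %in% f, logical(1))
}

selectRecords <- function(rec, family = NULL, subfamily = NULL,
                          chrom = NULL, onArray = NULL) {
  keep <- rep(TRUE, nrow(rec))
  if (!is.null(family))    keep <- keep & rec$family %in% as.integer(family)
  if (!is.null(subfamily)) keep <- keep & rec$subfamily %in% subfamily
  if (!is.null(chrom))     keep <- keep & !is.na(rec$chromosome) &
                             rec$chromosome %in% as.character(chrom)
  if (!is.null(onArray))   keep <- keep & (hasFlag(rec, "on_array") == onArray)
  rec[keep, , drop = FALSE]
}

#' Count distinct CYP genes and families
#'
#' Counting follows a one-gene-one-distinct-name convention: assembly
#' copies (`c1`/`c2` suffixes) of the same base name collapse to a single
#' gene, and genes missing from the assembly still count.  On the
#' packaged registry `countGenes()` returns 94 and `countFamilies()` 18.
#'
#' @param x a [CypRegistry-class].
#' @param family optional integer CYP family number(s) to restrict to.
#' @param subfamily optional subfamily code(s), e.g. `"2K"` or `"46A"`.
#' @param chrom optional chromosome label(s).
#' @param onArray if `TRUE`/`FALSE`, restrict to genes (not) represented
#'   on the microarray.
#' @return an integer count.
#' @examples
#' reg <- loadRegistry()
#' countGenes(reg, family = 3)       # five CYP3 genes
#' countGenes(reg, subfamily = "46A")
#' @rdname countGenes
#' @export
setMethod("countGenes", "CypRegistry",
  function(x, family = NULL, subfamily = NULL, chrom = NULL, onArray = NULL) {
    rec <- selectRecords(x@records, family, subfamily, chrom, onArray)
    length(unique(baseGeneName(rec$gene_name)))
  })

#' @rdname countGenes
#' @export
setMethod("countFamilies", "CypRegistry",
  function(x, family = NULL, subfamily = NULL, chrom = NULL, onArray = NULL) {
    rec <- selectRecords(x@records, family, subfamily, chrom, onArray)
    length(unique(rec$family))
  })

#' Genomic ranges of registry records
#'
#' @param x a [CypRegistry-class].
#' @param ... unused.
#' @return a [GenomicRanges::GRanges] with one range per record that has
#'   coordinates; records missing from the assembly are dropped.
#' @rdname CypRegistry-class
#' @export
setMethod("registryRanges", "CypRegistry", function(x, ...) {
  rec <- x@records
  rec <- rec[!hasFlag(rec, "missing_from_assembly"), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = rec$chromosome,
    ranges   = IRanges::IRanges(start = rec$tx_start, end = rec$tx_end),
    strand   = ifelse(rec$strand == 1L, "+", "-")
  )
  names(gr) <- rec$gene_name
  S4Vectors::mcols(gr) <- rec[, c("gene_name", "family", "subfamily",
                                  "exon_count", "flags")]
  gr
})

#' Detect tandemly duplicated gene clusters
#'
#' Single-linkage grouping of genes along each chromosome, within one CYP
#' family: records in scope are sorted by transcript start (ties broken
#' by end, then name) and a new cluster opens whenever the gap between
#' the next transcript start and the running maximum transcript end
#' exceeds `maxGap`.  Singletons are reported as size-1 clusters.  On the
#' packaged registry with the default 100 kb gap this recovers, among
#' others, the 8-gene CYP2K array on chromosome 3, the 10-gene CYP2AA
#' array on chromosome 23, and an 11-member family-2 cluster (CYP2N/2AD/
#' 2V/2P subfamilies) on chromosome 20.
#'
#' @param x a [CypRegistry-class].
#' @param maxGap maximum intergenic gap, in base pairs, for two
#'   neighbours to join the same cluster (default 100000; large enough to
#'   keep printed intra-array gaps together while separating the CYP2AE
#'   pair ~230 kb downstream of the CYP2AA array).
#' @param chrom,family,subfamily optional scope filters.
#' @return a [S4Vectors::DataFrame], one row per cluster, with columns
#'   `chromosome`, `family`, `n`, `span_start`, `span_end` and a
#'   `members` [IRanges::CharacterList] ordered by transcript start.
#' @examples
#' reg <- loadRegistry()
#' tandemClusters(reg, chrom = 23, subfamily = "2AA")
#' @rdname tandemClusters
#' @export
setMethod("tandemClusters", "CypRegistry",
  function(x, maxGap = 100000, chrom = NULL, family = NULL,
           subfamily = NULL) {
    rec <- selectRecords(x@records, family, subfamily, chrom)
    absent <- hasFlag(rec, "missing_from_assembly")
    if (any(absent))
      message(sprintf("tandemClusters: excluding %d record(s) without coordinates: %s",
                      sum(absent), paste(rec$gene_name[absent], collapse = ", ")))
    rec <- rec[!absent, , drop = FALSE]
    out <- list()
    if (nrow(rec)) {
      groups <- split(seq_len(nrow(rec)),
                      paste(rec$chromosome, rec$family, sep = "|"))
      for (idx in groups) {
        g <- rec[idx, , drop = FALSE]
        ord <- order(g$tx_start, g$tx_end, g$gene_name)
        g <- g[ord, , drop = FALSE]
        run_end <- cummax(g$tx_end)
        gap <- c(0, g$tx_start[-1L] - run_end[-nrow(g)])
        cl <- cumsum(gap > maxGap)
        for (k in split(seq_len(nrow(g)), cl)) {
          out[[length(out) + 1L]] <- list(
            chromosome = g$chromosome[k[1L]],
            family     = g$family[k[1L]],
            n          = length(k),
            span_start = min(g$tx_start[k]),
            span_end   = max(g$tx_end[k]),
            members    = g$gene_name[k]
          )
        }
      }
    }
    res <- S4Vectors::DataFrame(
      chromosome = vapply(out, `[[`, character(1), "chromosome"),
      family     = vapply(out, `[[`, integer(1), "family"),
      n          = vapply(out, `[[`, integer(1), "n"),
      span_start = vapply(out, `[[`, integer(1), "span_start"),
      span_end   = vapply(out, `[[`, integer(1), "span_end"),
      members    = IRanges::CharacterList(lapply(out, `[[`, "members"))
    )
    res[order(res$chromosome, res$span_start), , drop = FALSE]
  })

#' Export a registry to TSV, BED or GFF3
#'
#' TSV preserves the registry losslessly (a round trip through
#' [loadRegistry()] reproduces the object).  BED uses 0-based half-open
#' coordinates and `+`/`-` strand; GFF3 stays 1-based inclusive.  Records
#' without coordinates are only representable in TSV and are dropped
#' (with a message) from BED/GFF3.
#'
#' @param x a [CypRegistry-class].
#' @param path output file path.
#' @param format one of `"tsv"`, `"bed"`, `"gff3"`.
#' @param ... unused.
#' @return `path`, invisibly.
#' @rdname exportRegistry
#' @export
setMethod("exportRegistry", "CypRegistry",
  function(x, path, format = c("tsv", "bed", "gff3"), ...) {
    if (!is.character(format) || !all(format %in% c("tsv", "bed", "gff3")))
      usageError("unknown export format '%s'", paste(format, collapse = ","))
    format <- match.arg(format)
    rec <- x@records
    if (format == "tsv") {
      df <- as.data.frame(rec[, setdiff(colnames(rec), "flags")])
      df$flags <- vapply(rec$flags, paste, character(1), collapse = ",")
      for (cl in c("tx_start", "tx_end", "strand", "exon_count", "chromosome"))
        df[[cl]][is.na(df[[cl]])] <- ""
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else {
      gr <- registryRanges(x)
      dropped <- nrow(rec) - length(gr)
      if (dropped > 0L)
        message(sprintf("exportRegistry: dropping %d record(s) without coordinates",
                        dropped))
      if (format == "bed") {
        bed <- data.frame(
          chrom = as.character(GenomicRanges::seqnames(gr)),
          start = GenomicRanges::start(gr) - 1L,  # 0-based half-open
          end   = GenomicRanges::end(gr),
          name  = names(gr),
          score = 0L,
          strand = as.character(GenomicRanges::strand(gr))
        )
        utils::write.table(bed, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
      } else {
        mc <- S4Vectors::mcols(gr)
        gff <- gr
        S4Vectors::mcols(gff) <- S4Vectors::DataFrame(
          source = "cypwaves", type = "gene",
          ID = mc$gene_name, Name = mc$gene_name,
          cyp_family = mc$family, cyp_subfamily = mc$subfamily,
          exon_count = mc$exon_count
        )
        rtracklayer::export.gff3(gff, path)
      }
    }
    invisible(path)
  })
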