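reg <- loadRegistry()

test_that("packaged registry loads with the expected gene accounting", {
  expect_s4_class(reg, "CypRegistry")
  expect_equal(length(reg), 96L)            # rows, incl. two c1/c2 pairs
  expect_equal(countGenes(reg), 94L)        # distinct genes
  expect_equal(countFamilies(reg), 18L)
  # assembly copies collapse: rows - number of c2 copies
  tab <- registryTable(reg)
  n_c2 <- sum(grepl("c2$", tab$gene_name))
  expect_equal(countGenes(reg), length(reg) - n_c2)
  expect_equal(countGenes(reg, family = 999), 0L)  # empty selection
})

test_that("family and subfamily counts match the gene complement", {
  expect_equal(countGenes(reg, family = 1), 5L)
  expect_equal(countGenes(reg, family = 3), 5L)
  expect_equal(countGenes(reg, family = 4), 4L)
  expect_equal(countGenes(reg, family = 27), 7L)
  expect_equal(countGenes(reg, subfamily = "46A"), 4L)
  expect_equal(countGenes(reg, onArray = TRUE), 88L)
  # distinct families among the endogenous-function set (families >= 5)
  fams <- unique(registryTable(reg)$family)
  expect_equal(countFamilies(reg, family = fams[fams >= 5]), 14L)
  one <- loadRegistry(writeRegistryTsv(
    miniRegistry("CYP1A", 1L, "1A", "18", 3972990L, 3983879L, -1L)))
  expect_equal(countFamilies(one), 1L)
})

test_that("malformed registry files are rejected with named rows", {
  empty <- tempfile(fileext = ".tsv")
  writeLines(paste(c("gene_name", "family", "subfamily", "chromosome",
                     "tx_start", "tx_end", "strand", "exon_count", "flags"),
                   collapse = "\t"), empty)
  expect_error(loadRegistry(empty), class = "cypwaves_schema_error")

  df <- miniRegistry("CYP1A", 1L, "1A", "18", 3972990L, 3983879L, -1L)
  noCol <- df[, setdiff(colnames(df), "strand")]
  expect_error(loadRegistry(writeRegistryTsv(noCol)),
               class = "cypwaves_schema_error")

  bad_strand <- miniRegistry("CYP1A", 1L, "1A", "18", 10L, 20L, strand = 0L)
  expect_error(loadRegistry(writeRegistryTsv(bad_strand)),
               class = "cypwaves_validation_error")

  flipped <- miniRegistry("CYP1A", 1L, "1A", "18", 500L, 100L, 1L)
  expect_error(loadRegistry(writeRegistryTsv(flipped)), "CYP1A")

  mismatch <- miniRegistry("CYP2K6", 3L, "2K", "3", 10L, 20L)
  expect_error(loadRegistry(writeRegistryTsv(mismatch)),
               class = "cypwaves_validation_error")
})

test_that("tandem arrays on chromosomes 3, 20 and 23 are recovered", {
  aa <- suppressMessages(tandemClusters(reg, chrom = 23, subfamily = "2AA"))
  expect_equal(nrow(aa), 1L)
  expect_equal(aa$n, 10L)

  k <- tandemClusters(reg, chrom = 3, subfamily = "2K")
  expect_setequal(k$n, c(8L, 3L))
  small <- unlist(k$members[k$n == 3L])
  expect_setequal(small, c("CYP2K22", "CYP2K7", "CYP2K31"))

  fam2 <- tandemClusters(reg, chrom = 20, family = 2)
  expect_equal(nrow(fam2), 1L)
  expect_equal(fam2$n, 11L)

  # the CYP2AE tandem pair ~230 kb downstream stays separate at 100 kb
  chr23 <- tandemClusters(reg, chrom = 23, family = 2)
  ae <- chr23[vapply(chr23$members, function(m) "CYP2AE1" %in% m, logical(1)), ]
  expect_equal(ae$n, 2L)
})

test_that("clustering is a gap-bounded partition, invariant to row order", {
  sub <- registryTable(reg)
  sub <- as.data.frame(sub[sub$chromosome %in% "20" & sub$family == 2L,
                           setdiff(colnames(sub), "flags")])
  sub$flags <- "on_array"
  maxGap <- 30000
  cl <- tandemClusters(loadRegistry(writeRegistryTsv(sub)), maxGap = maxGap)
  # partition: every gene in exactly one cluster
  all_members <- unlist(cl$members)
  expect_setequal(all_members, sub$gene_name)
  expect_false(anyDuplicated(all_members) > 0)
  # brute-force all-pairs oracle on this <= 20 gene instance:
  # consecutive within-cluster gaps <= maxGap, between-cluster gaps > maxGap
  ord <- order(sub$tx_start)
  run_end <- cummax(sub$tx_end[ord])
  gaps <- sub$tx_start[ord][-1L] - run_end[-length(ord)]
  oracle_breaks <- which(gaps > maxGap)
  expect_equal(nrow(cl), length(oracle_breaks) + 1L)
  # cross-check against interval merging from GenomicRanges
  gr <- GenomicRanges::GRanges("20", IRanges::IRanges(sub$tx_start, sub$tx_end))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = maxGap)
  expect_equal(nrow(cl), length(merged))
  # row order invariance
  shuf <- sub[sample(nrow(sub)), ]
  cl2 <- tandemClusters(loadRegistry(writeRegistryTsv(shuf)), maxGap = maxGap)
  expect_identical(as.list(cl$members), as.list(cl2$members))

  far <- miniRegistry(c("CYP9A1", "CYP9A2"), 9L, "9A", "1",
                      c(1000L, 301000L), c(2000L, 302000L))
  two <- tandemClusters(loadRegistry(writeRegistryTsv(far)), maxGap = 100000)
  expect_equal(two$n, c(1L, 1L))
})

test_that("export formats convert coordinates correctly and round-trip", {
  bed <- tempfile(fileext = ".bed")
  suppressMessages(exportRegistry(reg, bed, "bed"))
  b <- read.delim(bed, header = FALSE)
  cyp5 <- b[b$V4 == "CYP5A1", ]
  expect_equal(cyp5$V2, 12577084L - 1L)   # 0-based half-open start
  expect_equal(cyp5$V3, 12755668L)
  cyp7a <- b[b$V4 == "CYP7A1", ]
  expect_equal(cyp7a$V6, "-")

  tsv <- tempfile(fileext = ".tsv")
  exportRegistry(reg, tsv, "tsv")
  back <- loadRegistry(tsv)
  expect_equal(as.data.frame(registryTable(back)),
               as.data.frame(registryTable(reg)))

  gff <- tempfile(fileext = ".gff3")
  suppressMessages(exportRegistry(reg, gff, "gff3"))
  g <- rtracklayer::import(gff)
  expect_equal(GenomicRanges::start(g[g$Name == "CYP5A1"]), 12577084L)

  expect_error(exportRegistry(reg, tempfile(), "xlsx"),
               class = "cypwaves_usage_error")
})

test_that("registryRanges drops assembly-missing loci and keeps metadata", {
  gr <- registryRanges(reg)
  expect_equal(length(gr), 94L)  # 96 rows - 2 missing-from-assembly loci
  expect_false(any(c("CYP46A5", "CYP2AA13") %in% names(gr)))
  expect_equal(unname(S4Vectors::mcols(gr)$family[names(gr) == "CYP51A1"]), 51L)
})
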