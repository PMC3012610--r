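#' Read and write spot-level intensity tables
#'
#' The on-disk dialect is a long tab-separated table, one row per
#' (probe, spot, array) instance, with columns `probe_id`, `spot_index`,
#' `array_id`, `timepoint_hpf`, `replicate`, `signal`, `saturated`,
#' `above_background`.
#'
#' @param x an [IntensityExperiment-class].
#' @param path file path.
#' @return `writeIntensityTable()` returns `path` invisibly;
#'   `readIntensityTable()` returns an [IntensityExperiment-class].
#' @export
writeIntensityTable <- function(x, path) {
  stopifnot(is(x, "IntensityExperiment"))
  rd <- SummarizedExperiment::rowData(x)
  cd <- SummarizedExperiment::colData(x)
  sig <- SummarizedExperiment::assay(x, "signal")
  sat <- SummarizedExperiment::assay(x, "saturated")
  abv <- SummarizedExperiment::assay(x, "above_background")
  nr <- nrow(sig); nc <- ncol(sig)
  df <- data.frame(
    probe_id = rep(rd$probe_id, times = nc),
    spot_index = rep(rd$spot_index, times = nc),
    array_id = rep(colnames(sig), each = nr),
    timepoint_hpf = rep(cd$timepoint_hpf, each = nr),
    replicate = rep(cd$replicate, each = nr),
    signal = as.vector(sig),
    saturated = as.vector(sat),
    above_background = as.vector(abv))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeIntensityTable
#' @export
readIntensityTable <- function(path) {
  if (!file.exists(path)) schemaError("intensity table not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("probe_id", "spot_index", "array_id", "timepoint_hpf",
            "replicate", "signal", "saturated", "above_background")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols))
    schemaError("intensity table missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  aid <- unique(df$array_id)
  feat <- unique(paste(df$probe_id, df$spot_index, sep = "_"))
  key <- paste(df$probe_id, df$spot_index, sep = "_")
  toMatrix <- function(v) {
    m <- matrix(NA, length(feat), length(aid),
                dimnames = list(feat, aid))
    m[cbind(match(key, feat), match(df$array_id, aid))] <- v
    m
  }
  first <- !duplicated(key)
  cd_first <- !duplicated(df$array_id)
  rd <- S4Vectors::DataFrame(probe_id = df$probe_id[first],
                             spot_index = df$spot_index[first])
  cd <- S4Vectors::DataFrame(array_id = df$array_id[cd_first],
                             timepoint_hpf = df$timepoint_hpf[cd_first],
                             replicate = as.character(df$replicate[cd_first]))
  rownames(cd) <- cd$array_id
  new("IntensityExperiment", SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = toMatrix(df$signal),
                  saturated = toMatrix(df$saturated) > 0,
                  above_background = toMatrix(df$above_background) > 0),
    rowData = rd, colData = cd))
}

# deterministic TSV writer for numeric result tables (full precision)
writeResultTable <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- sprintf("%.10g", df[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
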