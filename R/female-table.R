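#' Load the female sperm-viability table
#'
#' Reads a CSV of per-female records: sperm storage time in the seminal
#' receptacle (months) and percentage of viable spermatozoa (FDA staining).
#' The packaged default is the published 30-female *Maja brachydactyla*
#' study table used by the statistical examples and tests.
#'
#' @param path CSV with columns `individual`, `trial`, `storage_months`,
#'   `viability`. Defaults to the packaged table.
#' @return A data.frame with columns `individual_id`, `trial_id`,
#'   `storage_time` (months) and `viability` (percent), in file order.
#' @examples
#' fem <- load_female_table()
#' nrow(fem)            # 30
#' range(fem$storage_time)
#' @export
load_female_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "female_viability.csv", package = "cometseg",
                        mustWork = TRUE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("individual", "trial", "storage_months", "viability")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop(errorCondition(
      sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
      class = c("cometseg_schema_error", "cometseg_error")))
  }
  out <- data.frame(individual_id = as.character(raw$individual),
                    trial_id = as.character(raw$trial),
                    storage_time = as.numeric(raw$storage_months),
                    viability = as.numeric(raw$viability),
                    stringsAsFactors = FALSE)
  bad <- which(!is.finite(out$viability) | out$viability < 0 | out$viability > 100)
  if (length(bad)) {
    stop(errorCondition(
      sprintf("viability outside [0, 100] in row(s): %s", paste(bad, collapse = ", ")),
      class = c("cometseg_validation_error", "cometseg_error")))
  }
  if (any(!is.finite(out$storage_time) | out$storage_time < 0)) {
    stop(errorCondition("storage_months must be non-negative",
                        class = c("cometseg_validation_error", "cometseg_error")))
  }
  out
}

#' Export per-comet metrics as CSV
#'
#' Writes one row per comet with a fixed column order:
#' `image_id, comet_id, head_area, tail_area, head_dna, tail_dna,
#' tail_dna_fraction, tail_length_px, tail_moment, accepted, discard_reason`.
#' Decimal point, UTF-8, header row.
#'
#' @param metrics a data.frame (or list of rows) of comet metrics as
#'   produced by [measure_comet()] plus `image_id` / `comet_id` columns.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
export_metrics_csv <- function(metrics, path) {
  cols <- c("image_id", "comet_id", "head_area", "tail_area", "head_dna",
            "tail_dna", "tail_dna_fraction", "tail_length_px", "tail_moment",
            "accepted", "discard_reason")
  if (!is.data.frame(metrics)) {
    metrics <- do.call(rbind, lapply(metrics, function(m) {
      as.data.frame(m[cols], stringsAsFactors = FALSE)
    }))
  }
  missing <- setdiff(cols, names(metrics))
  if (length(missing)) {
    stop(sprintf("metrics missing column(s): %s", paste(missing, collapse = ", ")))
  }
  tmp <- paste0(path, ".tmp", Sys.getpid())
  utils::write.csv(metrics[, cols, drop = FALSE], tmp, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE); unlink(tmp)
  }
  invisible(path)
}
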