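#' Build a scan-record manifest
#'
#' One row per acquired 3D power-Doppler scan: subject, gestational age in
#' days, image-quality score on the 0 (optimal) to 3 (unusable) scale, and
#' file references for the amplitude grid and placental mask.
#'
#' @param subject_id Character vector of subject identifiers.
#' @param ga_days Gestational age at scan (days).
#' @param quality Integer quality scores in 0..3.
#' @param grid_path,mask_path Optional file paths.
#' @return A data.frame with class `scan_manifest`.
#' @export
scan_manifest <- function(subject_id, ga_days, quality,
                          grid_path = NA_character_, mask_path = NA_character_) {
  quality <- as.integer(quality)
  if (anyNA(quality) || any(quality < 0L | quality > 3L))
    stop("quality scores must be integers in 0..3")
  out <- data.frame(subject_id = as.character(subject_id),
                    ga_days = as.numeric(ga_days),
                    quality = quality,
                    grid_path = as.character(grid_path),
                    mask_path = as.character(mask_path),
                    stringsAsFactors = FALSE)
  class(out) <- c("scan_manifest", "data.frame")
  out
}

#' Drop unusable scans by image quality
#'
#' Scans are scored 0 (optimal) to 3 (unusable); score-3 scans are excluded
#' from all analyses. Order is preserved and the operation is idempotent.
#'
#' @param records A [scan_manifest()] or data.frame with a `quality` column.
#' @return The records with `quality <= 2`, in the original order.
#' @export
filter_by_quality <- function(records) {
  if (!"quality" %in% names(records)) stop("records need a `quality` column")
  q <- records$quality
  if (anyNA(q) || any(q != round(q)) || any(q < 0 | q > 3))
    stop("quality scores must be integers in 0..3")
  records[q <= 2, , drop = FALSE]
}

#' Read / write a scan manifest CSV
#'
#' Columns: subject_id, ga_days, quality, grid_path, mask_path.
#' @param path CSV path.
#' @return `read_manifest`: a [scan_manifest()].
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "ga_days", "quality")
  if (!all(need %in% names(df)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  if (!"grid_path" %in% names(df)) df$grid_path <- NA_character_
  if (!"mask_path" %in% names(df)) df$mask_path <- NA_character_
  scan_manifest(df$subject_id, df$ga_days, df$quality, df$grid_path,
                df$mask_path)
}

#' @rdname read_manifest
#' @param records A scan manifest.
#' @export
write_manifest <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
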