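#' Acquisition metadata for an OCT scan
#'
#' Describes how a macular volume was acquired.  The two Spectralis-style
#' protocols supported are `"raster"` (parallel B-scans, default
#' 25 B-scans of 512 A-scans) and `"star"` (radially arranged B-scans,
#' default 12 B-scans of 768 A-scans).  Arbitrary sizes are accepted; the
#' defaults only apply when `n_bscans`/`n_ascans` are omitted.
#'
#' @param pattern Acquisition pattern, `"raster"` or `"star"`.
#' @param eye Laterality, `"OD"` (right) or `"OS"` (left).
#' @param n_bscans,n_ascans Number of B-scans and of A-scans per B-scan.
#' @param axial_resolution_um Axial sampling of the scanner in micrometres.
#' @param scan_id,subject_id Free-form identifiers.
#' @return An object of class `scan_meta`.
#' @export
scan_meta <- function(pattern = c("raster", "star"), eye = c("OD", "OS"),
                      n_bscans = NULL, n_ascans = NULL,
                      axial_resolution_um = 3.87,
                      scan_id = "scan", subject_id = "subject") {
  pattern <- match.arg(pattern)
  eye <- match.arg(eye)
  if (is.null(n_bscans)) n_bscans <- if (pattern == "raster") 25L else 12L
  if (is.null(n_ascans)) n_ascans <- if (pattern == "raster") 512L else 768L
  n_bscans <- as.integer(n_bscans)
  n_ascans <- as.integer(n_ascans)
  if (n_bscans < 1L || n_ascans < 1L)
    stop("n_bscans and n_ascans must be positive integers", call. = FALSE)
  if (!is.numeric(axial_resolution_um) || axial_resolution_um <= 0)
    stop("axial_resolution_um must be a positive real", call. = FALSE)
  structure(
    list(pattern = pattern, eye = eye, n_bscans = n_bscans,
         n_ascans = n_ascans,
         axial_resolution_um = as.numeric(axial_resolution_um),
         scan_id = as.character(scan_id),
         subject_id = as.character(subject_id)),
    class = "scan_meta")
}

#' @export
print.scan_meta <- function(x, ...) {
  cat(sprintf("<scan_meta> %s %s: %d B-scans x %d A-scans (axial %.2f um), %s/%s\n",
              x$pattern, x$eye, x$n_bscans, x$n_ascans,
              x$axial_resolution_um, x$subject_id, x$scan_id))
  invisible(x)
}

#' Per-A-scan OCT layer segmentation container
#'
#' Holds the inner limiting membrane (ILM) and Bruch's membrane (BM)
#' heights of every A-scan, together with the lateral position of each
#' A-scan in the scanner plane (mm, origin at the scan centre, x temporal
#' to nasal and y inferior to superior after standardization).  Heights
#' are in micrometres above a flat reference with the BM flattening
#' already applied, so `ilm_um >= bm_um` everywhere and their difference
#' is the total retinal thickness.
#'
#' @param meta A [scan_meta()] object.
#' @param data A data frame with columns `bscan_index`, `ascan_index`
#'   (0-based integers), `x_mm`, `y_mm`, `ilm_um`, `bm_um` and optionally
#'   `trt_um`.
#' @return An object of class `oct_scan`.
#' @export
oct_scan <- function(meta, data) {
  if (!inherits(meta, "scan_meta")) stop("meta must be a scan_meta", call. = FALSE)
  req <- c("bscan_index", "ascan_index", "x_mm", "y_mm", "ilm_um", "bm_um")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    stop("scan data is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  data <- as.data.frame(data)[, intersect(c(req, "trt_um"), names(data))]
  x <- structure(list(meta = meta, data = data), class = "oct_scan")
  validate_scan(x)
}

validate_scan <- function(scan) {
  d <- scan$data
  num <- c("x_mm", "y_mm", "ilm_um", "bm_um")
  for (cn in num) {
    bad <- which(!is.finite(d[[cn]]))
    if (length(bad))
      stop(sprintf("non-finite %s at data row(s) %s", cn,
                   paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  bad <- which(d$ilm_um < d$bm_um)
  if (length(bad))
    stop(sprintf("ilm_um < bm_um at data row(s) %s (segmentation order violated)",
                 paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  counts <- table(d$bscan_index)
  if (length(unique(as.integer(counts))) > 1L)
    stop("inconsistent B-scan lengths: every B-scan must hold the same number of A-scans",
         call. = FALSE)
  scan
}

#' @export
print.oct_scan <- function(x, ...) {
  print(x$meta)
  cat(sprintf("  %d A-scans, x in [%.2f, %.2f] mm, y in [%.2f, %.2f] mm\n",
              nrow(x$data), min(x$data$x_mm), max(x$data$x_mm),
              min(x$data$y_mm), max(x$data$y_mm)))
  invisible(x)
}

scan_columns <- c("bscan_index", "ascan_index", "x_mm", "y_mm",
                  "ilm_um", "bm_um", "trt_um")

#' Read an OCT scan from the TSV interchange format
#'
#' The interchange format replaces the proprietary scanner export: a TSV
#' file with header `bscan_index`, `ascan_index`, `x_mm`, `y_mm`,
#' `ilm_um`, `bm_um` (plus optional `trt_um`) and a JSON sidecar
#' `<path>.json` holding the [scan_meta()] fields.
#'
#' @param path Path to the TSV file.
#' @return A validated [oct_scan()].
#' @seealso [write_scan()]
#' @export
read_scan <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing JSON sidecar: ", sidecar, call. = FALSE)
  m <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  meta <- scan_meta(pattern = m$pattern, eye = m$eye,
                    n_bscans = m$n_bscans, n_ascans = m$n_ascans,
                    axial_resolution_um = m$axial_resolution_um,
                    scan_id = m$scan_id, subject_id = m$subject_id)
  d <- read.delim(path, sep = "\t", header = TRUE,
                  colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(scan_columns[1:6], names(d))
  if (length(missing_cols))
    stop("interchange file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cn in intersect(scan_columns, names(d))) {
    v <- suppressWarnings(as.numeric(d[[cn]]))
    bad <- which(is.na(v) & !(d[[cn]] %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("non-numeric value in column %s at data row(s) %s", cn,
                   paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
    d[[cn]] <- v
  }
  d$bscan_index <- as.integer(d$bscan_index)
  d$ascan_index <- as.integer(d$ascan_index)
  oct_scan(meta, d)
}

#' Write an OCT scan in the TSV interchange format
#'
#' Values are serialized with 6 significant digits (the 3.87 um axial
#' resolution makes finer digits meaningless); `read_scan(write_scan(s))`
#' reproduces the scan at that precision.
#'
#' @param scan An [oct_scan()].
#' @param path Output TSV path; the metadata sidecar is written to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "oct_scan"))
  d <- scan$data
  out <- data.frame(bscan_index = d$bscan_index, ascan_index = d$ascan_index)
  for (cn in setdiff(intersect(scan_columns, names(d)),
                     c("bscan_index", "ascan_index")))
    out[[cn]] <- signif(d[[cn]], 6L)
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write to: ", path, call. = FALSE)
  jsonlite::write_json(unclass(scan$meta), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
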