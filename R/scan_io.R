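#' Multi-scan intensity container
#'
#' A `scanset` holds raw median-foreground fluorescence (FLU) for one set of
#' arrays scanned at several PMT sensitivities: a probe x array x scan array
#' of integers in `[0, ceiling]`, together with probe identifiers, per-probe
#' control annotations and ordered scan labels. The scan axis is ordered
#' low-to-high by per-array median intensity; probe order is identical across
#' arrays and scans.
#'
#' @param intensities numeric array, dim `(n_probes, n_arrays, n_scans)`.
#' @param probe_ids character vector of unique probe identifiers.
#' @param control_type per-probe annotation: `"experimental"`,
#'   `"negative_control"` or `"other_control"`.
#' @param scan_labels labels for the scan levels, lowest first.
#' @param pmt_settings optional numeric matrix (array x scan) of PMT values.
#' @param ceiling detector saturation value (default 65535).
#' @return an object of class `scanset`.
#' @export
scanset <- function(intensities, probe_ids, control_type,
                    scan_labels = NULL, pmt_settings = NULL,
                    ceiling = 65535) {
  if (length(dim(intensities)) != 3L)
    stop("intensities must be a 3-d array (probe x array x scan)")
  n <- dim(intensities)[1]
  if (length(probe_ids) != n || length(control_type) != n)
    stop("probe_ids and control_type must match the probe dimension")
  if (anyDuplicated(probe_ids))
    stop("duplicate probe IDs: ", probe_ids[duplicated(probe_ids)][1])
  bad <- !control_type %in% c("experimental", "negative_control", "other_control")
  if (any(bad)) stop("unknown control_type value: ", control_type[bad][1])
  if (any(intensities < 0 | intensities > ceiling, na.rm = TRUE))
    stop("intensities outside [0, ceiling]")
  m <- dim(intensities)[3]
  if (is.null(scan_labels)) scan_labels <- paste0("scan", seq_len(m))
  if (length(scan_labels) != m) stop("need one scan label per scan level")
  structure(list(probe_ids = as.character(probe_ids),
                 control_type = as.character(control_type),
                 intensities = intensities,
                 scan_labels = as.character(scan_labels),
                 pmt_settings = pmt_settings,
                 ceiling = ceiling),
            class = "scanset")
}

#' @export
print.scanset <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("scanset: %d probes x %d arrays x %d scans (ceiling %g)\n",
              d[1], d[2], d[3], x$ceiling))
  cat(sprintf("  %d negative controls; scans: %s\n",
              sum(x$control_type == "negative_control"),
              paste(x$scan_labels, collapse = " < ")))
  invisible(x)
}

#' Extract one array's raw intensity matrix (probe x scan)
#' @param x a [scanset()].
#' @param array array index.
#' @param scans scan indices (default all).
#' @return numeric matrix, probes x selected scans.
#' @export
scan_matrix <- function(x, array, scans = NULL) {
  stopifnot(inherits(x, "scanset"))
  if (is.null(scans)) scans <- seq_len(dim(x$intensities)[3])
  m <- x$intensities[, array, scans, drop = FALSE]
  matrix(m, nrow = dim(x$intensities)[1], ncol = length(scans),
         dimnames = list(x$probe_ids, x$scan_labels[scans]))
}

#' Extract one scan level across all arrays (probe x array)
#' @param x a [scanset()].
#' @param scan scan index (1 = lowest sensitivity).
#' @return numeric matrix, probes x arrays.
#' @export
scan_slice <- function(x, scan) {
  stopifnot(inherits(x, "scanset"))
  out <- x$intensities[, , scan, drop = FALSE]
  matrix(out, nrow = dim(x$intensities)[1], dimnames = list(x$probe_ids, NULL))
}

#' Read one array/scan probe-intensity table
#'
#' Reads a tab-delimited table with header columns `probe_id`, `control_type`
#' and `median_fg` (non-background-subtracted median foreground FLU), the
#' generic equivalent of an image-quantification export. Row order is
#' preserved; non-numeric or missing intensities and duplicate probe IDs are
#' rejected.
#'
#' @param path file path.
#' @param dialect table dialect; only `"generic_tsv"` is defined.
#' @return a data.frame with columns `probe_id`, `control_type`, `median_fg`.
#' @export
read_intensity_table <- function(path, dialect = c("generic_tsv")) {
  dialect <- match.arg(dialect)
  d <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("probe_id", "control_type", "median_fg")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$probe_id))
    stop("format error: duplicate probe ID: ",
         d$probe_id[duplicated(d$probe_id)][1])
  v <- suppressWarnings(as.numeric(d$median_fg))
  bad <- which(is.na(v) | !is.finite(v))
  if (length(bad))
    stop("format error: non-numeric intensity in row ", bad[1],
         " (probe ", d$probe_id[bad[1]], ", value '", d$median_fg[bad[1]], "')")
  data.frame(probe_id = d$probe_id, control_type = d$control_type,
             median_fg = v, stringsAsFactors = FALSE)
}

#' Write one array/scan probe-intensity table
#' @param slice a data.frame as returned by [read_intensity_table()].
#' @param path output path.
#' @export
write_intensity_table <- function(slice, path) {
  stopifnot(all(c("probe_id", "control_type", "median_fg") %in% names(slice)))
  utils::write.table(slice[, c("probe_id", "control_type", "median_fg")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble per-array, per-scan slices into a scanset
#'
#' Takes a list of arrays, each a list of single-scan slices, aligns probes
#' by ID against the first slice, and orders the scan axis by increasing
#' median intensity (averaged over arrays) rather than trusting input order:
#' PMT ranges can overlap between nominal settings, and the fusion algorithms
#' need the empirically ordered ladder.
#'
#' @param slices list (one element per array) of lists (one per scan) of
#'   slices from [read_intensity_table()].
#' @param expected_scans required number of scans per array (optional check).
#' @param ceiling detector ceiling.
#' @return a [scanset()].
#' @export
assemble_scanset <- function(slices, expected_scans = NULL, ceiling = 65535) {
  if (!length(slices)) stop("no arrays given")
  if (!is.list(slices[[1]])) slices <- list(slices)  # single array
  nscan <- unique(vapply(slices, length, 1L))
  if (length(nscan) != 1L)
    stop("alignment error: arrays have differing numbers of scans")
  if (!is.null(expected_scans) && nscan != expected_scans)
    stop("alignment error: expected ", expected_scans, " scans, found ", nscan)
  ref <- slices[[1]][[1]]
  ids <- ref$probe_id
  n <- length(ids); na <- length(slices)
  raw <- array(NA_real_, dim = c(n, na, nscan))
  for (a in seq_len(na)) {
    for (j in seq_len(nscan)) {
      s <- slices[[a]][[j]]
      if (!setequal(s$probe_id, ids)) {
        extra <- setdiff(s$probe_id, ids); missing <- setdiff(ids, s$probe_id)
        stop("alignment error: probe sets differ (array ", a, ", scan ", j,
             "): missing [", paste(utils::head(missing, 5), collapse = ", "),
             "], unexpected [", paste(utils::head(extra, 5), collapse = ", "), "]")
      }
      raw[, a, j] <- s$median_fg[match(ids, s$probe_id)]
    }
  }
  med <- apply(raw, 3, stats::median)
  ord <- order(med)
  raw <- raw[, , ord, drop = FALSE]
  scanset(raw, probe_ids = ids, control_type = ref$control_type,
          scan_labels = paste0("scan", seq_len(nscan)), ceiling = ceiling)
}
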