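# Region-wise normalized histograms of the index maps and the three summary
# metrics: median (from raw voxel values), peak location (modal bin center),
# peak height (maximal normalized frequency).

.default_hist_specs <- list(
  md = list(bin_width = 0.05e-3, range = c(0, 4e-3)),
  ad = list(bin_width = 0.05e-3, range = c(0, 4e-3)),
  rd = list(bin_width = 0.05e-3, range = c(0, 4e-3)),
  fa = list(bin_width = 0.03, range = c(0, 1)),
  mo = list(bin_width = 0.08, range = c(-1, 1))
)

#' Histogram binning specification for one index
#'
#' Bins are anchored at the range minimum, left-closed right-open, with the
#' last bin closed; the final bin may overshoot the range maximum when the
#' width does not divide the range. Defaults per index: bin width
#' 0.05x10^-3 mm^2/s on `[0, 4x10^-3]` for MD/AD/RD, 0.03 on `[0, 1]` for
#' FA, 0.08 on `[-1, 1]` for MO.
#'
#' @param index One of `"md"`, `"fa"`, `"ad"`, `"rd"`, `"mo"`.
#' @param bin_width,range Optional overrides.
#' @return Object of class `histogram_spec` with `bin_width`, `range`,
#'   `breaks`, `centers`.
#' @export
histogram_spec <- function(index, bin_width = NULL, range = NULL) {
  index <- match.arg(tolower(index), names(.default_hist_specs))
  def <- .default_hist_specs[[index]]
  bw <- if (is.null(bin_width)) def$bin_width else bin_width
  rg <- if (is.null(range)) def$range else range
  if (bw <= 0) stop("bin_width must be > 0")
  if (diff(rg) <= 0) stop("invalid range")
  n_bins <- ceiling(round(diff(rg) / bw, 9))
  breaks <- rg[1L] + bw * (0:n_bins)
  structure(list(index = index, bin_width = bw, range = rg,
                 breaks = breaks, centers = breaks[-1L] - bw / 2),
            class = "histogram_spec")
}

#' Build a normalized region histogram
#'
#' Counts valid in-mask voxels into the spec's bins (left-closed right-open,
#' last bin closed) and normalizes by the number counted, so frequencies sum
#' to one regardless of region size. Out-of-range voxels are excluded and
#' tallied; more than 5% out of range is an error (misconfigured range).
#'
#' @param index_map 3-D map (or numeric vector of in-mask values).
#' @param mask [region_mask()] / logical array; ignored for vector input.
#' @param validity Logical array of per-voxel validity (optional).
#' @param spec A [histogram_spec()].
#' @return Object of class `dti_histogram`: `centers`, `freq`, `counts`,
#'   `n_counted`, `n_excluded`, `values` (the raw in-mask values counted).
#' @export
build_histogram <- function(index_map, mask = NULL, validity = NULL, spec) {
  if (!inherits(spec, "histogram_spec")) stop("spec must be a histogram_spec")
  if (is.array(index_map) && length(dim(index_map)) == 3L) {
    keep <- .as_mask_array(mask, dim(index_map))
    if (!is.null(validity)) keep <- keep & validity
    vals <- index_map[keep]
  } else {
    vals <- as.numeric(index_map)
  }
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop("empty effective mask: no valid voxels to histogram")

  inr <- vals >= spec$range[1L] & vals <= spec$breaks[length(spec$breaks)]
  n_excluded <- sum(!inr)
  if (n_excluded / length(vals) > 0.05)
    stop(sprintf("%.1f%% of voxels fall outside the histogram range: range misconfigured",
                 100 * n_excluded / length(vals)))
  v <- vals[inr]
  k <- pmin(floor((v - spec$range[1L]) / spec$bin_width) + 1L,
            length(spec$centers))                      # last bin closed
  counts <- tabulate(k, nbins = length(spec$centers))
  structure(list(centers = spec$centers, freq = counts / length(v),
                 counts = counts, n_counted = length(v), n_excluded = n_excluded,
                 values = v, spec = spec),
            class = "dti_histogram")
}

#' Histogram metrics: median, peak location, peak height
#'
#' The median is computed from the raw counted voxel values (midpoint of the
#' two central order statistics for even n), not from binned counts. The peak
#' location is the center of the bin with maximal normalized frequency (ties
#' broken toward the lowest bin center) and the peak height is that maximal
#' frequency.
#'
#' @param histogram A [build_histogram()] result.
#' @return List with `median`, `peak_location`, `peak_height`, `n`.
#' @export
compute_metrics <- function(histogram) {
  if (!inherits(histogram, "dti_histogram")) stop("histogram must come from build_histogram()")
  if (histogram$n_counted == 0L) stop("no counted voxels")
  pk <- which.max(histogram$freq)   # first maximum = lowest bin center on ties
  list(median = stats::median(histogram$values),
       peak_location = histogram$centers[pk],
       peak_height = histogram$freq[pk],
       n = histogram$n_counted)
}

#' Per-region, per-index histogram metrics table
#'
#' Produces the 2 regions x 5 indices x 3 metrics = 30 values that summarize
#' one subject/timepoint. Values are in native units (diffusivities mm^2/s);
#' report formatting scales them by 10^3.
#'
#' @param index_maps An `index_maps` object (3-D maps).
#' @param masks Named list of [region_mask()] objects.
#' @param specs Optional named list of [histogram_spec()] overrides.
#' @return data.frame with columns `region`, `index`, `metric`, `value`, `n`.
#' @export
region_metrics_table <- function(index_maps, masks, specs = NULL) {
  idx_names <- c("md", "fa", "ad", "rd", "mo")
  if (!all(idx_names %in% names(index_maps)))
    stop("index_maps must contain md/fa/ad/rd/mo")
  rows <- list()
  for (rg in names(masks)) {
    if (!inherits(masks[[rg]], "region_mask")) next
    for (ix in idx_names) {
      spec <- if (!is.null(specs[[ix]])) specs[[ix]] else histogram_spec(ix)
      h <- build_histogram(index_maps[[ix]], masks[[rg]], index_maps$valid, spec)
      m <- compute_metrics(h)
      rows[[length(rows) + 1L]] <- data.frame(
        region = masks[[rg]]$label, index = ix,
        metric = c("median", "peak_location", "peak_height"),
        value = c(m$median, m$peak_location, m$peak_height),
        n = m$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
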