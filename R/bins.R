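#' Aerodynamic-diameter size bins
#'
#' Construct an ordered grid of aerodynamic-diameter bins. The grid is the
#' coordinate system for every size-resolved profile in the package:
#' concentration profiles, loss-rate tables, emission profiles and taxa
#' abundance tables are all defined per bin and must share an identical grid
#' before they can be combined.
#'
#' Bin edges are in micrometres of aerodynamic diameter (the diameter of a
#' unit-density sphere with the same settling velocity), the size coordinate
#' of cascade-impactor stages. Bins are half-open `[d_lo, d_hi)`, must be
#' strictly ordered and must not overlap; edges are matched exactly across
#' tables, never joined with a tolerance.
#'
#' @param d_lo_um,d_hi_um Numeric vectors of lower/upper bin edges, um.
#' @return A data frame of class `size_bins` with columns `d_lo_um`, `d_hi_um`.
#' @examples
#' size_bins(c(0.4, 1.1), c(1.1, 2.1))
#' @seealso [impactor_bins()] for the default six-stage grid.
#' @export
size_bins <- function(d_lo_um, d_hi_um) {
  if (length(d_lo_um) != length(d_hi_um)) {
    stop("d_lo_um and d_hi_um must have the same length", call. = FALSE)
  }
  if (length(d_lo_um) == 0L) stop("empty bin grid", call. = FALSE)
  if (!is.numeric(d_lo_um) || !is.numeric(d_hi_um) ||
      any(!is.finite(d_lo_um)) || any(!is.finite(d_hi_um))) {
    stop("bin edges must be finite numbers", call. = FALSE)
  }
  if (any(d_lo_um <= 0)) stop("bin lower edges must be positive", call. = FALSE)
  if (any(d_hi_um <= d_lo_um)) {
    bad <- which(d_hi_um <= d_lo_um)
    stop("bin upper edge must exceed lower edge (bin ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  o <- order(d_lo_um)
  d_lo_um <- d_lo_um[o]; d_hi_um <- d_hi_um[o]
  if (length(d_lo_um) > 1L) {
    overlap <- which(d_lo_um[-1L] < d_hi_um[-length(d_hi_um)] - 1e-12)
    if (length(overlap)) {
      stop("overlapping bins at rows ",
           paste(overlap, overlap + 1L, sep = "-", collapse = ", "),
           call. = FALSE)
    }
  }
  structure(data.frame(d_lo_um = d_lo_um, d_hi_um = d_hi_um),
            class = c("size_bins", "data.frame"))
}

#' Default six-stage impactor bin grid
#'
#' The six aerodynamic-diameter bins of a non-viable cascade impactor with
#' nominal cut-points 0.4, 1.1, 2.1, 3.3, 4.7 and 9.0 um. The top stage has no
#' sharp physical upper cut; a 20 um cap is assumed, justified by the rapid
#' gravitational removal of larger particles from well-mixed room air. The
#' sensitivity of results to this cap is quantified by
#' [upper_limit_sensitivity()].
#'
#' @param top_cap_um Assumed upper limit of the largest stage, um.
#' @return A [size_bins()] grid with six bins.
#' @export
impactor_bins <- function(top_cap_um = 20) {
  size_bins(c(0.4, 1.1, 2.1, 3.3, 4.7, 9.0),
            c(1.1, 2.1, 3.3, 4.7, 9.0, top_cap_um))
}

#' Decadal-log bin widths
#'
#' @param bins A [size_bins()] grid.
#' @return Numeric vector `log10(d_hi/d_lo)` per bin.
#' @export
dlog_width <- function(bins) {
  bins <- as_size_bins(bins)
  log10(bins$d_hi_um / bins$d_lo_um)
}

#' @export
format.size_bins <- function(x, ...) {
  paste0("[", format(x$d_lo_um), ", ", format(x$d_hi_um), ") um")
}

as_size_bins <- function(x) {
  if (inherits(x, "size_bins") && identical(names(x), c("d_lo_um", "d_hi_um"))) {
    return(x)
  }
  if (is.data.frame(x) && all(c("d_lo_um", "d_hi_um") %in% names(x))) {
    return(size_bins(x$d_lo_um, x$d_hi_um))
  }
  stop("expected a size_bins grid (columns d_lo_um, d_hi_um)", call. = FALSE)
}

n_bins <- function(bins) nrow(as_size_bins(bins))

# Exact-edge grid equality; mismatched grids are an error, never interpolated.
same_bins <- function(a, b) {
  a <- as_size_bins(a); b <- as_size_bins(b)
  nrow(a) == nrow(b) &&
    all(a$d_lo_um == b$d_lo_um) && all(a$d_hi_um == b$d_hi_um)
}

stop_if_bins_differ <- function(a, b, what = "inputs") {
  if (!same_bins(a, b)) {
    stop(what, " are on different size-bin grids; edges must match exactly",
         call. = FALSE)
  }
  invisible(TRUE)
}

bin_labels <- function(bins) {
  bins <- as_size_bins(bins)
  sprintf("%g-%g um", bins$d_lo_um, bins$d_hi_um)
}
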