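#' Build the gridded intrinsic-growth-rate (r_i) map
#'
#' Evaluates the fitted thermal growth curve on a mean-annual-temperature
#' raster and multiplies by the binary suitability raster, so cells outside
#' the suitability prediction get r_i = 0 while remaining in the simulation
#' grid. The growth curve itself is strictly positive at any temperature, so
#' the suitability mask is the sole zeroing mechanism. Inputs must share the
#' grid exactly; no resampling is performed.
#'
#' @param model fitted `growth_model`.
#' @param temperature `grid_raster` of mean annual temperature, °C.
#' @param suitability binary `grid_raster` (values 0/1, NoData allowed).
#' @param region optional logical matrix (same dims) or `grid_raster`;
#'   cells outside the region become NoData.
#' @return `grid_raster` of r_i (per day); NoData where either input is
#'   NoData or outside `region`.
#' @export
build_r_map <- function(model, temperature, suitability, region = NULL) {
  stopifnot(inherits(model, "growth_model"))
  stop_if_misaligned(temperature, suitability,
                     "temperature and suitability rasters")
  sv <- suitability$values
  bad <- is.finite(sv) & !(sv %in% c(0, 1))
  if (any(bad)) stop("suitability raster must be binary (0/1/NoData)")
  r <- evaluate_growth(model, temperature$values) * sv
  if (!is.null(region)) {
    if (inherits(region, "grid_raster")) {
      stop_if_misaligned(temperature, region, "temperature and region rasters")
      region <- is.finite(region$values) & region$values > 0
    }
    stopifnot(identical(dim(region), dim(r)))
    r[!region] <- NA_real_
  }
  grid_raster(r, temperature$xll, temperature$yll,
              temperature$cellsize, temperature$crs)
}
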