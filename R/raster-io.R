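#' Write a landscape to TIFF rasters with a JSON sidecar
#'
#' Writes `cover.tif`, `biomass.tif` and `distance.tif` (where present) as
#' 32-bit float TIFFs. TIFF float samples are stored on a [0, 1] scale, so
#' each layer is divided by a per-layer scale factor recorded, together
#' with resolution, origin, forest threshold and any generative truth, in
#' `landscape.json`; [read_landscape()] restores the original values.
#' `NA` pixels (non-forest) are stored as 0 and re-masked on read using the
#' cover layer and the forest threshold.
#'
#' @param landscape A `"forest_landscape"`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layers <- list(cover = landscape$cover, biomass = landscape$biomass,
                 distance = landscape$distance)
  layers <- Filter(Negate(is.null), layers)
  scales <- lapply(layers, function(m) {
    v <- m[is.finite(m)]
    max(1, if (length(v)) max(v) else 1)
  })
  for (nm in names(layers)) {
    m <- layers[[nm]] / scales[[nm]]
    m[!is.finite(m)] <- 0
    tiff::writeTIFF(m, file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 32, reduce = FALSE)
  }
  meta <- list(scales = scales, resolution = landscape$resolution,
               origin = landscape$origin, threshold = landscape$threshold,
               clipped_pixels = landscape$clipped_pixels,
               truth = if (!is.null(landscape$truth))
                 unclass(landscape$truth))
  jsonlite::write_json(meta, file.path(dir, "landscape.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a landscape written by [write_landscape()]
#'
#' @param dir Directory containing the TIFFs and `landscape.json`.
#' @return A `"forest_landscape"` object.
#' @export
read_landscape <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "landscape.json"),
                              simplifyVector = TRUE)
  layer <- function(nm) {
    f <- file.path(dir, paste0(nm, ".tif"))
    if (!file.exists(f)) return(NULL)
    m <- tiff::readTIFF(f)
    matrix(as.numeric(m) * meta$scales[[nm]], nrow = nrow(m))
  }
  cover <- layer("cover")
  mask <- cover >= meta$threshold
  remask <- function(m) {
    if (!is.null(m)) m[!mask] <- NA_real_
    m
  }
  ls <- structure(list(cover = cover, biomass = remask(layer("biomass")),
                       distance = remask(layer("distance")),
                       resolution = meta$resolution,
                       origin = meta$origin, threshold = meta$threshold,
                       clipped_pixels = meta$clipped_pixels),
                  class = "forest_landscape")
  if (!is.null(meta$truth))
    ls$truth <- do.call(landscape_truth, meta$truth)
  ls
}
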