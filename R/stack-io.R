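# Stack serialization: multi-page TIFF + JSON sidecar with acquisition
# metadata. The sidecar wins over TIFF resolution tags on conflict.

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write a speckle stack to disk
#'
#' Pixel data go to a multi-page TIFF (32-bit float by default, 16-bit when
#' the images are small-integer valued), metadata to a JSON sidecar next to
#' it (`<stem>.json`).
#'
#' @param stack a [speckle_stack()]
#' @param path TIFF file path
#' @param bits sample depth; default picks 16-bit for integer-valued stacks
#' @return `path`, invisibly
#' @export
write_stack <- function(stack, path, bits = NULL) {
  stopifnot(inherits(stack, "speckle_stack"))
  g <- stack$grid
  if (is.null(bits)) {
    intish <- all(stack$images == round(stack$images)) &&
      max(stack$images) < 65536 && min(stack$images) >= 0
    bits <- if (intish) 16L else 32L
  }
  write_tiff(stack$images, path, bits = bits,
             dx = if (!is.null(g)) g$dx else 1,
             dy = if (!is.null(g)) g$dy else 1)
  meta <- list(modality = stack$modality, z_f = stack$z_f,
               photon_budget = stack$photon_budget, seeds = stack$seeds,
               scale = stack$scale, optics = stack$optics,
               grid = if (!is.null(g)) unclass(g) else NULL)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a speckle stack from disk
#'
#' Restores pixel data and sidecar metadata. A missing sidecar is tolerated:
#' the stack loads with modality `"unknown"` and a warning.
#'
#' @param path TIFF file path
#' @return a [speckle_stack()]
#' @export
read_stack <- function(path) {
  images <- read_tiff(path)
  side <- sidecar_path(path)
  if (!file.exists(side)) {
    warning("no metadata sidecar found for ", path,
            "; loading with modality 'unknown'", call. = FALSE)
    g <- NULL
    dx <- attr(images, "dx_nm")
    if (!is.na(dx))
      g <- grid_geometry(dim(images)[1], dim(images)[2], 1L,
                         dx = dx, dy = attr(images, "dy_nm"))
    return(speckle_stack(unname_attrs(images), modality = "unknown", grid = g))
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  g <- if (!is.null(meta$grid))
    grid_geometry(meta$grid$nx, meta$grid$ny, meta$grid$nz,
                  meta$grid$dx, meta$grid$dy, meta$grid$dz) else NULL
  speckle_stack(unname_attrs(images),
                modality = if (is.null(meta$modality)) "unknown" else meta$modality,
                z_f = meta$z_f, photon_budget = meta$photon_budget,
                seeds = meta$seeds, scale = if (is.null(meta$scale)) 1 else meta$scale,
                optics = as.list(meta$optics), grid = g)
}

unname_attrs <- function(x) {
  attr(x, "dx_nm") <- NULL
  attr(x, "dy_nm") <- NULL
  x
}

#' Write / read a height map (nm) as single-page 32-bit TIFF
#'
#' @param heightmap nx x ny matrix in nm
#' @param path file path
#' @param grid optional [grid_geometry()] for the resolution tags
#' @return `path` (write) / matrix (read)
#' @export
write_heightmap <- function(heightmap, path, grid = NULL) {
  write_tiff(heightmap, path, bits = 32L,
             dx = if (!is.null(grid)) grid$dx else 1,
             dy = if (!is.null(grid)) grid$dy else 1)
}

#' @rdname write_heightmap
#' @export
read_heightmap <- function(path) {
  x <- read_tiff(path)
  x[, , 1]
}
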