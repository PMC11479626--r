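#' Voxel grid geometry
#'
#' Describes the simulation/reconstruction grid: voxel counts and physical
#' pitches in nanometres. The reference simulation grid is 512 x 512 x 128
#' voxels at dx = dy = 38.5 nm, dz = 87.5 nm; [grid_paper()] and
#' [grid_desk()] build that grid and a smaller desk-scale variant.
#'
#' @param nx,ny,nz voxel counts (>= 1)
#' @param dx,dy lateral voxel pitch in nm (> 0)
#' @param dz axial voxel pitch in nm (> 0)
#' @return an object of class `grid_geometry`
#' @examples
#' g <- grid_geometry(128, 128, 32, dx = 38.5, dz = 87.5)
#' g$nx
#' @export
grid_geometry <- function(nx, ny = nx, nz = 1L, dx = 38.5, dy = dx, dz = 87.5) {
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  stopifnot(nx >= 1L, ny >= 1L, nz >= 1L, dx > 0, dy > 0, dz > 0)
  structure(list(nx = nx, ny = ny, nz = nz, dx = dx, dy = dy, dz = dz),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d x %d voxels, dx=%g dy=%g dz=%g nm\n",
              x$nx, x$ny, x$nz, x$dx, x$dy, x$dz))
  invisible(x)
}

#' @rdname grid_geometry
#' @export
grid_paper <- function() grid_geometry(512L, 512L, 128L, dx = 38.5, dz = 87.5)

#' @rdname grid_geometry
#' @param nz number of axial slices for the desk grid
#' @export
grid_desk <- function(nz = 32L) grid_geometry(128L, 128L, nz, dx = 38.5, dz = 87.5)

# Axial slice offsets (nm), centered on focus: slice floor(nz/2)+1 is z = 0.
grid_z_offsets <- function(grid) centered_coords(grid$nz, grid$dz)

# z-range spanned by the slice centers, as [min, max].
grid_z_range <- function(grid) range(grid_z_offsets(grid))

# Check that a lateral grid can hold the super-resolved band of a pupil:
# the reconstruction carries frequencies up to 4 NA / lambda, which needs
# dx <= lambda / (8 NA). Warn (not error) when only the widefield band fits.
check_nyquist <- function(grid, na, wavelength) {
  d <- max(grid$dx, grid$dy)
  if (d >= wavelength / (2 * na))
    stop("lateral pitch ", d, " nm cannot represent the pupil cutoff NA/lambda; ",
         "need dx < lambda/(2 NA) = ", signif(wavelength / (2 * na), 4), " nm")
  if (d > wavelength / (8 * na))
    warning("lateral pitch ", d, " nm exceeds lambda/(8 NA) = ",
            signif(wavelength / (8 * na), 4),
            " nm; grid is not Nyquist for the super-resolved band", call. = FALSE)
  invisible(TRUE)
}
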