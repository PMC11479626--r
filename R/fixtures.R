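# Simulation presets and fixture generation.

#' Simulation presets
#'
#' `paper_full` is the reference simulation geometry: a 512 x 512 x 128 grid
#' at dx = dy = 38.5 nm, dz = 87.5 nm, in-medium wavelength 530/1.3 nm and
#' NA 0.8. `desk_small` keeps the pitches and optics but shrinks the grid to
#' 128 x 128 x 32 so the whole pipeline runs in seconds to minutes on one
#' CPU.
#'
#' @param preset `"desk_small"` or `"paper_full"`
#' @return a named list: `grid`, `na`, `wavelength_nm`, `n_lobes`,
#'   `n_speckles`, `photon_budget`
#' @export
preset_config <- function(preset = c("desk_small", "paper_full")) {
  preset <- match.arg(preset)
  if (preset == "paper_full")
    list(preset = preset, grid = grid_paper(), na = 0.8,
         wavelength_nm = 530 / 1.3, n_lobes = 40L, n_speckles = 100L,
         photon_budget = 1000)
  else
    list(preset = preset, grid = grid_desk(), na = 0.8,
         wavelength_nm = 530 / 1.3, n_lobes = 40L, n_speckles = 100L,
         photon_budget = 1000)
}

#' Generate the standard fixture set
#'
#' Writes, under `out_dir`: the star phantom, the three topography height
#' maps, a focal-slice speckle ensemble, an EDF acquisition stack of the
#' flat-topography star, and the effective configuration as JSON. Everything
#' is deterministic given `seed`.
#'
#' @param preset `"desk_small"` or `"paper_full"`
#' @param out_dir output directory (created if missing)
#' @param seed master integer seed
#' @param n_speckles override the preset's stack size
#' @return named character vector of the files written, invisibly
#' @export
make_fixtures <- function(preset = c("desk_small", "paper_full"), out_dir,
                          seed = 1L, n_speckles = NULL) {
  cfg <- preset_config(match.arg(preset))
  if (!is.null(n_speckles)) cfg$n_speckles <- as.integer(n_speckles)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- cfg$grid
  pupil <- make_pupil(cfg$na, cfg$wavelength_nm, g)
  star <- make_star_density(g, cfg$n_lobes)
  files <- c(star = file.path(out_dir, "star.tif"))
  write_tiff(star, files["star"], dx = g$dx, dy = g$dy)
  for (kind in c("flat", "cone", "random")) {
    z <- make_topography(g, kind, seed = seed)
    f <- file.path(out_dir, paste0("topo_", kind, ".tif"))
    write_heightmap(z, f, g)
    files[paste0("topo_", kind)] <- f
  }
  set.seed(as.integer(seed))
  ens_seeds <- sample.int(.Machine$integer.max - 1L, 16L)
  ens <- vapply(ens_seeds, function(s)
    generate_speckle(pupil, g, seed = s, z_offsets = 0)[, , 1],
    matrix(0, g$nx, g$ny))
  files["speckles"] <- file.path(out_dir, "speckles_focal.tif")
  write_tiff(ens, files["speckles"], dx = g$dx, dy = g$dy)

  sample_v <- embed_on_surface(star, make_topography(g, "flat"), g)
  stack <- simulate_acquisition(sample_v, pupil, n_speckles = cfg$n_speckles,
                                photon_budget = cfg$photon_budget,
                                modality = "edf", seed = seed)
  files["stack"] <- file.path(out_dir, "stack_flat.tif")
  write_stack(stack, files["stack"])
  files["config"] <- file.path(out_dir, "config.json")
  jsonlite::write_json(c(cfg[setdiff(names(cfg), "grid")],
                         list(grid = unclass(cfg$grid), seed = seed)),
                       files["config"], auto_unbox = TRUE, digits = NA)
  invisible(files)
}
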