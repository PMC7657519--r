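# Shared small fixtures, built once per test run. Grid sizes are kept small
# (96-128 px) so the whole suite stays fast; geometry is otherwise the
# default antral phantom.

quiet_wave <- function() wave_config(occlusion_frac = 0, active = FALSE)

no_resp <- function() respiration_config(amplitude_mm = 0)

clean_phantom <- function(grid = 96, n_frames = 60)
  phantom_config(grid_size = grid, n_frames = n_frames,
                 noise_sd = 0, texture_amp = 0)

# one noise-free contracting block, reused by several oracle tests
.clean_block <- generate_cine(clean_phantom(128), wave_config(occlusion_frac = 0.5),
                              no_resp(), seed = 101)

# same wave rendered with realistic noise, texture and breathing
.noisy_block <- generate_cine(phantom_config(grid_size = 128),
                              wave_config(occlusion_frac = 0.5),
                              respiration_config(), seed = 102)

# brute-force, sample-free oracle: count lumen pixels (>= half level between
# wall and lumen grey) along the 1-px-stepped perpendicular through a node
pixel_count_diameter <- function(img, node, phantom, step_frac = 1) {
  lev <- (phantom$intensities[["lumen"]] + phantom$intensities[["wall"]]) / 2
  n <- nrow(img)
  offs <- seq(-30, 30, by = step_frac * phantom$pixel_mm)
  xs <- (node$x_mm + offs * node$nx) / phantom$pixel_mm + (n + 1) / 2
  ys <- (node$y_mm + offs * node$ny) / phantom$pixel_mm + (n + 1) / 2
  ok <- xs >= 1 & xs <= n & ys >= 1 & ys <= n
  vals <- img[cbind(round(xs[ok]), round(ys[ok]))]
  sum(vals >= lev) * step_frac * phantom$pixel_mm
}
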