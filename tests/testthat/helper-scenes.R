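# Shared fixture builders: a cell scene with an added fibrous SHG layer so
# every channel carries signal.

combined_frame <- function(size = 120, pixel_size_um = 0.5, n_cells = 3,
                           orr = c(0.7, 0.8, 0.9), droplets = 2,
                           scene_seed = 4) {
  sc <- generate_cell_scene(cell_scene(image_size_px = size,
                                       pixel_size_um = pixel_size_um,
                                       n_cells = n_cells, orr_targets = orr,
                                       n_lipid_droplets = droplets,
                                       seed = scene_seed))
  fib <- generate_fiber_image(
    fiber_scene(image_size_px = size, pixel_size_um = pixel_size_um,
                n_fibers = 15, fiber_length_um = size * pixel_size_um / 3,
                seed = scene_seed))
  ch <- sc$frame$channels
  ch$SHG <- fib$shg * 80
  list(frame = multimodal_frame(ch, pixel_size_um,
                                frame_id = sc$frame$frame_id),
       scene = sc)
}
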