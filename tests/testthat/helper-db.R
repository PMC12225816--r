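# one curated database instance shared by the whole suite
DB <- spsd_db("curated")

get_record <- function(key) {
  DB$segments[spsd:::.resolve_key(DB, key), , drop = FALSE]
}

# stamp a single rod into an all-marrow box phantom (controlled-geometry
# oracle for the morphometry tests)
single_rod_phantom <- function(axis, diameter, length, box = 10, vox = 0.1) {
  ph <- voxelize_shape(shape_spec("box", box, box, box), vox)
  lab <- ph$labels
  axis <- axis / sqrt(sum(axis^2))
  rods <- matrix(c(0, 0, box / 2, axis, diameter / 2, length / 2), nrow = 1)
  spsd:::cpp_stamp_rods(lab, dim(lab), vox, ph$origin, rods, Inf)
  ph$labels <- lab
  ph
}
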