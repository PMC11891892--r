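.onLoad <- function(libname, pkgname) {
  register_shape_backend("grid_overlap", grid_overlap_score)
}
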