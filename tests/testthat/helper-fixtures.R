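# Shared fixtures, built once per test run.

# spectrum calibrated to the 9.4 mm Al beam-quality target
cached_spectrum <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- calibrate_inherent_filtration(9.4)$spectrum
    s
  }
})

# coarse synthetic abdomen with materials assigned and an arc beam set
coarse_case <- local({
  cache <- list()
  function(concentration = 50, voxel_mm = 4.5, seed = 1) {
    key <- paste(concentration, voxel_mm, seed, sep = "_")
    if (is.null(cache[[key]])) {
      ab <- build_synthetic_abdomen(
        abdomen_params(voxel_mm = voxel_mm, concentration = concentration),
        seed = seed)
      ph <- assign_materials(ab$phantom, ab$structures,
                             lipiodol_material(concentration))
      beams <- make_arc_plan(ph, ab$structures, plan_spec(),
                             scanner_geometry(), cached_spectrum())
      cache[[key]] <<- list(phantom = ph, structures = ab$structures,
                            beams = beams)
    }
    cache[[key]]
  }
})

# water slab with a full-face parallel beam (oracle geometry)
water_slab <- function(thickness_cm, n_depth, lateral_cm = 20,
                       n_lateral = 2) {
  kvcert:::slab_phantom(
    list(list(material = standard_material("water"),
              thickness_cm = thickness_cm)),
    lateral_cm = lateral_cm, n_depth = n_depth, n_lateral = n_lateral)
}

full_face_beam <- function(lateral_cm = 20) {
  beam_spec(c(0, 0, 0), c(0, 1, 0), lateral_cm / 2, lateral_cm / 2,
            parallel = TRUE)
}
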