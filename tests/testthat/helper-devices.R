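# Shared builders for device tests: coarse meshes keep unit tests fast;
# the acceptance suite uses the full study mesh.

small_device <- function(nx = 101, ny = 7, ...) {
  build_device(device_spec(mesh_nx = nx, mesh_ny = ny, ...))
}

# electron/hole-symmetric parameters for ambipolar mirror checks
symmetric_materials <- function() {
  material_params(electron_mobility = 1000, hole_mobility = 1000,
                  effective_mass_e = 1, effective_mass_h = 1,
                  tunneling_mass_e = 0.19, tunneling_mass_h = 0.19)
}

# flat-top barrier: thermionic-dominated (sub-barrier WKB negligible)
plateau_barrier <- function(height = 0.30, plateau = 250, total = 300,
                            n = 150) {
  x <- seq(0, total, length.out = n)
  list(x = x, energy = ifelse(x <= plateau, height,
                              height * (total - x) / (total - plateau)))
}
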