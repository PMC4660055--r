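# Idealized base geometries in the base-pair standard reference frame
# (origin at the pair centre, x toward the major groove, y along the
# pseudo-dyad toward strand 1, z along the helix axis). Heavy-atom
# coordinates follow the conventional standard-frame layout; they are
# idealized values adequate for frame fitting and duplex construction,
# and the builder and the frame-fitting code share them, so
# build/measure round trips are exact by construction.

.base_templates <- list(
  A = rbind(
    `C1'` = c(-2.479, 5.346, 0.000),
    N9 = c(-1.291, 4.498, 0.000), C8 = c(0.024, 4.897, 0.000),
    N7 = c(0.877, 3.902, 0.000), C5 = c(0.071, 2.771, 0.000),
    C6 = c(0.369, 1.398, 0.000), N6 = c(1.611, 0.909, 0.000),
    N1 = c(-0.668, 0.532, 0.000), C2 = c(-1.912, 1.023, 0.000),
    N3 = c(-2.320, 2.290, 0.000), C4 = c(-1.267, 3.124, 0.000)
  ),
  G = rbind(
    `C1'` = c(-2.477, 5.399, 0.000),
    N9 = c(-1.289, 4.551, 0.000), C8 = c(0.023, 4.962, 0.000),
    N7 = c(0.870, 3.969, 0.000), C5 = c(0.071, 2.833, 0.000),
    C6 = c(0.424, 1.460, 0.000), O6 = c(1.554, 0.955, 0.000),
    N1 = c(-0.700, 0.641, 0.000), C2 = c(-1.999, 1.087, 0.000),
    N2 = c(-2.949, 0.139, 0.000), N3 = c(-2.342, 2.364, 0.000),
    C4 = c(-1.265, 3.177, 0.000)
  ),
  C = rbind(
    `C1'` = c(-2.477, 5.402, 0.000),
    N1 = c(-1.285, 4.542, 0.000), C2 = c(-1.472, 3.158, 0.000),
    O2 = c(-2.628, 2.709, 0.000), N3 = c(-0.391, 2.344, 0.000),
    C4 = c(0.837, 2.868, 0.000), N4 = c(1.875, 2.027, 0.000),
    C5 = c(1.056, 4.275, 0.000), C6 = c(-0.023, 5.068, 0.000)
  ),
  T = rbind(
    `C1'` = c(-2.481, 5.354, 0.000),
    N1 = c(-1.284, 4.500, 0.000), C2 = c(-1.462, 3.135, 0.000),
    O2 = c(-2.562, 2.608, 0.000), N3 = c(-0.298, 2.407, 0.000),
    C4 = c(0.994, 2.897, 0.000), O4 = c(1.944, 2.119, 0.000),
    C5 = c(1.106, 4.338, 0.000), C7 = c(2.466, 4.961, 0.000),
    C6 = c(-0.024, 5.057, 0.000)
  )
)

# ring atoms used for least-squares frame fitting (planar, rigid part)
.base_ring_atoms <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  T = c("N1", "C2", "N3", "C4", "C5", "C6")
)

.complement <- c(A = "T", T = "A", G = "C", C = "G")

# Backbone phosphate placement relative to the pair frame, cylindrical
# (radius, azimuth from +x toward +y, axial offset). Calibrated so an
# ideal duplex at canonical B-form rise/twist reads a raw cross-strand
# P-P minor groove of about 11.6 A.
.phosphate_geometry <- c(radius = 9.0, azimuth_deg = 95, z_offset = 2.0)

.pdb_base <- function(res_name) {
  code <- sub("^D", "", toupper(res_name))
  if (!code %in% names(.base_templates)) {
    return(NA_character_)
  }
  code
}
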