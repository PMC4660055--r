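test_that("PDB records parse, separate chains and round-trip at PDB precision", {
  d <- build_ideal_bdna("ATGCATGC")
  atoms <- duplex_to_atoms(d)
  tmp <- tempfile(fileext = ".pdb")
  write_pdb(atoms, tmp)
  back <- read_pdb(tmp)
  expect_equal(nrow(back), nrow(atoms))
  expect_setequal(unique(back$chain), c("C", "D"))
  expect_equal(back$x, atoms$x, tolerance = 5e-4)
  expect_equal(back$z, atoms$z, tolerance = 5e-4)

  one <- read_pdb("ATOM      1  P   DA  C   2       1.000   2.000   3.000")
  expect_equal(nrow(one), 1L)
  expect_equal(one$y, 2)
  expect_equal(one$element, "P")

  bad <- "ATOM      1  P   DA  C   2       1.0x0   2.000   3.000"
  expect_error(read_pdb(bad), "line 1")
  ins <- "ATOM      1  P   DA  C   2A      1.000   2.000   3.000"
  expect_error(read_pdb(ins), "insertion")
  expect_error(read_pdb("REMARK nothing"), "no ATOM")
})

test_that("ideal duplex construction has the prescribed geometry", {
  n <- 25
  d <- build_ideal_bdna(strrep("ATGCG", 5), rise = 3.32, twist = 36)
  expect_equal(d$n_pairs, n)
  fr <- base_pair_frames(d)
  orig <- t(vapply(fr, `[[`, numeric(3), "origin"))
  # frame origins collinear along the helix axis, end-to-end 24 * rise
  expect_equal(sqrt(sum((orig[n, ] - orig[1, ])^2)), 24 * 3.32, tolerance = 1e-6)
  expect_lt(max(abs(orig[, 1:2])), 1e-6)
  # 36 degrees: pairs i and i+10 related by pure translation
  a <- d$atoms
  p1 <- a[a$pair == 3 & a$atom_name != "P", c("x", "y", "z")]
  p2 <- a[a$pair == 13 & a$atom_name != "P", c("x", "y", "z")]
  shift <- as.matrix(p2) - as.matrix(p1)
  expect_lt(max(abs(sweep(shift, 2, c(0, 0, 10 * 3.32)))), 1e-9)
  expect_error(build_ideal_bdna("AXG"), "invalid base")
  expect_error(build_ideal_bdna("A"), ">= 2")
})

test_that("step parameters round-trip the builder's rise and twist", {
  d <- build_ideal_bdna(strrep("ATGCG", 5), rise = 3.32, twist = 36)
  sp <- step_parameters(base_pair_frames(d))
  expect_equal(attr(sp, "mean_twist"), 36, tolerance = 0.01)
  expect_equal(attr(sp, "mean_rise"), 3.32, tolerance = 0.01)

  d30 <- build_ideal_bdna("ATGCATGCATGC", rise = 3.4, twist = 30)
  sp30 <- step_parameters(base_pair_frames(d30))
  expect_equal(attr(sp30, "mean_twist"), 30, tolerance = 0.01)

  # property: exact round trip across the B-form neighbourhood
  set.seed(21)
  for (i in 1:5) {
    rise <- runif(1, 2.5, 4)
    twist <- runif(1, 25, 40)
    dd <- build_ideal_bdna("GCGCGCGCGC", rise = rise, twist = twist)
    spp <- step_parameters(base_pair_frames(dd))
    expect_equal(attr(spp, "mean_twist"), twist, tolerance = 0.01)
    expect_equal(attr(spp, "mean_rise"), rise, tolerance = 0.01)
  }

  # reversing the duplex direction preserves the magnitudes
  fr <- base_pair_frames(d)
  spr <- step_parameters(rev(fr))
  expect_equal(abs(spr$twist), rev(abs(sp$twist)), tolerance = 1e-6)
  expect_equal(abs(spr$rise), rev(abs(sp$rise)), tolerance = 1e-6)
  expect_error(step_parameters(fr[1]), ">= 2")
})

test_that("geometry is invariant under rigid-body motion", {
  set.seed(33)
  d <- build_ideal_bdna("ATGCATGCATGCATGC", rise = 3.32, twist = 36)
  sp0 <- step_parameters(base_pair_frames(d))
  gw0 <- minor_groove_widths(d)
  for (i in 1:3) {
    R <- random_rotation()
    tr <- rnorm(3, 0, 20)
    dm <- transform_duplex(d, R, tr)
    sp <- step_parameters(base_pair_frames(dm))
    expect_equal(sp$twist, sp0$twist, tolerance = 1e-8)
    expect_equal(sp$rise, sp0$rise, tolerance = 1e-8)
    expect_equal(minor_groove_widths(dm)$width, gw0$width, tolerance = 1e-8)
    # frames transform equivariantly: superposing moved origins back
    # onto the originals is exact
    o0 <- t(vapply(base_pair_frames(d), `[[`, numeric(3), "origin"))
    om <- t(vapply(base_pair_frames(dm), `[[`, numeric(3), "origin"))
    expect_lt(max(abs(om - sweep(o0 %*% t(R), 2, tr, `+`))), 1e-6)
  }
})

test_that("minor groove widths read ~12 A for canonical B-DNA and scale", {
  d <- build_ideal_bdna(strrep("ATGCG", 5), rise = 3.32, twist = 36)
  gw <- minor_groove_widths(d)
  expect_gt(mean(gw$width), 11.3)
  expect_lt(mean(gw$width), 12.2)
  # a palindromic ideal duplex has a flat (hence symmetric) profile
  expect_lt(diff(range(gw$width)), 1e-6)
  # pure scaling of coordinates scales widths
  ds <- d
  ds$atoms[, c("x", "y", "z")] <- ds$atoms[, c("x", "y", "z")] * 1.1
  expect_equal(minor_groove_widths(ds)$width, gw$width * 1.1, tolerance = 1e-9)
  # the narrowed-backbone variant reads ~9.7 A
  dn <- build_ideal_bdna(strrep("ATGCG", 5), 3.32, 36, p_azimuth_deg = 81)
  expect_equal(mean(minor_groove_widths(dn)$width), 9.7, tolerance = 0.1)
})

test_that("bend angle reads 0 for straight and the built angle for bent DNA", {
  d <- build_ideal_bdna(strrep("ATGCG", 5), rise = 3.32, twist = 36)
  fr <- base_pair_frames(d)
  expect_lt(bend_angle(fr), 0.5)
  db <- bend_duplex(d, split = 12, angle_deg = 40)
  frb <- base_pair_frames(db)
  expect_equal(bend_angle(frb, split = 12), 40, tolerance = 1)
  # rigid motion leaves the bend unchanged
  set.seed(5)
  dm <- transform_duplex(db, random_rotation(), rnorm(3, 0, 10))
  expect_equal(bend_angle(base_pair_frames(dm), split = 12),
               bend_angle(frb, split = 12), tolerance = 1e-6)
  expect_error(bend_angle(fr[1:6], split = 3), ">= 4")
})

test_that("Shrake-Rupley areas match analytic spheres and caps", {
  lone <- data.frame(x = 0, y = 0, z = 0, element = "C")
  expect_equal(as.numeric(sasa(lone)), 4 * pi * (1.70 + 1.4)^2,
               tolerance = 0.02 * 4 * pi * 3.1^2)
  expect_error(sasa(data.frame(x = 0, y = 0, z = 0, element = "Zz")), "unknown")

  # far-apart chains bury nothing
  b <- data.frame(x = 20, y = 0, z = 0, element = "C")
  expect_equal(buried_interface_area(lone, b), 0)

  # two identical overlapping spheres: buried area = 2 pi R h per the
  # spherical-cap formula, h = R - d/2
  R <- 1.70 + 1.4
  for (dist in c(2.0, 4.0)) {
    b2 <- data.frame(x = dist, y = 0, z = 0, element = "C")
    analytic <- 2 * pi * R * (R - dist / 2)
    expect_equal(buried_interface_area(lone, b2), analytic,
                 tolerance = 0.03 * analytic)
    # symmetry in the two arguments
    expect_equal(buried_interface_area(lone, b2), buried_interface_area(b2, lone))
  }
})

test_that("duplexes extracted from PDB atoms reproduce built geometry", {
  d <- build_ideal_bdna("ATGCATGCATGCATG", rise = 3.32, twist = 36)
  tmp <- tempfile(fileext = ".pdb")
  write_pdb(duplex_to_atoms(d), tmp)
  d2 <- duplex_from_atoms(read_pdb(tmp), chains = c("C", "D"))
  expect_equal(d2$sequence, d$sequence)
  sp <- step_parameters(base_pair_frames(d2))
  expect_equal(attr(sp, "mean_twist"), 36, tolerance = 0.05)
  expect_equal(attr(sp, "mean_rise"), 3.32, tolerance = 0.01)

  # a non-complementary pairing warns but does not abort
  atoms <- duplex_to_atoms(d)
  atoms$res_name[atoms$chain == "C" & atoms$res_seq == 1] <- "DG"
  expect_warning(duplex_from_atoms(atoms), "not Watson-Crick")
})
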