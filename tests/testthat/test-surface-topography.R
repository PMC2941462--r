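single_atom <- function(el = "C") {
  quick_structure(at("CA", el, "GLY", 1, c(0, 0, 0)))
}

test_that("a single atom's envelope is a sphere with radial normals", {
  pts <- build_envelope(single_atom())
  r <- sqrt(pts$x^2 + pts$y^2 + pts$z^2)
  expect_equal(max(abs(r - 3.1)), 0, tolerance = 1e-9)       # vdW 1.7 + probe 1.4
  # normals radial outward
  dotp <- (pts$x * pts$nx + pts$y * pts$ny + pts$z * pts$nz) / r
  expect_equal(min(dotp), 1, tolerance = 1e-9)
  # dot-count x per-dot area recovers the analytic sphere area within 5%
  expect_equal(sum(attr(pts, "point_area")), 4 * pi * 3.1^2, tolerance = 0.05)
})

test_that("no envelope dots survive inside the mutually buried lens", {
  sep <- 2.0
  two <- quick_structure(at("CA", "C", "GLY", 1, c(0, 0, 0)),
                         at("CA", "C", "GLY", 2, c(sep, 0, 0)))
  pts <- build_envelope(two)
  d1 <- sqrt(pts$x^2 + pts$y^2 + pts$z^2)
  d2 <- sqrt((pts$x - sep)^2 + pts$y^2 + pts$z^2)
  # analytic lens exclusion: every kept dot lies on its own sphere and
  # outside the other inflated sphere
  expect_true(all(pmax(d1, d2) >= 3.1 - 1e-6))
  expect_true(all(abs(pmin(d1, d2) - 3.1) < 1e-6 | pmax(d1, d2) >= 3.1 - 1e-6))
  # the lune midplane region is empty
  expect_false(any(abs(pts$x - sep / 2) < 0.3 &
                   sqrt(pts$y^2 + pts$z^2) < sqrt(3.1^2 - (sep / 2)^2) - 0.3))
})

# hand-built spherical patches as surface_points, bypassing the envelope
sphere_patch <- function(R, concave = TRUE, n = 600) {
  dirs <- dhtopo:::fibonacci_sphere(n)
  keep <- dirs[, 3] < -0.2                        # a cap
  dirs <- dirs[keep, , drop = FALSE]
  pos <- dirs * R
  nrm <- if (concave) -dirs else dirs
  out <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
                    atom = 1L)
  class(out) <- c("surface_points", "data.frame")
  out
}

test_that("the osculating-sphere fit recovers radius and sign on exact spheres", {
  # inside of a sphere of radius 2: concave, theta = +2
  pin <- estimate_theta(sphere_patch(2.0, concave = TRUE))
  expect_equal(median(pin$theta, na.rm = TRUE), 2.0, tolerance = 0.1)
  expect_true(all(pin$theta[!pin$flat] > 0))
  # outside of a sphere of radius 3: convex, theta = -3
  pout <- estimate_theta(sphere_patch(3.0, concave = FALSE))
  expect_equal(median(pout$theta, na.rm = TRUE), -3.0, tolerance = 0.1)
  expect_true(all(pout$theta[!pout$flat] < 0))
  # a single atom's accessible sphere is convex with theta = -3.1
  pts <- estimate_theta(build_envelope(single_atom()))
  expect_equal(median(pts$theta, na.rm = TRUE), -3.1, tolerance = 0.05)
})

test_that("degenerate planar patches are flagged flat", {
  g <- expand.grid(x = seq(-3, 3, by = 0.4), y = seq(-3, 3, by = 0.4))
  out <- data.frame(x = g$x, y = g$y, z = 0, nx = 0, ny = 0, nz = 1, atom = 1L)
  class(out) <- c("surface_points", "data.frame")
  est <- estimate_theta(out)
  expect_true(all(est$flat))
  expect_true(all(is.na(est$theta)))
})

test_that("pit fixtures recover the prescribed curvature radius and sign", {
  # a hemispherical pit milled into a slab: pit interior concave at theta*,
  # slab top flat
  th <- 3.5
  s <- make_cavity_surface(th, slab_halfwidth = 13)
  pts <- estimate_theta(build_envelope(s))
  P <- attr(s, "pit_center")
  d <- sqrt((pts$x - P[1])^2 + (pts$y - P[2])^2 + (pts$z - P[3])^2)
  pit <- d < th + 0.3 & pts$z < P[3] - 0.3 * th
  expect_gt(sum(pit), 50)
  expect_equal(median(pts$theta[pit], na.rm = TRUE), th, tolerance = 0.3)
  expect_true(mean(pts$theta[pit] > 0, na.rm = TRUE) > 0.95)
  # the slab's outer rim reads convex or flat almost everywhere (the atom
  # lattice leaves a few genuinely concave grooves on the side wall)
  rim <- (abs(pts$x) > 13 | abs(pts$y) > 13) & pts$z > 0
  expect_gt(mean(pts$theta[rim] < 0 | pts$flat[rim], na.rm = TRUE), 0.85)
})

test_that("flat slabs contribute no sub-nanoscale concave spectrum", {
  s <- make_cavity_surface(NULL)
  pts <- estimate_theta(build_envelope(s))
  top <- pts$z > 2.5 & abs(pts$x) < 8 & abs(pts$y) < 8
  h <- theta_histogram(pts$theta[top])
  expect_equal(sum(h$count), 0)
})

test_that("curvature recovery holds across the sub-nanoscale grid", {
  for (th in c(1.0, 2.25, 5.0, 7.5, 10.0)) {
    s <- make_cavity_surface(th)
    pts <- estimate_theta(build_envelope(s))
    P <- attr(s, "pit_center")
    d <- sqrt((pts$x - P[1])^2 + (pts$y - P[2])^2 + (pts$z - P[3])^2)
    pit <- d < th + 0.3 & pts$z < P[3] - 0.3 * th
    m <- median(pts$theta[pit], na.rm = TRUE)
    expect_gt(m, 0)
    expect_lt(abs(m - th) / th, 0.10)
  }
})

test_that("theta values are exactly rigid-body invariant", {
  h <- classify_nonpolar_groups(place_amide_hydrogens(make_helix(10)))
  p1 <- estimate_theta(build_envelope(h))
  for (seed in c(3, 11)) {
    tr <- random_rigid_transform(seed)
    p2 <- estimate_theta(build_envelope(transform_structure(h, tr)))
    expect_identical(p2$flat, p1$flat)
    ok <- !is.na(p1$theta)
    expect_equal(p2$theta[ok], p1$theta[ok], tolerance = 1e-6)
  }
})

test_that("refining the dot spacing leaves the bond summary stable", {
  sb <- make_cavity_surface(2.25, with_bond = TRUE, slab_halfwidth = 8)
  sb <- classify_nonpolar_groups(sb)
  b <- detect_bhbs(sb)
  get_summary <- function(spacing) {
    pts <- estimate_theta(build_envelope(sb, point_spacing = spacing))
    bhb_vicinity_spectrum(b[1, ], pts, sb)$summary_theta
  }
  s050 <- get_summary(0.5)
  s025 <- get_summary(0.25)
  expect_lt(abs(s050 - s025) / s025, 0.05)
})

test_that("vicinity spectra attach pit curvature to the buried bond", {
  s <- classify_nonpolar_groups(make_cavity_surface(2.25, with_bond = TRUE))
  b <- detect_bhbs(s)
  expect_equal(nrow(b), 1)
  pts <- estimate_theta(build_envelope(s))
  sp <- bhb_vicinity_spectrum(b[1, ], pts, s)
  expect_false(sp$buried)
  expect_equal(sp$summary_theta, 2.25, tolerance = 0.3)
  expect_equal(sum(sp$histogram$count), sum(sp$thetas > 0 & sp$thetas < 10))
})

test_that("a bond sealed away from the surface yields an empty, buried spectrum", {
  # embed an ideal bond inside a solid ball of atoms: nothing near the
  # baricenter is solvent-exposed
  bond <- dhtopo:::.ideal_bond_atoms()
  bxyz <- do.call(rbind, lapply(bond, function(r) c(r$x, r$y, r$z)))
  g <- seq(-6.5, 6.5, by = 1.2)
  lat <- as.matrix(expand.grid(g, g, g))
  lat <- lat[sqrt(rowSums(lat^2)) <= 6.5, , drop = FALSE]
  ok <- vapply(seq_len(nrow(lat)), function(k)
    min(sqrt(rowSums((bxyz - rep(lat[k, ], each = nrow(bxyz)))^2))) >= 0.9,
    logical(1))
  lat <- lat[ok, , drop = FALSE]
  fill <- lapply(seq_len(nrow(lat)), function(k)
    dhtopo:::.atom_row_df("CA", "C", "GLY", 1000 + k, lat[k, ]))
  s <- dhtopo:::.finish_atoms(c(bond, fill))
  b <- detect_bhbs(s)
  expect_equal(nrow(b), 1)
  pts <- estimate_theta(build_envelope(s))
  sp <- bhb_vicinity_spectrum(b[1, ], pts, s)
  expect_true(sp$buried)
  expect_length(sp$thetas, 0)
  expect_true(is.na(sp$summary_theta))
})

test_that("quarter-angstrom histograms bin on the left-edge grid", {
  h <- theta_histogram(rep(2.0, 7))
  expect_equal(h$count[h$bin_left == 2.0], 7)    # [2.00, 2.25)
  expect_equal(sum(h$count), 7)
  expect_equal(h$bin_left, seq(0, 9.75, by = 0.25))
  # 3:1 mixture lands 0.75 / 0.25 of the mass
  mix <- c(rep(2.1, 75), rep(5.1, 25))
  hm <- theta_histogram(mix)
  expect_equal(hm$density[hm$bin_left == 2.0], 0.75)
  expect_equal(hm$density[hm$bin_left == 5.0], 0.25)
  # out-of-range and convex values carry no mass
  expect_equal(sum(theta_histogram(c(-3, 0, 10, 12))$count), 0)
})

test_that("pooled spectrum mass splits exactly into EBHB plus well-wrapped", {
  reps <- lapply(1:6, function(k) {
    th <- if (k %% 2) 2.25 else 5
    w <- if (k %% 2) 4 else 25
    s <- make_cavity_surface(th, with_bond = TRUE, w = w,
                             slab_halfwidth = 8, seed = 40 + k)
    s <- classify_nonpolar_groups(s)
    b <- classify_ebhb(compute_wrapping(detect_bhbs(s), s))
    pts <- estimate_theta(build_envelope(s))
    list(bonds = b, spectra = bhb_vicinity_spectra(b, pts, s))
  })
  bonds <- do.call(rbind, lapply(reps, `[[`, "bonds"))
  spectra <- do.call(c, lapply(reps, `[[`, "spectra"))
  pooled <- protein_theta_spectrum(bonds, spectra)
  expect_equal(pooled$count_bhb, pooled$count_ebhb + pooled$count_wrapped)
  expect_equal(sum(pooled$density_bhb), 1, tolerance = 1e-9)
  # the EBHB mass sits at low theta, the wrapped mass higher
  expect_gt(sum(pooled$density_ebhb[pooled$bin_left < 4]), 0.8)
  expect_gt(sum(pooled$density_wrapped[pooled$bin_left >= 4]), 0.8)
})
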