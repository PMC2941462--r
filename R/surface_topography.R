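# Solvent-accessible envelope sampling and signed osculating-sphere
# curvature radii (theta).
#
# The envelope is the surface traced by the center of a 1.4 A probe rolling
# over van der Waals spheres: every heavy atom is inflated by
# vdW + probe radius, quasi-uniform dots are placed on each sphere, and
# dots strictly inside any other inflated sphere are discarded.  The local
# curvature radius at a dot is the radius of the least-squares
# (first-order contact) sphere fitted to the dots within a small patch;
# theta > 0 marks concave regions (fitted center on the solvent side of the
# surface) and theta < 0 convex ones.  Sub-nanoscale spectra keep
# 0 < theta < 10 A; |theta| beyond the flatness cutoff is reported flat.

# Rotation-covariant orthonormal frame derived from the atom cloud, so dot
# sampling (and hence every theta) transforms exactly with a rigid-body
# motion of the input.  Principal axes of the centered coordinates, signs
# fixed against the two atoms farthest from the centroid; identity for
# degenerate clouds (< 3 atoms or near-equal eigenvalues).
.structure_frame <- function(centers) {
  n <- nrow(centers)
  if (n < 3) return(diag(3))
  cc <- sweep(centers, 2, colMeans(centers))
  ev <- eigen(crossprod(cc) / n, symmetric = TRUE)
  gaps <- -diff(ev$values)
  if (any(gaps < 1e-8 * max(ev$values[1], 1e-12))) return(diag(3))
  d <- sqrt(rowSums(cc^2))
  fix_sign <- function(v) {
    m3 <- sum((cc %*% v)^3)
    if (abs(m3) > 1e-8 * max(d)^3) return(v * sign(m3))
    ref <- cc[which.max(d), ]
    if (sum(v * ref) < 0) -v else v
  }
  v1 <- fix_sign(ev$vectors[, 1])
  v2 <- fix_sign(ev$vectors[, 2])
  cbind(v1, v2, cross3(v1, v2))
}

#' Sample the solvent-accessible envelope
#'
#' @param structure a `protein_structure` (heavy atoms; hydrogens are
#'   ignored when `ignore_hydrogens`)
#' @param probe_radius water-probe radius, angstroms (default 1.4)
#' @param point_spacing target dot spacing on each atom sphere, angstroms
#'   (default 0.5)
#' @param ignore_hydrogens drop H atoms before inflating (default TRUE;
#'   heavy-atom vdW surfaces are the convention)
#' @return a `surface_points` data.frame: dot position `x,y,z`, outward unit
#'   normal `nx,ny,nz`, and `atom` (row of the generating atom).  Per-dot
#'   area and the call parameters are attached as attributes.
#' @export
build_envelope <- function(structure, probe_radius = 1.4, point_spacing = 0.5,
                           ignore_hydrogens = TRUE) {
  stopifnot(inherits(structure, "protein_structure"))
  a <- structure$atoms
  rows <- seq_len(nrow(a))
  if (ignore_hydrogens) rows <- rows[a$element[rows] != "H"]
  if (!length(rows)) stop("empty structure: no heavy atoms to build an envelope from")
  centers <- as.matrix(a[rows, c("x", "y", "z")])
  radii <- vdw_radius(a$element[rows]) + probe_radius
  frame <- .structure_frame(centers)

  pts <- vector("list", length(rows))
  norms <- vector("list", length(rows))
  parent <- vector("list", length(rows))
  area <- numeric(0)
  for (k in seq_along(rows)) {
    n_dots <- max(24L, ceiling(4 * pi * radii[k]^2 / point_spacing^2))
    dirs <- fibonacci_sphere(n_dots) %*% t(frame)
    pts[[k]] <- sweep(dirs * radii[k], 2, centers[k, ], "+")
    norms[[k]] <- dirs
    parent[[k]] <- rep.int(k, n_dots)
    area <- c(area, rep.int(4 * pi * radii[k]^2 / n_dots, n_dots))
  }
  P <- do.call(rbind, pts)
  Nn <- do.call(rbind, norms)
  par <- unlist(parent)
  keep <- .cpp_prune_buried(P, par, centers, radii)
  out <- data.frame(x = P[keep, 1], y = P[keep, 2], z = P[keep, 3],
                    nx = Nn[keep, 1], ny = Nn[keep, 2], nz = Nn[keep, 3],
                    atom = rows[par[keep]])
  class(out) <- c("surface_points", "data.frame")
  attr(out, "point_area") <- area[keep]
  attr(out, "probe_radius") <- probe_radius
  attr(out, "point_spacing") <- point_spacing
  out
}

#' Estimate signed osculating-sphere curvature radii
#'
#' Fits an algebraic least-squares sphere (Coope formulation) to the
#' envelope dots within `patch_radius` of each dot.  theta is the fitted
#' radius, signed positive (concave) when the center lies on the
#' outward-normal side.  A sphere is only osculating where the patch does
#' not out-span the feature, so dots whose first-pass |theta| is smaller
#' than the patch are refit once with a patch shrunk to the local radius
#' (`refine = TRUE`); this removes the upward bias inside cavities tighter
#' than `patch_radius`.  Under-populated or degenerate (near-planar beyond
#' the conditioning tolerance) patches and fits with |theta| above
#' `flat_cutoff` are reported flat (theta = NA, `flat = TRUE`).
#'
#' @param points a `surface_points` table from [build_envelope()]
#' @param patch_radius fitting-patch radius, angstroms (default 2.5)
#' @param flat_cutoff |theta| above which the surface counts as flat,
#'   angstroms (default 20)
#' @param min_points minimum dots per patch (default 6)
#' @param cond_tol pivot-ratio bound flagging a degenerate patch (default 1e8)
#' @param refine second adaptive pass for high-curvature dots (default TRUE)
#' @param plane_tol RMS height, angstroms, under which a patch counts as
#'   planar whatever radius the sphere fit reports (default 0.05; sampling
#'   ripple on an inflated-sphere envelope stays below this, genuine
#'   sub-nanoscale features far above it)
#' @return `points` with `theta` (signed, NA when flat) and `flat` columns
#' @export
estimate_theta <- function(points, patch_radius = 2.5, flat_cutoff = 20,
                           min_points = 6, cond_tol = 1e8, refine = TRUE,
                           plane_tol = 0.05) {
  stopifnot(inherits(points, "surface_points"))
  P <- as.matrix(points[, c("x", "y", "z")])
  Nn <- as.matrix(points[, c("nx", "ny", "nz")])
  pr <- rep(patch_radius, nrow(P))
  fit <- .cpp_fit_spheres(P, Nn, pr, as.integer(min_points), cond_tol)
  if (refine) {
    small <- !is.na(fit[, 1]) & fit[, 2] == 1 & abs(fit[, 1]) < patch_radius
    if (any(small)) {
      pr2 <- pmax(1.0, pmin(patch_radius, 1.2 * abs(fit[, 1])))
      pr2[!small] <- patch_radius
      fit2 <- .cpp_fit_spheres(P, Nn, pr2, as.integer(min_points), cond_tol)
      fit[small, ] <- fit2[small, ]
    }
  }
  theta <- fit[, 1]
  flat <- fit[, 2] == 0 | (!is.na(theta) & abs(theta) > flat_cutoff) |
    fit[, 3] < plane_tol
  theta[flat] <- NA_real_
  points$theta <- theta
  points$flat <- flat
  attr(points, "patch_radius") <- patch_radius
  attr(points, "flat_cutoff") <- flat_cutoff
  points
}

#' Quarter-angstrom histogram of concave curvature radii
#'
#' Left-edge convention: bin k covers [k*binwidth, (k+1)*binwidth).
#'
#' @param thetas numeric curvature radii
#' @param binwidth bin width, angstroms (default 0.25)
#' @param theta_range kept range, default c(0, 10) (sub-nanoscale, concave)
#' @return data.frame `bin_left`, `count`, `density` (unit mass; NaN-free
#'   when empty)
#' @export
theta_histogram <- function(thetas, binwidth = 0.25, theta_range = c(0, 10)) {
  thetas <- thetas[!is.na(thetas) & thetas > theta_range[1] & thetas < theta_range[2]]
  edges <- seq(theta_range[1], theta_range[2], by = binwidth)
  lefts <- edges[-length(edges)]
  idx <- findInterval(thetas, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(lefts))
  data.frame(bin_left = lefts, count = counts,
             density = if (sum(counts)) counts / sum(counts) else rep(0, length(counts)))
}

#' Curvature spectrum in the vicinity of one bond
#'
#' Collects theta over envelope dots whose generating atom lies within
#' `vicinity_radius` of the bond baricenter.  The per-bond reduction
#' `summary_theta` is the median of the concave (theta > 0, sub-nanoscale)
#' vicinal values, falling back to the median of all vicinal values when no
#' concave dot exists.  A bond with no vicinal dots at all is flagged
#' buried.
#'
#' @param bond one row of a `bhb_table`
#' @param points a `surface_points` table with theta estimated
#' @param structure the parent `protein_structure`
#' @param vicinity_radius baricenter-to-atom cutoff, angstroms (default 3)
#' @param theta_max sub-nanoscale upper bound, angstroms (default 10)
#' @param binwidth histogram bin, angstroms (default 0.25)
#' @return a `curvature_spectrum` list: `thetas` (all vicinal values,
#'   signed), `summary_theta`, `buried`, `histogram`
#' @export
bhb_vicinity_spectrum <- function(bond, points, structure, vicinity_radius = 3.0,
                                  theta_max = 10, binwidth = 0.25) {
  stopifnot(inherits(structure, "protein_structure"))
  if (is.null(points$theta)) stop("points carry no theta; run estimate_theta() first")
  b <- c(bond$bx, bond$by, bond$bz)
  co <- as.matrix(structure$atoms[, c("x", "y", "z")])
  d_at <- sqrt(colSums((t(co) - b)^2))
  vat <- which(d_at <= vicinity_radius)
  sel <- points$atom %in% vat
  thetas <- points$theta[sel]
  thetas <- thetas[!is.na(thetas)]
  concave <- thetas[thetas > 0 & thetas < theta_max]
  summary_theta <- if (length(concave)) median(concave)
                   else if (length(thetas)) median(thetas) else NA_real_
  out <- list(
    donor = bond$donor, acceptor = bond$acceptor,
    thetas = thetas,
    summary_theta = summary_theta,
    buried = !any(sel),
    histogram = theta_histogram(concave, binwidth, c(0, theta_max))
  )
  class(out) <- "curvature_spectrum"
  out
}

#' @export
print.curvature_spectrum <- function(x, ...) {
  cat(sprintf("curvature_spectrum bond %s->%s: %d vicinal thetas, summary %.2f A%s\n",
              x$donor, x$acceptor, length(x$thetas),
              if (is.na(x$summary_theta)) NaN else x$summary_theta,
              if (x$buried) " [buried]" else ""))
  invisible(x)
}

#' Vicinity spectra for every bond
#'
#' @inheritParams bhb_vicinity_spectrum
#' @param bonds a `bhb_table`
#' @return list of `curvature_spectrum`, one per bond row
#' @export
bhb_vicinity_spectra <- function(bonds, points, structure, vicinity_radius = 3.0,
                                 theta_max = 10, binwidth = 0.25) {
  lapply(seq_len(nrow(bonds)), function(k)
    bhb_vicinity_spectrum(bonds[k, ], points, structure, vicinity_radius,
                          theta_max, binwidth))
}

#' Attach per-bond summary theta to a bond table
#'
#' @param bonds a `bhb_table`
#' @param spectra list from [bhb_vicinity_spectra()]
#' @return `bonds` with `summary_theta` and `buried` columns
#' @export
bond_theta_summary <- function(bonds, spectra) {
  stopifnot(nrow(bonds) == length(spectra))
  bonds$summary_theta <- vapply(spectra, function(s) s$summary_theta, numeric(1))
  bonds$buried <- vapply(spectra, function(s) s$buried, logical(1))
  bonds
}

#' Pooled sub-nanoscale curvature spectra per bond class
#'
#' Pools the vicinal concave thetas of all bonds and of the EBHB subset into
#' quarter-angstrom histograms (counts and unit-mass densities).  Before
#' normalization the BHB histogram mass equals the EBHB mass plus the
#' well-wrapped mass bin by bin.
#'
#' @param bonds a `bhb_table` with `is_ebhb`
#' @param spectra list from [bhb_vicinity_spectra()]
#' @param binwidth,theta_max histogram geometry (defaults 0.25, 10)
#' @return data.frame: `bin_left`, `count_bhb`, `density_bhb`, `count_ebhb`,
#'   `density_ebhb`, `count_wrapped`, `density_wrapped`
#' @export
protein_theta_spectrum <- function(bonds, spectra, binwidth = 0.25, theta_max = 10) {
  if (is.null(bonds$is_ebhb)) stop("bonds carry no is_ebhb column; run classify_ebhb() first")
  stopifnot(nrow(bonds) == length(spectra))
  pool <- function(sel) {
    th <- unlist(lapply(spectra[sel], function(s) s$thetas))
    theta_histogram(th, binwidth, c(0, theta_max))
  }
  all_h <- pool(rep(TRUE, length(spectra)))
  e_h <- pool(bonds$is_ebhb)
  w_h <- pool(!bonds$is_ebhb)
  data.frame(bin_left = all_h$bin_left,
             count_bhb = all_h$count, density_bhb = all_h$density,
             count_ebhb = e_h$count, density_ebhb = e_h$density,
             count_wrapped = w_h$count, density_wrapped = w_h$density)
}
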