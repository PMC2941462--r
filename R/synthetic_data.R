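# Deterministic fixture generators.  Each generator encodes a known ground
# truth that the corresponding pipeline stage must recover: an ideal helix
# with its i -> i+4 bond set, a single ideal bond with exactly w wrappers, a
# slab whose accessible envelope carries a spherical pit of curvature radius
# theta*, tetrahedral water networks of prescribed coordination, and a
# solvated bond whose nearest water sits at a prescribed distance with
# prescribed coordination.  Identical parameters + seed give bit-identical
# output.

.OH_BOND <- 0.96          # water O-H bond length, A
.HB_OO <- 2.8             # water-water hydrogen-bond O-O distance, A
.TETRA_DEG <- 109.4712206 # tetrahedral angle, degrees
.CONTACT <- 3.0           # water-oxygen / heavy-atom clearance floor, A
                          # (~ water and carbon vdW radii in contact)

# ---------------------------------------------------------------------------
# Peptides

.atom_row_df <- function(name, element, resname, resno, p, chain = "A") {
  data.frame(serial = NA_integer_, name = name, element = element,
             resname = resname, resno = resno, chain = chain,
             x = p[1], y = p[2], z = p[3], occupancy = 1, altloc = "",
             stringsAsFactors = FALSE)
}

.finish_atoms <- function(rows, solvent = NULL) {
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  protein_structure(at, solvent = solvent)
}

#' Ideal polyalanine alpha-helix
#'
#' Backbone built from standard internal coordinates with phi = -57,
#' psi = -47, omega = 180 degrees; every residue carries N, H (amide), CA,
#' CB, C, O.  The candidate backbone hydrogen bonds are the i -> i+4 set
#' (n - 4 of them).
#'
#' @param n_residues chain length (>= 5 so at least one bond exists)
#' @param seed kept for interface uniformity; the construction is
#'   deterministic
#' @return a `protein_structure`
#' @export
make_helix <- function(n_residues, seed = 1L) {
  if (n_residues < 5) stop("need n_residues >= 5 for a helical hydrogen bond")
  phi <- -57; psi <- -47
  N <- CA <- C <- matrix(NA_real_, n_residues, 3)
  N[1, ] <- c(0, 0, 0); CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- place_atom(c(0, 1, 0), N[1, ], CA[1, ], 1.525, 111.2, 0)
  for (i in 2:n_residues) {
    N[i, ]  <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], 1.329, 116.2, psi)
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], 1.458, 121.7, 180)
    C[i, ]  <- place_atom(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi)
  }
  rows <- list()
  for (i in seq_len(n_residues)) {
    O <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, psi + 180)
    CB <- place_atom(N[i, ], C[i, ], CA[i, ], 1.521, 110.1, 123)  # L chirality
    rows[[length(rows) + 1]] <- .atom_row_df("N", "N", "ALA", i, N[i, ])
    if (i > 1) {
      h <- N[i, ] + unit(-(unit(C[i - 1, ] - N[i, ]) + unit(CA[i, ] - N[i, ])))
      rows[[length(rows) + 1]] <- .atom_row_df("H", "H", "ALA", i, h)
    }
    rows[[length(rows) + 1]] <- .atom_row_df("CA", "C", "ALA", i, CA[i, ])
    rows[[length(rows) + 1]] <- .atom_row_df("CB", "C", "ALA", i, CB)
    rows[[length(rows) + 1]] <- .atom_row_df("C", "C", "ALA", i, C[i, ])
    rows[[length(rows) + 1]] <- .atom_row_df("O", "O", "ALA", i, O)
  }
  .finish_atoms(rows)
}

# One ideal backbone hydrogen bond in local coordinates: donor glycine
# (resno 5) N-H pointing at the acceptor glycine (resno 1) carbonyl along
# -x, N-O = 3.0 A, a_HB = 160 deg, baricenter at the origin.
.ideal_bond_atoms <- function(shift = c(0, 0, 0)) {
  Np <- c(1.5, 0, 0); Hp <- c(0.5, 0, 0)
  CAd <- Np + 1.458 * c(0.48, 0, -0.877)
  Cd <- CAd + 1.525 * c(0.5, 0, -0.866)
  Od <- Cd + 1.231 * c(0.7, 0, -0.714)
  Oa <- c(-1.5, 0, 0)
  Ca <- Oa - 1.231 * c(cos(20 * pi / 180), 0, -sin(20 * pi / 180))
  CAa <- Ca + 1.525 * c(cos(220 * pi / 180), 0, sin(220 * pi / 180))
  Na <- CAa + 1.458 * c(0, 1, 0)
  mk <- function(name, el, resno, p) .atom_row_df(name, el, "GLY", resno, p + shift)
  list(mk("N", "N", 1, Na), mk("CA", "C", 1, CAa), mk("C", "C", 1, Ca),
       mk("O", "O", 1, Oa),
       mk("N", "N", 5, Np), mk("H", "H", 5, Hp), mk("CA", "C", 5, CAd),
       mk("C", "C", 5, Cd), mk("O", "O", 5, Od))
}

# rejection-sample n pseudo-CH3 carbons inside the two-sphere desolvation
# domain, >= 1 A from everything placed so far, with an optional extra
# acceptance predicate
.sample_wrappers <- function(n, ca1, ca2, radius, occupied, extra_ok = NULL,
                             max_tries = 20000) {
  placed <- matrix(NA_real_, 0, 3)
  tries <- 0
  while (nrow(placed) < n) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("infeasible wrapper packing; try a larger desolvation radius")
    ctr <- if (stats::runif(1) < 0.5) ca1 else ca2
    dir <- stats::rnorm(3); dir <- dir / vnorm(dir)
    p <- ctr + dir * radius * stats::runif(1)^(1 / 3)
    if (vnorm(p - ca1) > radius && vnorm(p - ca2) > radius) next
    all_pts <- rbind(occupied, placed)
    if (nrow(all_pts) && min(sqrt(rowSums((all_pts - rep(p, each = nrow(all_pts)))^2))) < 1.0) next
    if (!is.null(extra_ok) && !extra_ok(p)) next
    placed <- rbind(placed, p)
  }
  placed
}

#' One ideal bond with exactly w nonpolar wrappers
#'
#' Builds a single glycine-glycine backbone hydrogen bond and scatters
#' exactly `w` pseudo-CH3 carbons (alanine CB records) uniformly inside the
#' two-sphere desolvation domain, at least 1 A from every other atom, so the
#' wrapping ground truth is rho = w.
#'
#' @param w wrapper count (>= 0)
#' @param desolvation_radius domain sphere radius, angstroms (default 6)
#' @param seed RNG seed for wrapper placement
#' @return a `protein_structure` (attr `w` holds the ground truth)
#' @export
make_wrapped_bond <- function(w, desolvation_radius = 6, seed = 1L) {
  if (w < 0) stop("w must be >= 0")
  set.seed(seed)
  rows <- .ideal_bond_atoms()
  occ <- do.call(rbind, lapply(rows, function(r) c(r$x, r$y, r$z)))
  ca1 <- c(rows[[2]]$x, rows[[2]]$y, rows[[2]]$z)
  ca2 <- c(rows[[7]]$x, rows[[7]]$y, rows[[7]]$z)
  if (w > 0) {
    pts <- .sample_wrappers(w, ca1, ca2, desolvation_radius, occ)
    for (k in seq_len(w))
      rows[[length(rows) + 1]] <- .atom_row_df("CB", "C", "ALA", 100 + k, pts[k, ])
  }
  out <- .finish_atoms(rows)
  attr(out, "w") <- w
  out
}

# ---------------------------------------------------------------------------
# Cavity surfaces

#' Slab surface with a spherical pit of prescribed curvature radius
#'
#' A dense carbon slab whose accessible envelope is flat at z = 3.1,
#' interrupted by a spherical pit of curvature radius `theta_star` centered
#' on the envelope plane: shell atoms on the sphere of radius
#' theta* + vdW + probe around the pit center generate a concave envelope
#' cap of radius exactly theta*.  With `theta_star = NULL` the slab is
#' uninterrupted (flat ground truth).  With `with_bond = TRUE` an ideal
#' backbone hydrogen bond is buried 2 A beneath the pit floor so the pit
#' dominates the bond's vicinity spectrum; `w` wrappers can be added in the
#' solid region around its alpha-carbons.
#'
#' @param theta_star pit curvature radius, angstroms (1 to 10), or NULL
#' @param with_bond bury an ideal bond beneath the pit floor
#' @param w wrappers for the buried bond (default 0)
#' @param slab_halfwidth slab extent, angstroms (default 10)
#' @param atom_spacing slab / shell atom spacing, angstroms (default 0.7;
#'   dense enough that the lattice ripple stays well under the pit scale)
#' @param probe_radius probe used for the 3.1 A inflation (default 1.4)
#' @param seed RNG seed (wrapper placement)
#' @return a `protein_structure`; attributes `theta_star`, `pit_center`,
#'   `floor_z` carry the ground truth
#' @export
make_cavity_surface <- function(theta_star = NULL, with_bond = FALSE, w = 0,
                                slab_halfwidth = 10, atom_spacing = 0.7,
                                probe_radius = 1.4, seed = 1L) {
  if (!is.null(theta_star) && (theta_star < 1 || theta_star > 10))
    stop("theta_star must lie in [1, 10] angstroms")
  set.seed(seed)
  infl <- 1.70 + probe_radius                # carbon vdW + probe
  P <- c(0, 0, infl)                         # pit center, on the flat envelope
  g <- seq(-slab_halfwidth, slab_halfwidth, by = atom_spacing)
  grid <- as.matrix(expand.grid(x = g, y = g))
  slab <- rbind(cbind(grid, z = 0), cbind(grid, z = -atom_spacing))
  keep_rows <- rep(TRUE, nrow(slab))
  shell <- NULL
  if (!is.null(theta_star)) {
    r_sph <- theta_star + infl
    d2P <- sqrt(rowSums((slab - rep(P, each = nrow(slab)))^2))
    keep_rows <- d2P > r_sph - 1e-6
    nsh <- ceiling(4 * pi * r_sph^2 / atom_spacing^2)
    sh <- sweep(fibonacci_sphere(nsh) * r_sph, 2, P, "+")
    # keep the shell up to the pit-center height: the envelope is then
    # spherical over a full hemisphere of the pit, so curvature patches
    # near the floor never leave the spherical region
    shell <- sh[sh[, 3] <= P[3], , drop = FALSE]
  }
  coords <- rbind(slab[keep_rows, , drop = FALSE], shell)
  rows <- lapply(seq_len(nrow(coords)), function(k)
    .atom_row_df("CA", "C", "GLY", 1000 + k, coords[k, ]))
  if (with_bond) {
    if (is.null(theta_star)) stop("with_bond requires a pit (theta_star)")
    # the bond sits immediately behind the continuous shell: the carbonyl
    # oxygen 0.2 A outside the shell-atom sphere, so the bond is fully
    # buried, the pit envelope stays purely spherical, and the baricenter
    # keeps the floor shell atoms inside its 3 A vicinity
    r_sph <- theta_star + infl
    zb <- P[3] - sqrt((r_sph + 0.2)^2 - 1.5^2)
    bond_rows <- .ideal_bond_atoms(shift = c(0, 0, zb))
    bond_xyz <- do.call(rbind, lapply(bond_rows, function(r) c(r$x, r$y, r$z)))
    # backing lattice under the bond: buries it from below so no crease
    # between bond spheres and the open shell underside enters the bond's
    # vicinity; only pit-floor points remain vicinal
    bg <- seq(-5.4, 5.4, by = 1.2)
    back <- as.matrix(expand.grid(x = bg, y = bg, z = zb - seq(0.8, 5, by = 1.2)))
    okb <- sqrt(rowSums((back - rep(P, each = nrow(back)))^2)) >= r_sph
    for (k in seq_len(nrow(back))) {
      if (!okb[k]) next
      if (min(sqrt(rowSums((bond_xyz - rep(back[k, ], each = nrow(bond_xyz)))^2))) < 0.8) next
      rows[[length(rows) + 1]] <- .atom_row_df("CA", "C", "GLY", 5000 + k, back[k, ])
    }
    rows <- c(bond_rows, rows)
    if (w > 0) {
      bond_atoms <- do.call(rbind, lapply(rows[1:9], function(r) c(r$x, r$y, r$z)))
      ca1 <- bond_atoms[2, ]; ca2 <- bond_atoms[7, ]
      r_sph <- theta_star + infl
      ok <- function(p) p[3] <= 0 && vnorm(p - P) >= r_sph
      pts <- .sample_wrappers(w, ca1, ca2, 6, bond_atoms, extra_ok = ok)
      wr <- lapply(seq_len(w), function(k) .atom_row_df("CB", "C", "ALA", 100 + k, pts[k, ]))
      rows <- append(rows, wr, after = 9)
    }
  }
  out <- .finish_atoms(rows)
  attr(out, "theta_star") <- theta_star
  attr(out, "pit_center") <- P
  attr(out, "floor_z") <- if (is.null(theta_star)) NULL else infl - (theta_star + infl)
  out
}

# ---------------------------------------------------------------------------
# Water networks

# diamond-cubic oxygen lattice with nearest-neighbor distance .HB_OO
.diamond_sites <- function(n) {
  a0 <- 4 * .HB_OO / sqrt(3)
  basis <- matrix(c(0, 0, 0,  0, .5, .5,  .5, 0, .5,  .5, .5, 0,
                    .25, .25, .25,  .25, .75, .75,  .75, .25, .75,  .75, .75, .25),
                  ncol = 3, byrow = TRUE)
  m <- ceiling((n / 8)^(1 / 3)) + 2  # margin keeps the seed's full neighbor shell in-block
  cells <- as.matrix(expand.grid(0:(m - 1), 0:(m - 1), 0:(m - 1)))
  sites <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k)
    sweep(basis, 2, cells[k, ], "+")))
  sites <- sites * a0
  ctr <- colMeans(sites)
  d_ctr <- sqrt(rowSums((sites - rep(ctr, each = nrow(sites)))^2))
  seed_site <- sites[which.min(d_ctr), ]
  # grow the block outward from a seed site so small n stays connected
  d_seed <- sqrt(rowSums((sites - rep(seed_site, each = nrow(sites)))^2))
  ord <- order(d_seed, sites[, 1], sites[, 2], sites[, 3])
  sites[ord[seq_len(n)], , drop = FALSE]
}

# orient an undirected edge list so every node donates (out-degree) <= 2;
# greedy with path-reversal repair.  Feasible whenever |E| <= 2|V| holds on
# every subgraph, which degree-<=-4 graphs satisfy.
.orient_edges <- function(edges, n) {
  donates <- integer(n)
  adj_out <- vector("list", n)        # node -> indices of edges it donates
  donor <- integer(nrow(edges))
  free_path <- function(start) {
    # BFS along donated edges from `start`; returns edge-index path ending
    # at a node with spare donation capacity, or NULL
    prev_edge <- rep(NA_integer_, n); seen <- logical(n)
    queue <- start; seen[start] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (ei in adj_out[[v]]) {
        u <- if (donor[ei] == edges[ei, 1]) edges[ei, 2] else edges[ei, 1]
        if (seen[u]) next
        seen[u] <- TRUE; prev_edge[u] <- ei
        if (donates[u] < 2) {
          path <- integer(0); node <- u
          while (node != start) {
            e <- prev_edge[node]; path <- c(e, path)
            node <- donor[e]
          }
          return(path)
        }
        queue <- c(queue, u)
      }
    }
    NULL
  }
  reverse_path <- function(path) {
    for (e in path) {
      old <- donor[e]
      new <- if (edges[e, 1] == old) edges[e, 2] else edges[e, 1]
      adj_out[[old]] <<- setdiff(adj_out[[old]], e)
      adj_out[[new]] <<- c(adj_out[[new]], e)
      donates[old] <<- donates[old] - 1L
      donates[new] <<- donates[new] + 1L
      donor[e] <<- new
    }
  }
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    pick <- if (donates[i] <= donates[j]) i else j
    if (donates[pick] >= 2) pick <- if (pick == i) j else i
    if (donates[pick] >= 2) {
      path <- free_path(i)
      if (is.null(path)) path <- free_path(j)
      if (is.null(path)) stop("cannot orient hydrogen-bond network with <= 2 donors per water")
      reverse_path(path)
      pick <- if (donates[i] < 2) i else j
    }
    donor[e] <- pick
    donates[pick] <- donates[pick] + 1L
    adj_out[[pick]] <- c(adj_out[[pick]], e)
  }
  donor
}

# a stray H direction from O that satisfies the angle criterion with none of
# the positions in `others`
.stray_h <- function(O, others, avoid = NULL, angle_min = 120) {
  cands <- list()
  if (nrow(others)) {
    s <- -colSums(sweep(others, 2, O, "-"))
    if (vnorm(s) > 1e-8) cands[[1]] <- unit(s)
  }
  extra <- fibonacci_sphere(64)
  for (k in seq_len(nrow(extra))) cands[[length(cands) + 1]] <- extra[k, ]
  for (d in cands) {
    H <- O + .OH_BOND * d
    bad <- FALSE
    if (nrow(others)) {
      for (m in seq_len(nrow(others))) {
        if (angle3(O, H, others[m, ]) >= angle_min) { bad <- TRUE; break }
      }
    }
    if (!bad && !is.null(avoid) && vec_angle(d, avoid) < 30) bad <- TRUE
    if (!bad) return(H)
  }
  stop("no valid stray hydrogen direction found")
}

#' Tetrahedral water network of prescribed coordination
#'
#' Oxygens sit on a compact block of the diamond-cubic (ice-like) lattice
#' with 2.8 A nearest neighbors; the nearest-neighbor edge set is pruned so
#' no molecule exceeds `g_star` hydrogen bonds, edges are oriented with at
#' most two donations per molecule, donated hydrogens lie on the O-O axis
#' (angle 180 degrees) and spare hydrogens point where they satisfy the
#' angle criterion with no neighbor.  The recovered hydrogen-bond graph
#' therefore equals the intended one exactly: interior molecules (all four
#' lattice neighbors present) have coordination `g_star`.
#'
#' @param g_star target coordination, 1 to 4
#' @param n_molecules number of waters
#' @param seed RNG seed (used only as a determinism handle)
#' @return a `solvent_frame`; attributes `edges_true` (intended edges) and
#'   `g_true` (intended per-molecule coordination)
#' @export
make_water_lattice <- function(g_star, n_molecules, seed = 1L) {
  if (!g_star %in% 1:4) stop("g_star must be 1, 2, 3 or 4")
  set.seed(seed)
  O <- .diamond_sites(n_molecules)
  n <- nrow(O)
  edges <- matrix(integer(0), 0, 2)
  if (n >= 2) {
    dm <- as.matrix(stats::dist(O))
    edges <- which(upper.tri(dm) & dm < .HB_OO + 0.1, arr.ind = TRUE)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  # prune to max degree g_star, removing edges between the most
  # over-coordinated nodes first (deterministic)
  deg <- tabulate(edges, nbins = n)
  repeat {
    over <- which(deg > g_star)
    if (!length(over)) break
    v <- over[which.max(deg[over])]
    inc <- which(edges[, 1] == v | edges[, 2] == v)
    nb <- ifelse(edges[inc, 1] == v, edges[inc, 2], edges[inc, 1])
    drop <- inc[order(-deg[nb], nb)[1]]
    edges <- edges[-drop, , drop = FALSE]
    deg <- tabulate(edges, nbins = n)
  }
  g_true <- deg
  H1 <- matrix(NA_real_, n, 3); H2 <- matrix(NA_real_, n, 3)
  if (nrow(edges)) {
    donor <- .orient_edges(edges, n)
    for (v in seq_len(n)) {
      mine <- which(donor == v)
      targets <- ifelse(edges[mine, 1] == v, edges[mine, 2], edges[mine, 1])
      hs <- list()
      for (t in targets) hs[[length(hs) + 1]] <- O[v, ] + .OH_BOND * unit(O[t, ] - O[v, ])
      # neighbors within HB distance that must NOT gain an edge from strays
      d <- sqrt(rowSums((O - rep(O[v, ], each = n))^2))
      near <- setdiff(which(d < 3.2 & d > 1e-9), targets)
      # also exclude intended partners that donate to v (edge exists anyway)
      partners <- unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
      near <- setdiff(near, partners)
      while (length(hs) < 2) {
        avoid <- if (length(hs)) unit(hs[[1]] - O[v, ]) else NULL
        hs[[length(hs) + 1]] <- .stray_h(O[v, ], O[near, , drop = FALSE], avoid)
      }
      H1[v, ] <- hs[[1]]; H2[v, ] <- hs[[2]]
    }
  } else {
    for (v in seq_len(n)) {
      H1[v, ] <- O[v, ] + .OH_BOND * c(1, 0, 0)
      H2[v, ] <- O[v, ] + .OH_BOND * c(cos(.TETRA_DEG * pi / 180),
                                       sin(.TETRA_DEG * pi / 180), 0)
    }
  }
  fr <- solvent_frame(O, H1, H2, 1L)
  attr(fr, "edges_true") <- unname(edges)
  attr(fr, "g_true") <- g_true
  fr
}

# ---------------------------------------------------------------------------
# Solvated bond

# tripod / tetrapod unit directions for a coordination shell, "up" = +z
.shell_dirs <- function(g_star, spin = 0) {
  th <- (180 - .TETRA_DEG) * pi / 180      # 70.53 deg from +z
  tripod <- t(vapply(spin + c(0, 120, 240), function(az) {
    az <- az * pi / 180
    c(sin(th) * cos(az), sin(th) * sin(az), cos(th))
  }, numeric(3)))
  switch(as.character(g_star),
         "0" = matrix(numeric(0), 0, 3),
         "1" = matrix(c(0, 0, 1), 1, 3),
         "2" = tripod[1:2, , drop = FALSE],
         "3" = tripod,
         "4" = rbind(c(0, 0, 1),
                     t(vapply(spin + c(60, 180, 300), function(az) {
                       az <- az * pi / 180
                       c(sin(.TETRA_DEG * pi / 180) * cos(az),
                         sin(.TETRA_DEG * pi / 180) * sin(az),
                         cos(.TETRA_DEG * pi / 180))
                     }, numeric(3)))))
}

# rotation taking +z onto unit vector v (Rodrigues)
.rot_from_z <- function(v) {
  z <- c(0, 0, 1)
  c_ <- sum(z * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  k <- unit(cross3(z, v))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(acos(c_)) * K + (1 - c_) * (K %*% K)
}

# Water-exclusion rule: lowest probe position (along `axis_dir`, decreasing
# s) at which the probe and all g_star coordination partners keep >=
# .CONTACT clearance from every protein atom, partners staying farther from
# the carbonyl than the probe.  The coordination shell is oriented with its
# open side along +axis_dir (the retreat direction).  Returns
# list(probe, partners).
.place_probe <- function(atom_xyz, Oc, g_star, d_star, axis_base, axis_dir,
                         z_hi, z_lo, step = 0.05, spins = seq(0, 110, by = 10)) {
  clear <- function(p) {
    d2 <- rowSums((atom_xyz - rep(p, each = nrow(atom_xyz)))^2)
    min(d2) >= .CONTACT^2
  }
  R <- .rot_from_z(unit(axis_dir))
  best <- NULL
  for (s in seq(z_hi, z_lo, by = -step)) {
    probe <- axis_base + s * axis_dir
    if (vnorm(probe - Oc) < d_star - 1e-9) break
    if (!clear(probe)) next
    found <- NULL
    for (sp in spins) {
      dirs <- .shell_dirs(g_star, sp) %*% t(R)
      partners <- sweep(dirs * .HB_OO, 2, probe, "+")
      ok <- TRUE
      if (nrow(partners)) {
        for (k in seq_len(nrow(partners))) {
          if (!clear(partners[k, ]) ||
              vnorm(partners[k, ] - Oc) <= vnorm(probe - Oc) + 0.2) { ok <- FALSE; break }
        }
      }
      if (ok) { found <- partners; break }
    }
    if (!is.null(found)) best <- list(probe = probe, partners = found)
    if (is.null(found) && !is.null(best)) break   # descended past feasibility
  }
  best
}

#' Solvated bond with prescribed hydration ground truth
#'
#' Builds a bond fixture (a bare wrapped bond, or a bond buried beneath a
#' cavity of curvature radius `theta_star`), then places a probe water and
#' its `g_star` tetrahedrally coordinated partners by the water-exclusion
#' rule: the probe descends toward the carbonyl only while its whole
#' coordination shell keeps clearance from the protein, and never closer
#' than `d_star`.  Hydrogens are oriented so the probe's hydrogen-bond
#' coordination is exactly `g_star`.  Frames jitter every molecule rigidly
#' by isotropic Gaussian noise.
#'
#' @param d_star requested nearest-water distance, angstroms (> 2.4); the
#'   realized distance `d_true` may be larger when the cavity excludes the
#'   coordination shell
#' @param g_star probe coordination, 0 to 4 (default 3, the interfacial value)
#' @param theta_star optional cavity curvature radius, angstroms
#' @param n_frames number of jittered frames (default 10)
#' @param sigma per-molecule jitter, angstroms (default 0.1)
#' @param w wrappers around the bond (default 0)
#' @param seed RNG seed
#' @param slab_halfwidth passed to [make_cavity_surface()] when a cavity is
#'   requested
#' @return list: `structure`, `frames`, `d_true` (realized probe-carbonyl
#'   distance), `g_star`, `bond_donor`, `bond_acceptor`
#' @export
make_solvated_bond <- function(d_star, g_star = 3, theta_star = NULL,
                               n_frames = 10, sigma = 0.1, w = 0, seed = 1L,
                               slab_halfwidth = 10) {
  if (d_star <= 2.4) stop("d_star must exceed 2.4 angstroms")
  if (!g_star %in% 0:4) stop("g_star must be 0..4")
  structure <- if (is.null(theta_star)) make_wrapped_bond(w, seed = seed)
               else make_cavity_surface(theta_star, with_bond = TRUE, w = w,
                                        slab_halfwidth = slab_halfwidth,
                                        seed = seed)
  set.seed(seed + 1L)
  bb <- backbone_index(structure)
  res <- structure$residues
  acc <- which(res$resno == 1 & res$resname == "GLY")[1]
  Oc <- .atom_xyz(structure, bb$O[acc])
  # clearance applies to the wall, not to the hydrogen-bond partner itself:
  # the acceptor carbonyl oxygen is excluded from the clash set
  keep <- structure$atoms$element != "H" & seq_len(nrow(structure$atoms)) != bb$O[acc]
  axyz <- as.matrix(structure$atoms[keep, c("x", "y", "z")])
  if (is.null(theta_star)) {
    ctr <- colMeans(axyz)
    sol <- NULL
    dirs <- rbind(unit(Oc - ctr), fibonacci_sphere(64))
    for (k in seq_len(nrow(dirs))) {
      u <- unit(dirs[k, ])
      cand <- .place_probe(axyz, Oc, g_star, d_star,
                           axis_base = Oc, axis_dir = u,
                           z_hi = d_star + 6, z_lo = d_star)
      if (is.null(cand)) next
      if (is.null(sol) || vnorm(cand$probe - Oc) < vnorm(sol$probe - Oc)) sol <- cand
      if (vnorm(sol$probe - Oc) <= d_star + 0.06) break
    }
  } else {
    P <- attr(structure, "pit_center")
    sol <- .place_probe(axyz, Oc, g_star, d_star,
                        axis_base = c(P[1], P[2], 0), axis_dir = c(0, 0, 1),
                        z_hi = P[3] + 8, z_lo = -theta_star + P[3] - 1)
  }
  if (is.null(sol)) stop("infeasible solvation spec: no clearance for the probe shell")
  O <- rbind(sol$probe, sol$partners)
  n <- nrow(O)
  H1 <- matrix(NA_real_, n, 3); H2 <- matrix(NA_real_, n, 3)
  n_donate <- min(2, g_star)
  hs <- list()
  for (k in seq_len(n_donate)) hs[[k]] <- O[1, ] + .OH_BOND * unit(O[1 + k, ] - O[1, ])
  while (length(hs) < 2) {
    avoid <- if (length(hs)) unit(hs[[1]] - O[1, ]) else NULL
    others <- if (g_star > 0) O[-1, , drop = FALSE] else matrix(numeric(0), 0, 3)
    hs[[length(hs) + 1]] <- .stray_h(O[1, ], others, avoid)
  }
  H1[1, ] <- hs[[1]]; H2[1, ] <- hs[[2]]
  if (g_star > 0) {
    for (k in 2:n) {
      if (k - 1 > n_donate) {       # this partner donates to the probe
        H1[k, ] <- O[k, ] + .OH_BOND * unit(O[1, ] - O[k, ])
      } else {                      # probe donates to it; stray first H
        H1[k, ] <- .stray_h(O[k, ], O[1, , drop = FALSE])
      }
      H2[k, ] <- .stray_h(O[k, ], O[1, , drop = FALSE],
                          avoid = unit(H1[k, ] - O[k, ]))
    }
  }
  frames <- lapply(seq_len(n_frames), function(f) {
    shift <- matrix(stats::rnorm(n * 3, sd = sigma), n, 3)
    # truncate rare large excursions so the intended hydrogen-bond topology
    # survives every frame (the jitter models thermal libration, not bond
    # breaking)
    nn <- sqrt(rowSums(shift^2))
    cap <- pmin(1, (1.7 * sigma) / pmax(nn, 1e-12))
    shift <- shift * cap
    solvent_frame(O + shift, H1 + shift, H2 + shift, f)
  })
  don <- which(res$resno == 5 & res$resname == "GLY")[1]
  list(structure = structure, frames = frames,
       d_true = vnorm(sol$probe - Oc), g_star = g_star,
       bond_donor = don, bond_acceptor = acc)
}
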