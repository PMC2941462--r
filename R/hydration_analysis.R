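# Water-water hydrogen-bond network, coordination field g(r), per-bond
# hydration parameters (d_min, g_min) and the coordination action A[g].
#
# A water-water hydrogen bond requires O-O distance < 3.2 A and an O-H-O
# angle (at the shared hydrogen, over any of the four donor-H arrangements)
# within [120, 180] degrees.  A molecule's coordination g is its degree in
# that graph.  The action A[g] sums squared coordination differences over
# ordered hydrogen-bonded neighbor pairs; it is zero exactly when g is
# constant on every connected component, so spatial changes in coordination
# are penalized.

#' Water-water hydrogen-bond graph of one frame
#'
#' @param frame a `solvent_frame`
#' @param oo_max O-O distance cutoff, angstroms (default 3.2)
#' @param angle_range O-H-O angle window, degrees (default c(120, 180))
#' @param strict require explicit hydrogens (default TRUE).  With
#'   `strict = FALSE`, frames without hydrogens fall back to the
#'   distance-only criterion and the graph is flagged `distance_only`.
#' @return a `water_hb_graph`: `n`, `edges` (two-column matrix, i < j),
#'   `g` (degree per molecule), `distance_only`
#' @export
water_hb_graph <- function(frame, oo_max = 3.2, angle_range = c(120, 180),
                           strict = TRUE) {
  stopifnot(inherits(frame, "solvent_frame"))
  n <- nrow(frame$O)
  if (n == 0) {
    out <- list(n = 0L, edges = matrix(integer(0), 0, 2), g = integer(0),
                distance_only = FALSE)
    class(out) <- "water_hb_graph"
    return(out)
  }
  hless <- !has_hydrogens(frame)
  if (hless && strict)
    stop("frame has no explicit hydrogens; pass strict = FALSE for the ",
         "distance-only fallback criterion")
  edges <- matrix(integer(0), 0, 2)
  if (n >= 2) {
    O <- frame$O
    dm <- as.matrix(stats::dist(O))
    cand <- which(upper.tri(dm) & dm < oo_max, arr.ind = TRUE)
    if (nrow(cand)) {
      if (hless) {
        edges <- cand
      } else {
        ok <- vapply(seq_len(nrow(cand)), function(k) {
          i <- cand[k, 1]; j <- cand[k, 2]
          .hb_angle_ok(O[i, ], frame$H1[i, ], frame$H2[i, ],
                       O[j, ], frame$H1[j, ], frame$H2[j, ], angle_range)
        }, logical(1))
        edges <- cand[ok, , drop = FALSE]
      }
    }
  }
  g <- tabulate(edges, nbins = n)
  out <- list(n = n, edges = unname(edges), g = g, distance_only = hless)
  class(out) <- "water_hb_graph"
  out
}

# any of the four O-H...O arrangements within the angle window?
.hb_angle_ok <- function(Oi, H1i, H2i, Oj, H1j, H2j, angle_range) {
  for (H in list(H1i, H2i)) {
    if (!anyNA(H) && .angle_at(H, Oi, Oj) >= angle_range[1] &&
        .angle_at(H, Oi, Oj) <= angle_range[2]) return(TRUE)
  }
  for (H in list(H1j, H2j)) {
    if (!anyNA(H) && .angle_at(H, Oj, Oi) >= angle_range[1] &&
        .angle_at(H, Oj, Oi) <= angle_range[2]) return(TRUE)
  }
  FALSE
}

# O_donor - H ... O_acceptor angle at H, degrees
.angle_at <- function(H, Od, Oa) angle3(Od, H, Oa)

#' @export
print.water_hb_graph <- function(x, ...) {
  cat(sprintf("water_hb_graph: %d waters, %d HB edges, mean g = %.2f%s\n",
              x$n, nrow(x$edges), if (x$n) mean(x$g) else NaN,
              if (x$distance_only) " [distance-only fallback]" else ""))
  invisible(x)
}

#' Coordination scalar field g(r)
#'
#' For each query position, the mean coordination of the waters whose
#' oxygen lies within `radius` (one water layer) of the query, averaged
#' over the frames in which at least one water enters the ball.  Queries no
#' water ever visits are flagged undefined.
#'
#' @param frames list of `solvent_frame`
#' @param queries m x 3 matrix of positions
#' @param radius ball radius, angstroms (default 2.5)
#' @param graphs optional precomputed list from [water_hb_graph()]
#' @param strict passed to [water_hb_graph()] when graphs are not supplied
#' @return data.frame: `qx,qy,qz`, `g`, `n_pairs` (contributing
#'   frame-water pairs), `defined`
#' @export
coordination_field <- function(frames, queries, radius = 2.5, graphs = NULL,
                               strict = TRUE) {
  if (inherits(frames, "solvent_frame")) frames <- list(frames)
  if (!length(frames)) stop("need at least one solvent frame")
  queries <- rbind(queries)
  if (is.null(graphs)) graphs <- lapply(frames, water_hb_graph, strict = strict)
  m <- nrow(queries)
  gsum <- numeric(m); nframe <- integer(m); npair <- integer(m)
  for (f in seq_along(frames)) {
    O <- frames[[f]]$O
    g <- graphs[[f]]$g
    for (q in seq_len(m)) {
      d <- sqrt(colSums((t(O) - queries[q, ])^2))
      inside <- d <= radius
      if (any(inside)) {
        gsum[q] <- gsum[q] + mean(g[inside])
        nframe[q] <- nframe[q] + 1L
        npair[q] <- npair[q] + sum(inside)
      }
    }
  }
  data.frame(qx = queries[, 1], qy = queries[, 2], qz = queries[, 3],
             g = ifelse(nframe > 0, gsum / nframe, NA_real_),
             n_pairs = npair, defined = nframe > 0)
}

#' Per-bond hydration parameters d_min and g_min
#'
#' For each frame, finds the water oxygen closest to the bond's carbonyl
#' oxygen (the acceptor's O; ties broken toward the lowest molecule index)
#' and records the distance and that molecule's coordination; `d_min` and
#' `g_min` are the frame means.  Frames without waters are skipped.
#'
#' @param bonds a `bhb_table`
#' @param frames list of `solvent_frame`
#' @param structure the parent `protein_structure`
#' @param graphs optional precomputed [water_hb_graph()] list
#' @param strict passed to [water_hb_graph()] when graphs are not supplied
#' @return a `hydration_records` data.frame: `donor`, `acceptor`, `d_min`,
#'   `g_min`, `n_frames`
#' @export
bhb_hydration <- function(bonds, frames, structure, graphs = NULL, strict = TRUE) {
  stopifnot(inherits(structure, "protein_structure"))
  if (inherits(frames, "solvent_frame")) frames <- list(frames)
  if (!length(frames)) stop("need at least one solvent frame")
  if (is.null(graphs)) graphs <- lapply(frames, water_hb_graph, strict = strict)
  bb <- backbone_index(structure)
  co <- as.matrix(structure$atoms[, c("x", "y", "z")])
  d_min <- g_min <- rep(NA_real_, nrow(bonds))
  n_used <- integer(nrow(bonds))
  for (k in seq_len(nrow(bonds))) {
    Oc <- co[bb$O[bonds$acceptor[k]], ]
    ds <- gs <- numeric(0)
    for (f in seq_along(frames)) {
      Ow <- frames[[f]]$O
      if (!nrow(Ow)) next
      d <- sqrt(colSums((t(Ow) - Oc)^2))
      i <- which.min(d)  # which.min takes the first (lowest index) on ties
      ds <- c(ds, d[i])
      gs <- c(gs, graphs[[f]]$g[i])
    }
    if (length(ds)) {
      d_min[k] <- mean(ds); g_min[k] <- mean(gs); n_used[k] <- length(ds)
    }
  }
  out <- data.frame(donor = bonds$donor, acceptor = bonds$acceptor,
                    d_min = d_min, g_min = g_min, n_frames = n_used)
  class(out) <- c("hydration_records", "data.frame")
  out
}

#' Curvature-binned hydration profiles
#'
#' Reproduces the theta-profile construction: bonds are pooled by their
#' summary curvature radius coarse-grained to quarter-angstrom bins, and
#' d_min / g_min are averaged within each occupied bin.
#'
#' @param records a `hydration_records` table
#' @param bonds a `bhb_table` with `summary_theta` (see
#'   [bond_theta_summary()])
#' @param binwidth theta bin, angstroms (default 0.25)
#' @return data.frame: `theta_bin` (left edge), `mean_d_min`, `mean_g_min`,
#'   `n_bonds`; empty bins are omitted
#' @export
theta_profiles <- function(records, bonds, binwidth = 0.25) {
  if (is.null(bonds$summary_theta))
    stop("bonds carry no summary_theta; run bond_theta_summary() first")
  key <- paste(records$donor, records$acceptor)
  bkey <- paste(bonds$donor, bonds$acceptor)
  theta <- bonds$summary_theta[match(key, bkey)]
  ok <- !is.na(theta) & !is.na(records$d_min)
  if (!any(ok)) {
    return(data.frame(theta_bin = numeric(0), mean_d_min = numeric(0),
                      mean_g_min = numeric(0), n_bonds = integer(0)))
  }
  bin <- floor(theta[ok] / binwidth) * binwidth
  agg <- split(data.frame(d = records$d_min[ok], g = records$g_min[ok]), bin)
  data.frame(theta_bin = as.numeric(names(agg)),
             mean_d_min = vapply(agg, function(x) mean(x$d), numeric(1)),
             mean_g_min = vapply(agg, function(x) mean(x$g), numeric(1)),
             n_bonds = vapply(agg, nrow, integer(1)),
             row.names = NULL)
}

#' Coordination action functional A[g]
#'
#' A[g] = sum over ordered hydrogen-bonded neighbor pairs (j, n) of
#' (g_j - g_n)^2, times `normalization`.  Nonnegative, zero exactly when
#' the coordination is constant across every connected component, and
#' increased by any configuration that changes coordination between
#' neighboring molecules.
#'
#' @param graph a `water_hb_graph`
#' @param normalization scale constant (default 1)
#' @return an `action_value` list: `A`, `n_waters`, `n_edges`
#' @export
action <- function(graph, normalization = 1) {
  stopifnot(inherits(graph, "water_hb_graph"))
  e <- graph$edges
  A <- if (nrow(e)) 2 * sum((graph$g[e[, 1]] - graph$g[e[, 2]])^2) else 0
  out <- list(A = normalization * A, n_waters = graph$n, n_edges = nrow(e))
  class(out) <- "action_value"
  out
}

#' @export
print.action_value <- function(x, ...) {
  cat(sprintf("action A[g] = %g over %d waters / %d HB edges\n",
              x$A, x$n_waters, x$n_edges))
  invisible(x)
}
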