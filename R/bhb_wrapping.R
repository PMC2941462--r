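# Backbone hydrogen-bond detection, wrapping (rho) and dehydron calls.
#
# A BHB is a geometric amide(N-H) -> carbonyl(O=C) interaction with
# N-O distance < 3.2 A and the angle between the N-H and O=C bond
# directions within [120, 180] degrees (180 = the ideal antiparallel
# alignment).  The wrapping parameter rho counts side-chain CHn carbons
# inside the desolvation domain: the union of two 6 A spheres centered on
# the alpha-carbons of the paired residues.  Bonds with rho <= 19 (one
# standard deviation below the database mean of 26.6) are exposed BHBs,
# also called dehydrons.

#' Detect backbone hydrogen bonds
#'
#' Scans every donor (amide N-H) / acceptor (carbonyl C=O) residue pair with
#' sequence separation >= `min_seq_sep` and returns those meeting both
#' geometric criteria.  A donor may bond two acceptors (bifurcation); each
#' qualifying pair is one row.  Incomplete residues (missing backbone atoms)
#' never participate.
#'
#' @param structure a `protein_structure` with amide hydrogens present (run
#'   [place_amide_hydrogens()] on crystal structures first)
#' @param max_no_distance N-O cutoff, angstroms (default 3.2)
#' @param angle_range allowed angle between the N-H and O=C bond vectors,
#'   degrees (default c(120, 180))
#' @param min_seq_sep minimum |i - j| in residue sequence numbers (default
#'   2; adjacent-residue contacts are covalent-geometry artifacts)
#' @param include_interchain also pair residues across chains (default
#'   FALSE; the reference statistics are for monomeric proteins)
#' @return a `bhb_table` data.frame: donor/acceptor residue ordinals, author
#'   numbers, chains and names, `n_o_distance`, `a_hb`, and the bond
#'   baricenter (midpoint of amide N and carbonyl O) as `bx, by, bz`
#' @export
detect_bhbs <- function(structure, max_no_distance = 3.2,
                        angle_range = c(120, 180), min_seq_sep = 2,
                        include_interchain = FALSE) {
  stopifnot(inherits(structure, "protein_structure"))
  bb <- backbone_index(structure)
  res <- structure$residues
  donors <- which(!res$incomplete & !is.na(bb$H) & !is.na(bb$N))
  acceptors <- which(!res$incomplete & !is.na(bb$C) & !is.na(bb$O))
  if (!length(donors)) {
    if (all(is.na(bb$H)))
      stop("no amide hydrogens in structure; run place_amide_hydrogens() first")
    return(.empty_bhb_table())
  }
  a <- structure$atoms
  co <- as.matrix(a[, c("x", "y", "z")])
  rows <- list()
  for (i in donors) {
    N <- co[bb$N[i], ]; H <- co[bb$H[i], ]
    u <- H - N
    for (j in acceptors) {
      if (!include_interchain && res$chain[i] != res$chain[j]) next
      if (res$chain[i] == res$chain[j] &&
          abs(res$resno[i] - res$resno[j]) < min_seq_sep) next
      O <- co[bb$O[j], ]
      d <- vnorm(N - O)
      if (d >= max_no_distance) next
      v <- O - co[bb$C[j], ]
      ang <- vec_angle(u, v)
      if (ang < angle_range[1] || ang > angle_range[2]) next
      b <- (N + O) / 2
      rows[[length(rows) + 1]] <- data.frame(
        donor = i, acceptor = j,
        donor_resno = res$resno[i], acceptor_resno = res$resno[j],
        donor_chain = res$chain[i], acceptor_chain = res$chain[j],
        donor_resname = res$resname[i], acceptor_resname = res$resname[j],
        n_o_distance = d, a_hb = ang,
        bx = b[1], by = b[2], bz = b[3],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else .empty_bhb_table()
  out <- out[order(out$donor, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bhb_table", "data.frame")
  out
}

.empty_bhb_table <- function() {
  out <- data.frame(donor = integer(0), acceptor = integer(0),
                    donor_resno = integer(0), acceptor_resno = integer(0),
                    donor_chain = character(0), acceptor_chain = character(0),
                    donor_resname = character(0), acceptor_resname = character(0),
                    n_o_distance = numeric(0), a_hb = numeric(0),
                    bx = numeric(0), by = numeric(0), bz = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("bhb_table", "data.frame")
  out
}

#' Count nonpolar wrappers in each bond's desolvation domain
#'
#' rho = number of classified side-chain CHn carbons whose center lies
#' within `desolvation_radius` of either paired alpha-carbon (union of the
#' two spheres; each carbon counted once).
#'
#' @param bonds a `bhb_table` from [detect_bhbs()]
#' @param structure the same structure, after [classify_nonpolar_groups()]
#' @param desolvation_radius sphere radius, angstroms (default 6, roughly
#'   three water layers)
#' @return `bonds` with an integer `rho` column; the contributing atom rows
#'   are attached as `attr(, "wrappers")` (a list, one vector per bond)
#' @export
compute_wrapping <- function(bonds, structure, desolvation_radius = 6) {
  stopifnot(inherits(structure, "protein_structure"))
  if (desolvation_radius <= 0) stop("desolvation_radius must be positive")
  if (is.null(structure$nonpolar))
    stop("nonpolar groups not classified; run classify_nonpolar_groups() first")
  bb <- backbone_index(structure)
  co <- as.matrix(structure$atoms[, c("x", "y", "z")])
  np <- structure$nonpolar
  npco <- co[np, , drop = FALSE]
  wrappers <- vector("list", nrow(bonds))
  rho <- integer(nrow(bonds))
  for (k in seq_len(nrow(bonds))) {
    ca1 <- co[bb$CA[bonds$donor[k]], ]
    ca2 <- co[bb$CA[bonds$acceptor[k]], ]
    d1 <- sqrt(colSums((t(npco) - ca1)^2))
    d2 <- sqrt(colSums((t(npco) - ca2)^2))
    hit <- d1 <= desolvation_radius | d2 <= desolvation_radius
    wrappers[[k]] <- np[hit]
    rho[k] <- sum(hit)
  }
  bonds$rho <- rho
  attr(bonds, "wrappers") <- wrappers
  attr(bonds, "desolvation_radius") <- desolvation_radius
  bonds
}

#' Classify exposed backbone hydrogen bonds (dehydrons)
#'
#' A bond is an EBHB when its wrapping rho is at or below the threshold.
#' The default 19 is the database mean 26.6 minus one standard deviation
#' 7.5, rounded down; `mode = "population"` recomputes
#' `floor(mean(rho) - sd(rho))` from the supplied bond population instead.
#'
#' @param bonds a `bhb_table` with a `rho` column (see [compute_wrapping()])
#' @param threshold wrapper-count cutoff (default 19)
#' @param mode "fixed" uses `threshold`; "population" derives it from the
#'   rho values in `bonds`
#' @return `bonds` with a logical `is_ebhb` column; the threshold used is
#'   attached as `attr(, "ebhb_threshold")`
#' @export
classify_ebhb <- function(bonds, threshold = 19, mode = c("fixed", "population")) {
  mode <- match.arg(mode)
  if (is.null(bonds$rho)) stop("bonds carry no rho column; run compute_wrapping() first")
  if (mode == "population") {
    if (nrow(bonds) < 2) stop("population mode needs at least two bonds")
    threshold <- floor(mean(bonds$rho) - stats::sd(bonds$rho))
  }
  bonds$is_ebhb <- bonds$rho <= threshold
  attr(bonds, "ebhb_threshold") <- threshold
  bonds
}
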