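# Structure ingestion and chemical normalization.
#
# A `protein_structure` is a list with:
#   atoms    data.frame: serial, name, element, resname, resno, chain,
#            x, y, z, occupancy, altloc, resid (ordinal residue index)
#   residues data.frame: resid, resno, chain, resname, incomplete
#   solvent  data.frame of water atoms routed out of the protein record
#            (or NULL), columns name, element, resno, x, y, z
#   nonpolar integer atom-row indices of side-chain CHn carbons (set by
#            classify_nonpolar_groups(), NULL before)
# Residue ordinals (`resid`) follow file order and are what sequence
# separation is measured on; `resno` keeps PDB author numbering for reports.

.backbone_names <- c("N", "CA", "C", "O")

#' Build a protein_structure from an atom table
#'
#' Mainly used by the synthetic generators and the PDB reader; computes the
#' residue table and flags residues missing any of N, CA, C, O as
#' incomplete (those are excluded from hydrogen-bond detection).
#'
#' @param atoms data.frame with columns serial, name, element, resname,
#'   resno, chain, x, y, z and optionally occupancy, altloc
#' @param solvent optional data.frame of water atoms (name, element, resno,
#'   x, y, z)
#' @return a `protein_structure`
#' @export
protein_structure <- function(atoms, solvent = NULL) {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "element", "resname", "resno", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table lacks column(s): ", paste(miss, collapse = ", "))
  if (!nrow(atoms)) stop("empty structure: no protein atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  key <- paste(atoms$chain, atoms$resno, sep = "|")
  atoms$resid <- match(key, unique(key))
  res_first <- !duplicated(atoms$resid)
  residues <- data.frame(
    resid = atoms$resid[res_first],
    resno = atoms$resno[res_first],
    chain = atoms$chain[res_first],
    resname = atoms$resname[res_first],
    stringsAsFactors = FALSE
  )
  has_bb <- vapply(residues$resid, function(r) {
    all(.backbone_names %in% atoms$name[atoms$resid == r])
  }, logical(1))
  residues$incomplete <- !has_bb
  x <- list(atoms = atoms, residues = residues, solvent = solvent, nonpolar = NULL)
  class(x) <- "protein_structure"
  x
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("protein_structure: %d atoms, %d residues (%d incomplete), %d chains\n",
              nrow(x$atoms), nrow(x$residues), sum(x$residues$incomplete),
              length(unique(x$residues$chain))))
  if (!is.null(x$solvent)) cat(sprintf("  + %d solvent atoms routed to waters\n", nrow(x$solvent)))
  if (!is.null(x$nonpolar)) cat(sprintf("  %d nonpolar side-chain groups classified\n", length(x$nonpolar)))
  invisible(x)
}

# Resolve element symbols when the PDB element column is blank.
.guess_element <- function(name) {
  nm <- gsub("[0-9' ]", "", name)
  substr(nm, 1, 1)
}

#' Read a protein structure from a PDB file
#'
#' Parses with bio3d, resolves alternate locations to the highest-occupancy
#' copy (ties broken toward altloc "A", then file order), routes water
#' residues (HOH/WAT/TIP/TIP3/SOL) to the solvent slot, and discards other
#' HETATM records.
#'
#' @param path PDB file
#' @param model_index 1-based model to use for multi-model files (default
#'   first model)
#' @return a `protein_structure`
#' @export
read_structure <- function(path, model_index = 1) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = model_index > 1, verbose = FALSE),
    error = function(e) stop("PDB parse error in '", path, "': ", conditionMessage(e))
  )
  at <- pdb$atom
  if (model_index > 1) {
    if (nrow(pdb$xyz) < model_index)
      stop("model_index ", model_index, " but file has ", nrow(pdb$xyz), " model(s)")
    co <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- co[, 1]; at$y <- co[, 2]; at$z <- co[, 3]
  }
  at$chain[is.na(at$chain)] <- "A"
  elem <- at$elesy
  blank <- is.na(elem) | elem == ""
  elem[blank] <- .guess_element(at$elety[blank])

  is_water <- toupper(at$resid) %in% .water_resnames
  keep_prot <- at$type == "ATOM" & !is_water

  df <- data.frame(
    serial = at$eleno, name = at$elety, element = toupper(elem),
    resname = toupper(at$resid), resno = at$resno, chain = at$chain,
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    stringsAsFactors = FALSE
  )
  prot <- df[keep_prot, , drop = FALSE]
  if (!nrow(prot)) stop("empty structure: no protein ATOM records in ", path)

  # altloc resolution: one copy per (chain, resno, name)
  if (any(prot$altloc != "")) {
    akey <- paste(prot$chain, prot$resno, prot$name, sep = "|")
    ord <- order(akey, -prot$occupancy, prot$altloc != "A",
                 seq_len(nrow(prot)))
    prot <- prot[ord, , drop = FALSE]
    prot <- prot[!duplicated(paste(prot$chain, prot$resno, prot$name, sep = "|")), , drop = FALSE]
    prot <- prot[order(prot$serial), , drop = FALSE]
  }

  solvent <- NULL
  if (any(is_water)) {
    solvent <- df[is_water, c("name", "element", "resno", "x", "y", "z"), drop = FALSE]
  }
  protein_structure(prot, solvent = solvent)
}

#' Write a normalized structure back to PDB
#'
#' @param structure a `protein_structure`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "protein_structure"))
  a <- structure$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resno, resid = a$resname, eleno = a$serial,
    elety = a$name, chain = a$chain, o = a$occupancy,
    b = rep(0, nrow(a)), elesy = a$element
  )
  invisible(path)
}

# Atom-row lookup: index of `name` in residue ordinal `resid`, NA if absent.
.atom_row <- function(structure, resid, name) {
  a <- structure$atoms
  hit <- which(a$resid == resid & a$name == name)
  if (length(hit)) hit[1] else NA_integer_
}

.atom_xyz <- function(structure, row) {
  as.numeric(structure$atoms[row, c("x", "y", "z")])
}

#' Backbone atom index per residue
#'
#' @param structure a `protein_structure`
#' @return data.frame with one row per residue and atom-row indices for N,
#'   H (amide), CA, C, O (NA where absent)
#' @export
backbone_index <- function(structure) {
  stopifnot(inherits(structure, "protein_structure"))
  a <- structure$atoms
  res <- structure$residues
  idx_of <- function(nm) {
    m <- rep(NA_integer_, nrow(res))
    rows <- which(a$name == nm)
    m[a$resid[rows]] <- rows
    m
  }
  h <- rep(NA_integer_, nrow(res))
  for (nm in c("H", "HN", "1H")) {  # common amide-H spellings; first hit wins
    rows <- which(a$name == nm)
    put <- a$resid[rows]
    fill <- is.na(h[put])
    h[put[fill]] <- rows[fill]
  }
  data.frame(resid = res$resid,
             N = idx_of("N"), H = h, CA = idx_of("CA"),
             C = idx_of("C"), O = idx_of("O"))
}

#' Place missing backbone amide hydrogens
#'
#' Adds an H atom 1.0 angstrom from each amide nitrogen, in the plane of
#' C(prev)-N-CA, opposite the bisector of the C(prev)-N and CA-N bonds (the
#' ideal trans-amide direction).  Prolines, chain N-termini, residues whose
#' preceding residue is missing its carbonyl carbon, and residues that
#' already carry an amide hydrogen are left untouched, so the operation is
#' idempotent.  Crystal structures rarely record hydrogens, and the
#' hydrogen-bond angle criterion needs them.
#'
#' @param structure a `protein_structure`
#' @return the structure with amide hydrogens added
#' @export
place_amide_hydrogens <- function(structure) {
  stopifnot(inherits(structure, "protein_structure"))
  bb <- backbone_index(structure)
  res <- structure$residues
  a <- structure$atoms
  new_rows <- list()
  for (i in seq_len(nrow(res))) {
    if (res$resname[i] == "PRO") next
    if (!is.na(bb$H[i])) next                       # keep experimental H
    if (i == 1 || res$chain[i - 1] != res$chain[i]) next  # chain N-terminus
    if (is.na(bb$N[i]) || is.na(bb$CA[i]) || is.na(bb$C[i - 1])) next
    n  <- .atom_xyz(structure, bb$N[i])
    ca <- .atom_xyz(structure, bb$CA[i])
    cp <- .atom_xyz(structure, bb$C[i - 1])
    if (vnorm(cp - n) > 2.0) next                   # chain break, no peptide bond
    h <- n + unit(-(unit(cp - n) + unit(ca - n)))
    new_rows[[length(new_rows) + 1]] <- data.frame(
      serial = NA_integer_, name = "H", element = "H",
      resname = res$resname[i], resno = res$resno[i], chain = res$chain[i],
      x = h[1], y = h[2], z = h[3], occupancy = 1, altloc = "",
      resid = res$resid[i], stringsAsFactors = FALSE
    )
  }
  if (length(new_rows)) {
    add <- do.call(rbind, new_rows)
    a2 <- rbind(a, add)
    a2 <- a2[order(a2$resid), , drop = FALSE]
    a2$serial <- seq_len(nrow(a2))
    out <- protein_structure(a2[, setdiff(names(a2), "resid")], solvent = structure$solvent)
    out$nonpolar <- NULL
    if (!is.null(structure$nonpolar)) out <- classify_nonpolar_groups(out)
    return(out)
  }
  structure
}

#' Classify side-chain nonpolar CHn groups
#'
#' Marks every side-chain carbon not covalently bonded to N, O or S, using
#' the bundled amino-acid connectivity table (robust to coordinate noise).
#' These carbons are the "wrappers" counted by [compute_wrapping()].
#' Nonstandard residues contribute no groups (with a warning).
#'
#' @param structure a `protein_structure`
#' @param include_polar_cb count the C-beta of Ser/Thr/Cys as well (default
#'   FALSE: they are bonded to O/S)
#' @return the structure with `$nonpolar` set to the qualifying atom rows
#' @export
classify_nonpolar_groups <- function(structure, include_polar_cb = FALSE) {
  stopifnot(inherits(structure, "protein_structure"))
  a <- structure$atoms
  res <- structure$residues
  known <- c(names(.sidechain_nonpolar))
  unk <- setdiff(unique(res$resname), known)
  if (length(unk))
    warning("nonstandard residue(s) contribute no nonpolar groups: ",
            paste(unk, collapse = ", "))
  nm <- a$name
  # normalize ILE CD -> CD1 (old PDB spelling)
  nm[a$resname == "ILE" & nm == "CD"] <- "CD1"
  keep <- logical(nrow(a))
  for (rn in intersect(unique(a$resname), known)) {
    want <- nonpolar_carbon_names(rn, include_polar_cb)
    if (length(want))
      keep <- keep | (a$resname == rn & nm %in% want & a$element == "C")
  }
  structure$nonpolar <- which(keep)
  structure
}

# ---------------------------------------------------------------------------
# Solvent frames

#' Construct a solvent frame from water coordinates
#'
#' @param O n x 3 matrix of water oxygen positions
#' @param H1,H2 n x 3 matrices of hydrogen positions, or NULL / NA rows when
#'   hydrogens are absent
#' @param frame_index integer label
#' @return a `solvent_frame`
#' @export
solvent_frame <- function(O, H1 = NULL, H2 = NULL, frame_index = 1L) {
  O <- rbind(O)
  n <- nrow(O)
  fix <- function(H) {
    if (is.null(H)) return(matrix(NA_real_, n, 3))
    H <- rbind(H)
    stopifnot(nrow(H) == n)
    H
  }
  H1 <- fix(H1); H2 <- fix(H2)
  for (H in list(H1, H2)) {
    ok <- stats::complete.cases(H)
    if (any(ok)) {
      d <- sqrt(rowSums((H[ok, , drop = FALSE] - O[ok, , drop = FALSE])^2))
      if (any(d <= 0.5 | d >= 1.3))
        stop("O-H distance outside (0.5, 1.3) angstrom; not a water geometry")
    }
  }
  x <- list(O = O, H1 = H1, H2 = H2, frame_index = as.integer(frame_index))
  class(x) <- "solvent_frame"
  x
}

#' @export
print.solvent_frame <- function(x, ...) {
  cat(sprintf("solvent_frame %d: %d waters (%d with hydrogens)\n",
              x$frame_index, nrow(x$O), sum(stats::complete.cases(x$H1))))
  invisible(x)
}

#' Does a solvent frame carry explicit hydrogens?
#'
#' @param frame a `solvent_frame`
#' @return logical
#' @export
has_hydrogens <- function(frame) UseMethod("has_hydrogens")

#' @rdname has_hydrogens
#' @export
has_hydrogens.solvent_frame <- function(frame) {
  any(stats::complete.cases(frame$H1))
}

# group a water-atom table (one frame) into a solvent_frame
.waters_to_frame <- function(df, frame_index = 1L) {
  mols <- split(df, factor(df$resno, levels = unique(df$resno)))
  n <- length(mols)
  O <- matrix(NA_real_, n, 3); H1 <- matrix(NA_real_, n, 3); H2 <- matrix(NA_real_, n, 3)
  for (k in seq_along(mols)) {
    m <- mols[[k]]
    io <- which(m$element == "O")
    ih <- which(m$element == "H")
    if (!length(io)) stop("water molecule without oxygen (resno ", names(mols)[k], ")")
    O[k, ] <- as.numeric(m[io[1], c("x", "y", "z")])
    if (length(ih) >= 1) H1[k, ] <- as.numeric(m[ih[1], c("x", "y", "z")])
    if (length(ih) >= 2) H2[k, ] <- as.numeric(m[ih[2], c("x", "y", "z")])
  }
  solvent_frame(O, H1, H2, frame_index)
}

#' Read explicit-solvent frames
#'
#' Two plain-text layouts are accepted: MODEL-separated PDB holding water
#' residues, and a simple XYZ-like format of whitespace records "EL x y z"
#' where each O line starts a molecule, following H lines (up to two) belong
#' to it, and any non-coordinate line starts a new frame.
#'
#' @param path file path
#' @param format "auto" (sniff), "pdb" or "xyz"
#' @return list of `solvent_frame`
#' @export
read_solvent_frames <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read solvent file: ", path)
  if (format == "auto") {
    head1 <- readLines(path, n = 50)
    format <- if (any(grepl("^(ATOM|HETATM|MODEL)", head1))) "pdb" else "xyz"
  }
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    at <- pdb$atom
    wat <- toupper(at$resid) %in% .water_resnames
    if (!any(wat)) stop("no water residues (", paste(.water_resnames, collapse = "/"), ") in ", path)
    elem <- at$elesy
    blank <- is.na(elem) | elem == ""
    elem[blank] <- .guess_element(at$elety[blank])
    nmod <- nrow(pdb$xyz)
    lapply(seq_len(nmod), function(m) {
      co <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
      df <- data.frame(element = toupper(elem[wat]), resno = at$resno[wat],
                       x = co[wat, 1], y = co[wat, 2], z = co[wat, 3])
      .waters_to_frame(df, m)
    })
  } else {
    lines <- readLines(path)
    tok <- strsplit(trimws(lines), "\\s+")
    is_atom <- vapply(tok, function(t) {
      length(t) == 4 && toupper(t[1]) %in% c("O", "H") &&
        !anyNA(suppressWarnings(as.numeric(t[2:4])))
    }, logical(1))
    frames <- list(); cur <- list(); fi <- 0L
    flush <- function() {
      if (!length(cur)) return()
      df <- do.call(rbind, cur)
      frames[[length(frames) + 1L]] <<- .waters_to_frame(df, fi)
    }
    mol <- 0L
    for (i in seq_along(lines)) {
      if (!is_atom[i]) {
        if (nzchar(trimws(lines[i])) || length(cur)) { flush(); cur <- list(); fi <- fi + 1L; mol <- 0L }
        next
      }
      t <- tok[[i]]
      el <- toupper(t[1])
      if (el == "O") mol <- mol + 1L
      if (mol == 0L) stop("XYZ frame line ", i, ": H before any O")
      cur[[length(cur) + 1L]] <- data.frame(element = el, resno = mol,
                                            x = as.numeric(t[2]), y = as.numeric(t[3]),
                                            z = as.numeric(t[4]))
    }
    flush()
    if (!length(frames)) stop("no solvent frames parsed from ", path)
    frames
  }
}

#' Write solvent frames in the XYZ-like layout
#'
#' @param frames list of `solvent_frame`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_solvent_frames <- function(frames, path) {
  if (inherits(frames, "solvent_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(sprintf("# frame %d, %d waters", fr$frame_index, nrow(fr$O)), con)
    for (k in seq_len(nrow(fr$O))) {
      writeLines(sprintf("O %.4f %.4f %.4f", fr$O[k, 1], fr$O[k, 2], fr$O[k, 3]), con)
      for (H in list(fr$H1, fr$H2)) {
        if (!anyNA(H[k, ]))
          writeLines(sprintf("H %.4f %.4f %.4f", H[k, 1], H[k, 2], H[k, 3]), con)
      }
    }
  }
  invisible(path)
}

#' Solvent waters bundled in a structure file, as a frame
#'
#' @param structure a `protein_structure` read from a PDB containing waters
#' @return a `solvent_frame`, or NULL when the file had no waters
#' @export
structure_solvent_frame <- function(structure) {
  stopifnot(inherits(structure, "protein_structure"))
  if (is.null(structure$solvent) || !nrow(structure$solvent)) return(NULL)
  .waters_to_frame(structure$solvent, 1L)
}
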