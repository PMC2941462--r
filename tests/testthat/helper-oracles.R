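# Independent brute-force oracles and small fixture builders.  These
# deliberately re-derive results from the raw coordinate tables, without
# going through the package's detection code paths.

# O(n^2) backbone hydrogen-bond scan straight off the atom table
brute_force_bhbs <- function(structure, max_no = 3.2, amin = 120, amax = 180,
                             min_sep = 2) {
  a <- structure$atoms
  res_keys <- unique(paste(a$chain, a$resno, sep = "|"))
  get <- function(key, nm) {
    ch <- sub("\\|.*", "", key); rn <- as.integer(sub(".*\\|", "", key))
    row <- which(a$chain == ch & a$resno == rn & a$name == nm)
    if (length(row)) as.numeric(a[row[1], c("x", "y", "z")]) else NULL
  }
  found <- character(0)
  for (dk in res_keys) for (ak in res_keys) {
    dch <- sub("\\|.*", "", dk); ach <- sub("\\|.*", "", ak)
    if (dch != ach) next
    drn <- as.integer(sub(".*\\|", "", dk)); arn <- as.integer(sub(".*\\|", "", ak))
    if (abs(drn - arn) < min_sep) next
    N <- get(dk, "N"); H <- get(dk, "H"); O <- get(ak, "O"); C <- get(ak, "C")
    CAd <- get(dk, "CA"); Cd <- get(dk, "C"); Od <- get(dk, "O")
    Na <- get(ak, "N"); CAa <- get(ak, "CA")
    # both residues must be backbone-complete
    if (is.null(N) || is.null(H) || is.null(O) || is.null(C) ||
        is.null(CAd) || is.null(Cd) || is.null(Od) ||
        is.null(Na) || is.null(CAa)) next
    d <- sqrt(sum((N - O)^2))
    if (d >= max_no) next
    u <- H - N; v <- O - C
    ang <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
    if (ang >= amin && ang <= amax) found <- c(found, paste(dk, ak, sep = ">"))
  }
  sort(found)
}

bond_keys <- function(bonds, structure) {
  res <- structure$residues
  sort(paste(
    paste(res$chain[bonds$donor], res$resno[bonds$donor], sep = "|"),
    paste(res$chain[bonds$acceptor], res$resno[bonds$acceptor], sep = "|"),
    sep = ">"))
}

# independent pairwise recount of water-water hydrogen-bond coordination
recount_g <- function(frame, oo_max = 3.2, amin = 120) {
  O <- frame$O; n <- nrow(O)
  g <- integer(n)
  ang_at <- function(H, Od, Oa) {
    u <- Od - H; v <- Oa - H
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  }
  if (n < 2) return(g)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((O[i, ] - O[j, ])^2)) >= oo_max) next
    hit <- FALSE
    for (H in list(frame$H1[i, ], frame$H2[i, ]))
      if (!anyNA(H) && ang_at(H, O[i, ], O[j, ]) >= amin) hit <- TRUE
    for (H in list(frame$H1[j, ], frame$H2[j, ]))
      if (!anyNA(H) && ang_at(H, O[j, ], O[i, ]) >= amin) hit <- TRUE
    if (hit) { g[i] <- g[i] + 1L; g[j] <- g[j] + 1L }
  }
  g
}

# one correctly column-aligned PDB coordinate line (altLoc at column 17)
pdb_line <- function(record, serial, name, alt, res, chain, resno, p,
                     occ = 1, el = substr(name, 1, 1)) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, paste0(" ", name), alt, res, chain, resno,
          p[1], p[2], p[3], occ, 0, el)
}

# correctly column-aligned multi-model PDB with water residues
write_model_pdb <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(frames)) {
    fr <- frames[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    k <- 0
    for (i in seq_len(nrow(fr$O))) {
      put <- function(nm, el, p) {
        k <<- k + 1
        writeLines(pdb_line("HETATM", k, nm, " ", "HOH", "A", i, p, el = el), con)
      }
      put("O", "O", fr$O[i, ])
      if (!anyNA(fr$H1[i, ])) put("H1", "H", fr$H1[i, ])
      if (!anyNA(fr$H2[i, ])) put("H2", "H", fr$H2[i, ])
    }
    writeLines("ENDMDL", con)
  }
  invisible(path)
}

# a protein_structure from a bare atom spec, one call
quick_structure <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(serial = i, name = r$name, element = r$el, resname = r$res,
               resno = r$resno, chain = "A",
               x = r$p[1], y = r$p[2], z = r$p[3],
               occupancy = 1, altloc = "", stringsAsFactors = FALSE)
  }))
  protein_structure(df)
}

at <- function(name, el, res, resno, p) list(name = name, el = el, res = res,
                                             resno = resno, p = p)
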