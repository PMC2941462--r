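# Orchestration: structure -> bonds -> wrapping -> curvature -> hydration,
# with pooled distributions, plus TSV/JSON report output.

#' Pipeline configuration with the standard defaults
#'
#' Every tunable of the pipeline, each at its conventional default:
#' hydrogen-bond geometry (3.2 A, 120-180 degrees), desolvation radius 6 A,
#' EBHB threshold 19 wrappers, probe 1.4 A, envelope dot spacing 0.5 A,
#' curvature patch 2.5 A, bond vicinity 3 A, quarter-angstrom histograms,
#' 10 A sub-nanoscale bound, 20 A flatness cutoff, 2.5 A coordination ball.
#'
#' @param ... overrides for any of the named defaults
#' @return a `run_config` list
#' @export
run_config <- function(...) {
  cfg <- list(
    max_no_distance = 3.2,     # N-O cutoff for a backbone hydrogen bond, A
    angle_range = c(120, 180), # N-H / O=C angle window, degrees
    min_seq_sep = 2,           # minimum residue separation |i - j|
    include_interchain = FALSE,
    desolvation_radius = 6,    # wrapping two-sphere radius, A
    ebhb_threshold = 19,       # wrappers at or below -> exposed bond
    ebhb_mode = "fixed",       # or "population": floor(mean - sd) of rho
    include_polar_cb = FALSE,  # count Ser/Thr/Cys C-beta as nonpolar
    probe_radius = 1.4,        # water probe, A
    point_spacing = 0.5,       # envelope dot spacing, A
    patch_radius = 2.5,        # curvature fitting patch, A
    vicinity_radius = 3.0,     # bond baricenter -> atom vicinity, A
    binwidth = 0.25,           # histogram coarse-graining, A
    theta_max = 10,            # sub-nanoscale upper bound, A
    flat_cutoff = 20,          # |theta| above which the surface is flat, A
    coordination_radius = 2.5, # g(r) ball radius, A
    strict_hb = TRUE,          # require explicit water hydrogens
    d_hist_range = c(2, 10),   # d_min histogram range, A
    seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown run_config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Histogram of nearest-water distances
#'
#' @param d numeric distances, angstroms
#' @param binwidth bin width (default 0.25)
#' @param range kept range (default c(2, 10))
#' @return data.frame `bin_left`, `count`, `density`
#' @export
dmin_histogram <- function(d, binwidth = 0.25, range = c(2, 10)) {
  theta_histogram(d, binwidth, range)
}

#' Run the full analysis on one structure
#'
#' Normalizes the structure (amide hydrogens, nonpolar groups), detects
#' bonds, counts wrappers, classifies dehydrons, builds the envelope and the
#' per-bond curvature spectra, and - when solvent frames are supplied -
#' computes per-bond d_min / g_min, the per-frame action, and the
#' theta-binned hydration profile.
#'
#' @param input a `protein_structure` or a PDB file path
#' @param frames optional list of `solvent_frame` (or a file path for
#'   [read_solvent_frames()])
#' @param config a [run_config()]
#' @return a `protein_report` list: `bonds` (per-bond table with geometry,
#'   rho, is_ebhb, summary_theta, buried, and d_min/g_min when frames were
#'   given), `spectra`, `theta_spectrum` (pooled per class), `dmin_histograms`
#'   (per class), `theta_profile`, `actions`, `points` (envelope with theta),
#'   `config`
#' @export
run_protein <- function(input, frames = NULL, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  structure <- if (inherits(input, "protein_structure")) input
               else read_structure(input)
  if (is.character(frames)) frames <- read_solvent_frames(frames)
  if (inherits(frames, "solvent_frame")) frames <- list(frames)

  structure <- place_amide_hydrogens(structure)
  structure <- classify_nonpolar_groups(structure,
                                        include_polar_cb = config$include_polar_cb)
  bonds <- detect_bhbs(structure,
                       max_no_distance = config$max_no_distance,
                       angle_range = config$angle_range,
                       min_seq_sep = config$min_seq_sep,
                       include_interchain = config$include_interchain)
  bonds <- compute_wrapping(bonds, structure, config$desolvation_radius)
  bonds <- classify_ebhb(bonds, config$ebhb_threshold, config$ebhb_mode)

  points <- build_envelope(structure, config$probe_radius, config$point_spacing)
  points <- estimate_theta(points, config$patch_radius, config$flat_cutoff)
  spectra <- bhb_vicinity_spectra(bonds, points, structure,
                                  config$vicinity_radius, config$theta_max,
                                  config$binwidth)
  bonds <- bond_theta_summary(bonds, spectra)
  theta_spectrum <- protein_theta_spectrum(bonds, spectra, config$binwidth,
                                           config$theta_max)

  records <- NULL; actions <- NULL; theta_profile <- NULL
  dmin_histograms <- NULL
  if (!is.null(frames) && length(frames)) {
    graphs <- lapply(frames, water_hb_graph, strict = config$strict_hb)
    records <- bhb_hydration(bonds, frames, structure, graphs = graphs)
    bonds$d_min <- records$d_min
    bonds$g_min <- records$g_min
    actions <- data.frame(
      frame = vapply(frames, function(f) f$frame_index, integer(1)),
      A = vapply(graphs, function(g) action(g)$A, numeric(1))
    )
    theta_profile <- theta_profiles(records, bonds, config$binwidth)
    dmin_histograms <- list(
      bhb = dmin_histogram(bonds$d_min, config$binwidth, config$d_hist_range),
      ebhb = dmin_histogram(bonds$d_min[bonds$is_ebhb], config$binwidth,
                            config$d_hist_range),
      wrapped = dmin_histogram(bonds$d_min[!bonds$is_ebhb], config$binwidth,
                               config$d_hist_range)
    )
  }
  out <- list(bonds = bonds, spectra = spectra, theta_spectrum = theta_spectrum,
              dmin_histograms = dmin_histograms, theta_profile = theta_profile,
              actions = actions, points = points, structure = structure,
              config = config)
  class(out) <- "protein_report"
  out
}

#' @export
print.protein_report <- function(x, ...) {
  nb <- nrow(x$bonds)
  ne <- if (nb) sum(x$bonds$is_ebhb) else 0
  cat(sprintf("protein_report: %d BHBs (%d exposed), %d envelope points\n",
              nb, ne, nrow(x$points)))
  if (!is.null(x$bonds$d_min))
    cat(sprintf("  hydration: mean d_min %.2f A, mean g_min %.2f\n",
                mean(x$bonds$d_min, na.rm = TRUE),
                mean(x$bonds$g_min, na.rm = TRUE)))
  invisible(x)
}

#' Run a batch of structures and pool the distributions
#'
#' Failures in individual inputs are caught and logged; the batch continues.
#' Pooled histograms are recomputed from the concatenated per-bond table, so
#' they equal the sum of the per-protein histograms.
#'
#' @param inputs list; each element either a structure / path, or a list
#'   with elements `input` and optionally `frames`
#' @param config a [run_config()]
#' @return a `batch_report`: `bonds` (concatenated, with a `protein` id
#'   column), `theta_spectrum`, `dmin_histograms`, `theta_profile`,
#'   `reports`, `failures`
#' @export
run_batch <- function(inputs, config = run_config()) {
  if (!length(inputs)) stop("empty batch")
  reports <- vector("list", length(inputs))
  failures <- character(0)
  for (i in seq_along(inputs)) {
    item <- inputs[[i]]
    if (!is.list(item) || inherits(item, "protein_structure")) item <- list(input = item)
    reports[[i]] <- tryCatch(
      run_protein(item$input, frames = item$frames, config = config),
      error = function(e) {
        failures <<- c(failures, sprintf("input %d: %s", i, conditionMessage(e)))
        NULL
      })
  }
  ok <- !vapply(reports, is.null, logical(1))
  if (!any(ok)) stop("all batch inputs failed:\n", paste(failures, collapse = "\n"))
  bonds <- do.call(rbind, lapply(which(ok), function(i) {
    b <- reports[[i]]$bonds
    b$protein <- rep(i, nrow(b))
    b
  }))
  th <- unlist(lapply(which(ok), function(i)
    lapply(reports[[i]]$spectra, function(s) s$thetas)), use.names = FALSE)
  th_e <- unlist(lapply(which(ok), function(i) {
    b <- reports[[i]]$bonds
    lapply(reports[[i]]$spectra[b$is_ebhb], function(s) s$thetas)
  }), use.names = FALSE)
  th_w <- unlist(lapply(which(ok), function(i) {
    b <- reports[[i]]$bonds
    lapply(reports[[i]]$spectra[!b$is_ebhb], function(s) s$thetas)
  }), use.names = FALSE)
  hb <- theta_histogram(th, config$binwidth, c(0, config$theta_max))
  he <- theta_histogram(th_e, config$binwidth, c(0, config$theta_max))
  hw <- theta_histogram(th_w, config$binwidth, c(0, config$theta_max))
  theta_spectrum <- data.frame(bin_left = hb$bin_left,
                               count_bhb = hb$count, density_bhb = hb$density,
                               count_ebhb = he$count, density_ebhb = he$density,
                               count_wrapped = hw$count, density_wrapped = hw$density)
  dmin_histograms <- NULL
  theta_profile <- NULL
  if (!is.null(bonds$d_min) && any(!is.na(bonds$d_min))) {
    dmin_histograms <- list(
      bhb = dmin_histogram(bonds$d_min, config$binwidth, config$d_hist_range),
      ebhb = dmin_histogram(bonds$d_min[bonds$is_ebhb], config$binwidth,
                            config$d_hist_range),
      wrapped = dmin_histogram(bonds$d_min[!bonds$is_ebhb], config$binwidth,
                               config$d_hist_range)
    )
    rec <- data.frame(donor = bonds$donor, acceptor = bonds$acceptor,
                      d_min = bonds$d_min, g_min = bonds$g_min)
    key <- !is.na(bonds$summary_theta) & !is.na(bonds$d_min)
    if (any(key)) {
      bin <- floor(bonds$summary_theta[key] / config$binwidth) * config$binwidth
      agg <- split(data.frame(d = bonds$d_min[key], g = bonds$g_min[key]), bin)
      theta_profile <- data.frame(
        theta_bin = as.numeric(names(agg)),
        mean_d_min = vapply(agg, function(x) mean(x$d), numeric(1)),
        mean_g_min = vapply(agg, function(x) mean(x$g), numeric(1)),
        n_bonds = vapply(agg, nrow, integer(1)), row.names = NULL)
    }
  }
  out <- list(bonds = bonds, theta_spectrum = theta_spectrum,
              dmin_histograms = dmin_histograms, theta_profile = theta_profile,
              reports = reports, failures = failures, config = config)
  class(out) <- "batch_report"
  out
}

#' Write a report's tables to a directory
#'
#' Bonds, pooled spectra, hydration profile and the envelope point table go
#' to TSV; the configuration to JSON.  Output is deterministic for a fixed
#' input and configuration.
#'
#' @param report a `protein_report` or `batch_report`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    if (is.null(df)) return()
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(report$bonds, "bonds.tsv")
  tsv(report$theta_spectrum, "theta_spectrum.tsv")
  tsv(report$theta_profile, "theta_profile.tsv")
  if (!is.null(report$dmin_histograms)) {
    tsv(report$dmin_histograms$bhb, "dmin_bhb.tsv")
    tsv(report$dmin_histograms$ebhb, "dmin_ebhb.tsv")
    tsv(report$dmin_histograms$wrapped, "dmin_wrapped.tsv")
  }
  if (!is.null(report$points)) tsv(as.data.frame(report$points), "surface_points.tsv")
  if (!is.null(report$actions)) tsv(report$actions, "actions.tsv")
  cfg <- report$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
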