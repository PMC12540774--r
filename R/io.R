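# Readers and writers for the formats the analysis stages consume, plus the
# config-driven pipeline runner. Coordinates are nanometres internally; PDB
# and XYZ files carry Angstroms and are converted on read/write.

check_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  for (cl in cols) {
    v <- df[[cl]]
    if (is.character(v) && any(grepl("^-?[0-9]+,[0-9]+$", v)))
      stop(sprintf("%s: column '%s' uses a decimal comma; export with '.' as decimal separator",
                   path, cl), call. = FALSE)
  }
  invisible(df)
}

#' Read a structure or trajectory from PDB
#'
#' Parses ATOM/HETATM records with \pkg{bio3d}; chain IDs and 1-based
#' residue numbers are preserved, coordinates converted to nm. Multi-model
#' files become trajectories.
#'
#' @param path PDB file path.
#' @return an [md_frame()] (single model) or [md_trajectory()].
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- toupper(substr(gsub("[0-9]", "", at$elety), 1, 1))
  base <- data.frame(atom_name = at$elety, element = elem,
                     resname = at$resid, resid = at$resno,
                     chain = ifelse(is.na(at$chain), "A", at$chain),
                     stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  n_models <- nrow(xyz)
  frames <- lapply(seq_len(n_models), function(m) {
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE) / 10
    a <- base
    a$x <- co[, 1]; a$y <- co[, 2]; a$z <- co[, 3]
    md_frame(a)
  })
  if (n_models == 1) frames[[1]] else md_trajectory(frames)
}

#' Write a frame or trajectory to PDB
#'
#' @param x an [md_frame()] or [md_trajectory()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(x, path) {
  frames <- if (inherits(x, "md_trajectory")) x$frames else list(x)
  at <- frames[[1]]$atoms
  if (any(nchar(at$chain) > 1)) {
    # the PDB chain field is a single character; remap deterministically
    ids <- unique(at$chain)
    pool <- c(LETTERS, letters, as.character(0:9))
    if (length(ids) > length(pool))
      stop("too many chains for PDB chain identifiers", call. = FALSE)
    warning("multi-character chain IDs remapped to single characters for PDB",
            call. = FALSE)
    at$chain <- pool[match(at$chain, ids)]
  }
  xyz <- do.call(rbind, lapply(frames, function(fr)
    as.vector(t(as.matrix(fr$atoms[c("x", "y", "z")]) * 10))))
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resid,
                   resid = at$resname, chain = at$chain, elety = at$atom_name)
  invisible(path)
}

#' Read an XYZ coordinate series onto a topology
#'
#' Standard XYZ frames (atom count, comment, then element x y z in
#' Angstroms) supply coordinates; atom names, residues and chains come from
#' the topology frame, whose atom order must match.
#'
#' @param path XYZ file with one or more frames.
#' @param topology an [md_frame()] providing the atom records.
#' @return an [md_trajectory()].
#' @export
read_xyz_frames <- function(path, topology) {
  stopifnot(inherits(topology, "md_frame"))
  lines <- readLines(path)
  n_at <- nrow(topology$atoms)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n))
      stop(sprintf("%s: line %d: expected an atom count", path, i),
           call. = FALSE)
    if (n != n_at)
      stop(sprintf("%s: line %d: frame has %d atoms, topology has %d",
                   path, i, n, n_at), call. = FALSE)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    co <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))) / 10
    if (any(!is.finite(co)))
      stop(sprintf("%s: malformed coordinate block starting at line %d",
                   path, i + 2L), call. = FALSE)
    a <- topology$atoms
    a$x <- co[, 1]; a$y <- co[, 2]; a$z <- co[, 3]
    frames[[length(frames) + 1L]] <- md_frame(a, box = topology$box)
    i <- i + 2L + n
  }
  md_trajectory(frames)
}

#' Write a trajectory as an XYZ series
#' @param traj an [md_trajectory()] or [md_frame()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_xyz_frames <- function(traj, path) {
  frames <- if (inherits(traj, "md_trajectory")) traj$frames else list(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    a <- fr$atoms
    writeLines(as.character(nrow(a)), con)
    writeLines("generated by coacervate", con)
    writeLines(sprintf("%s %.6f %.6f %.6f", a$element,
                       a$x * 10, a$y * 10, a$z * 10), con)
  }
  invisible(path)
}

#' Read titration wells from a long-format CSV
#'
#' Expects columns \code{well}, \code{step}, \code{addition_volume_uL},
#' \code{absorbance} (step 0 = pre-titration reading, addition volume
#' ignored for it), and a config carrying the well-independent parameters.
#'
#' @param path CSV path.
#' @param config list with \code{blank_absorbance}, \code{titrant_stock}
#'   (mM), \code{initial_volume} (uL), optional \code{initial_salt} (mM,
#'   default 0) and \code{labels} (named by well).
#' @return named list of [titration_record()] objects, one per well.
#' @export
read_titration_csv <- function(path, config) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("well", "step", "addition_volume_uL", "absorbance"),
                path)
  for (p in c("blank_absorbance", "titrant_stock", "initial_volume"))
    if (is.null(config[[p]]))
      stop("config missing '", p, "'", call. = FALSE)
  init_salt <- if (is.null(config$initial_salt)) 0 else config$initial_salt
  wells <- split(df, df$well)
  out <- lapply(names(wells), function(w) {
    d <- wells[[w]][order(wells[[w]]$step), ]
    titration_record(
      initial_volume = config$initial_volume,
      initial_salt = init_salt,
      titrant_stock = config$titrant_stock,
      addition_volumes = d$addition_volume_uL[d$step > 0],
      absorbances = d$absorbance,
      blank_absorbance = config$blank_absorbance,
      label = if (!is.null(config$labels[[w]])) config$labels[[w]] else w)
  })
  names(out) <- names(wells)
  out
}

#' Read FRAP traces from CSV
#'
#' Expects columns \code{time_s}, \code{intensity}, \code{droplet_id}.
#'
#' @param path CSV path.
#' @param n_prebleach number of pre-bleach frames per trace.
#' @return named list of [frap_trace()] objects.
#' @export
read_frap_csv <- function(path, n_prebleach) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("time_s", "intensity", "droplet_id"), path)
  by_id <- split(df, df$droplet_id)
  out <- lapply(names(by_id), function(id) {
    d <- by_id[[id]][order(by_id[[id]]$time_s), ]
    frap_trace(d$time_s, d$intensity, n_prebleach, droplet_id = id)
  })
  names(out) <- names(by_id)
  out
}

#' Read gel lane profiles from CSV
#'
#' Expects columns \code{lane}, \code{position}, \code{intensity} and
#' optionally \code{timepoint_h}.
#'
#' @param path CSV path.
#' @return named list of [lane_profile()] objects.
#' @export
read_lane_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("lane", "position", "intensity"), path)
  by_lane <- split(df, df$lane)
  out <- lapply(names(by_lane), function(l) {
    d <- by_lane[[l]][order(by_lane[[l]]$position), ]
    lane_profile(d$position, d$intensity, label = l,
                 timepoint = if ("timepoint_h" %in% names(d))
                   d$timepoint_h[1] else NA_real_)
  })
  names(out) <- names(by_lane)
  out
}

#' Read a coarse-grained bead table from CSV
#'
#' Expects columns \code{chain}, \code{type}, \code{sigma}, \code{x},
#' \code{y}, \code{z} (nm).
#'
#' @param path CSV path.
#' @param box box lengths (nm), length 3.
#' @return a [cg_frame()].
#' @export
read_cg_csv <- function(path, box) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("chain", "type", "sigma", "x", "y", "z"), path)
  cg_frame(df, box)
}

#' Read a grayscale image (PNG or TIFF) as an intensity matrix
#' @param path image path (.png, .tif/.tiff).
#' @return numeric matrix.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 3) img <- img[, , 1]
  as.matrix(img)
}

config_hash <- function(config) {
  j <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(j, tf)
  unname(tools::md5sum(tf))
}

#' Run an analysis stage from a configuration
#'
#' Dispatches one pipeline stage from a YAML file or an equivalent list and
#' writes its results as JSON (plus CSV for tabular outputs) into
#' \code{out_dir}, together with the configuration hash, package version and
#' seed, so identical configurations yield byte-identical results.
#'
#' Supported stages: \code{csc} (titration CSV to per-well CSC table),
#' \code{nmin} (lengths + CSC values to an N_min fit), \code{frap} (trace
#' CSV to per-droplet and averaged fits), \code{pe} (lane CSV + band windows
#' to a yield time course), \code{cg} (bead CSV to contact counts and a
#' density profile), \code{contacts} (PDB to per-nucleotide contact rates).
#'
#' @param config path to a YAML file or a named list. Required fields:
#'   \code{stage}, \code{out_dir}, plus stage-specific inputs (see the
#'   readers). Unknown top-level keys are rejected.
#' @return the result object, invisibly; files are written to
#'   \code{out_dir}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!length(config)) stop("empty configuration", call. = FALSE)
  known <- c("stage", "out_dir", "input", "dark_input", "params", "seed",
             "labels", "blank_absorbance", "titrant_stock",
             "initial_volume", "initial_salt", "n_prebleach",
             "band_windows", "box", "window", "peptide_lengths",
             "csc_values")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(config$stage)) stop("config missing 'stage'", call. = FALSE)
  if (is.null(config$out_dir)) stop("config missing 'out_dir'", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  result <- switch(
    config$stage,
    csc = {
      recs <- read_titration_csv(config$input, config)
      fits <- lapply(recs, extract_csc)
      tab <- data.frame(
        well = names(fits),
        csc_mM = vapply(fits, function(f) f$csc, numeric(1)),
        slope = vapply(fits, function(f) f$tangent$slope, numeric(1)),
        r_squared = vapply(fits, function(f) f$tangent$r_squared, numeric(1)),
        extrapolated = vapply(fits, function(f) f$extrapolated, logical(1)),
        stringsAsFactors = FALSE)
      utils::write.csv(tab, file.path(config$out_dir, "csc.csv"),
                       row.names = FALSE)
      tab
    },
    nmin = {
      fit <- fit_nmin(unlist(config$peptide_lengths),
                      unlist(config$csc_values))
      list(n_min = fit$n_min, slope = fit$slope, intercept = fit$intercept,
           r_squared = fit$r_squared)
    },
    frap = {
      traces <- read_frap_csv(config$input, config$n_prebleach)
      avg <- average_recovery(traces)
      per <- lapply(traces, function(t) fit_recovery(normalize_trace(t)))
      list(average = coef(avg$fit),
           per_droplet = lapply(per, coef))
    },
    pe = {
      lanes <- read_lane_csv(config$input)
      wins <- lapply(config$band_windows, unlist)
      tc <- timecourse(lanes, wins)
      utils::write.csv(tc, file.path(config$out_dir, "pe_timecourse.csv"),
                       row.names = FALSE)
      tc
    },
    cg = {
      fr <- read_cg_csv(config$input, unlist(config$box))
      contacts <- cg_contact_pairs(fr)
      prof <- slab_density_profile(fr)
      utils::write.csv(prof, file.path(config$out_dir, "profile.csv"),
                       row.names = FALSE)
      list(n_contacts = nrow(contacts), profile = prof)
    },
    contacts = {
      x <- read_structure(config$input)
      if (inherits(x, "md_frame")) x <- md_trajectory(list(x))
      s <- per_nucleotide_rates(x, window = config$window)
      list(per_mode_rate = as.list(s$per_mode_rate),
           total_rate = s$total_rate, n_frames = s$n_frames,
           n_nucleotides = s$n_nucleotides)
    },
    stop("unknown stage: ", config$stage, call. = FALSE))
  bundle <- list(stage = config$stage,
                 package_version = as.character(utils::packageVersion("coacervate")),
                 config_hash = config_hash(config),
                 seed = config$seed,
                 result = result)
  jsonlite::write_json(bundle, file.path(config$out_dir, "result.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(bundle)
}
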