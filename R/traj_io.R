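## traj_io: containers and file formats.
##
## Conventions: coordinates and region definitions in Angstrom; times are ns
## internally and ps at the MD-facing boundaries (frame strides). Readers
## validate and reject inconsistent inputs rather than repairing them.

#' Trajectory container
#'
#' @param coords numeric array, frames x atoms x 3, Angstrom.
#' @param atoms data frame with one row per atom and columns `name`,
#'   `resname`, `resno`, `chain`, `element`.
#' @param times_ns strictly increasing frame times, ns, on a fixed stride
#'   (constant to within 1e-6 ns).
#' @param provenance list of free-form metadata (source path, stride_ps, rng).
#' @return An object of class `trajectory`: a list with the validated fields.
#' @export
trajectory <- function(coords, atoms, times_ns, provenance = list()) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    .stopf("coords must be a frames x atoms x 3 array")
  n_frames <- dim(coords)[1]
  n_atoms <- dim(coords)[2]
  need <- c("name", "resname", "resno", "chain", "element")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms)))
    .stopf("atoms must be a data frame with columns %s",
           paste(need, collapse = ", "))
  if (nrow(atoms) != n_atoms)
    .stopf("atoms table (%d rows) does not match coords (%d atoms)",
           nrow(atoms), n_atoms)
  if (length(times_ns) != n_frames)
    .stopf("times_ns length (%d) does not match frame count (%d)",
           length(times_ns), n_frames)
  if (n_frames > 1) {
    d <- diff(times_ns)
    if (any(d <= 0)) .stopf("times_ns must be strictly increasing")
    if (diff(range(d)) > 1e-6)
      .stopf("frame stride is not constant (range %.3g ns)", diff(range(d)))
  }
  if (anyNA(coords) || any(!is.finite(coords)))
    .stopf("coords contain non-finite values")
  structure(list(coords = coords, atoms = atoms,
                 times_ns = as.numeric(times_ns), provenance = provenance),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, stride %.4g ns\n",
              n_frames(x), nrow(x$atoms), trajectory_stride_ns(x)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Frame stride of a trajectory in ns
#' @param traj a [trajectory()].
#' @return numeric stride, ns (NA for a single-frame trajectory).
#' @export
trajectory_stride_ns <- function(traj) {
  if (n_frames(traj) < 2) return(NA_real_)
  mean(diff(traj$times_ns))
}

## Resolve an atom selection: integer indices, or a character vector matched
## against trimmed atom names. Errors on an empty selection.
.select_atoms <- function(traj, selection) {
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (length(idx) == 0 || any(idx < 1 | idx > nrow(traj$atoms)))
      .stopf("atom selection out of range")
    return(idx)
  }
  idx <- which(trimws(traj$atoms$name) %in% trimws(selection))
  if (length(idx) == 0)
    .stopf("atom selection '%s' matches no atoms",
           paste(selection, collapse = ","))
  idx
}

## ---------------------------------------------------------------- PDB ----

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, fixed-column ATOM records, coordinates
#' printed at the standard 0.001 Angstrom precision.
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  a <- traj$atoms
  nm <- ifelse(nchar(trimws(a$name)) < 4,
               sprintf(" %-3s", trimws(a$name)), substr(a$name, 1, 4))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)), nm, substr(a$resname, 1, 3), substr(a$chain, 1, 1),
      a$resno, traj$coords[f, , 1], traj$coords[f, , 2], traj$coords[f, , 3],
      1.0, 0.0, a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Atom identity is taken from the first model and checked against every
#' other model; a model with a different atom count is an error naming that
#' model. Frame times are assigned from `stride_ps`.
#'
#' @param path PDB file with MODEL/ENDMDL blocks (a file without MODEL
#'   records is read as a single frame).
#' @param stride_ps frame spacing used to assign times, ps.
#' @return A [trajectory()].
#' @export
read_multimodel_pdb <- function(path, stride_ps = 50) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0) {
    counts <- sum(is_atom)
    if (counts == 0) .stopf("no models / no atoms in %s", path)
  } else {
    block <- findInterval(seq_along(lines), model_starts)
    counts <- tabulate(block[is_atom], nbins = length(model_starts))
    if (any(counts == 0)) .stopf("model %d contains no atoms",
                                 which(counts == 0)[1])
    if (length(unique(counts)) != 1) {
      bad <- which(counts != counts[1])[1]
      .stopf("model %d has %d atoms; expected %d (from model 1)",
             bad, counts[bad], counts[1])
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  n_atoms <- ncol(xyz) / 3
  n_mod <- nrow(xyz)
  coords <- array(NA_real_, c(n_mod, n_atoms, 3))
  coords[, , 1] <- xyz[, seq(1, 3 * n_atoms, 3), drop = FALSE]
  coords[, , 2] <- xyz[, seq(2, 3 * n_atoms, 3), drop = FALSE]
  coords[, , 3] <- xyz[, seq(3, 3 * n_atoms, 3), drop = FALSE]
  if (any(!is.finite(coords))) .stopf("unparseable coordinates in %s", path)
  at <- pdb$atom
  atoms <- data.frame(name = at$elety, resname = at$resid,
                      resno = at$resno,
                      chain = ifelse(is.na(at$chain), "A", at$chain),
                      element = ifelse(is.na(at$elesy) | at$elesy == "",
                                       substr(trimws(at$elety), 1, 1),
                                       at$elesy),
                      stringsAsFactors = FALSE)
  trajectory(coords, atoms,
             times_ns = (seq_len(n_mod) - 1) * stride_ps / 1000,
             provenance = list(source = path, stride_ps = stride_ps))
}

## ---------------------------------------------------------------- XYZ ----

#' Write a trajectory in multi-frame XYZ format
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @param digits coordinate precision (decimal places).
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path, digits = 6) {
  stopifnot(inherits(traj, "trajectory"))
  n_atoms <- nrow(traj$atoms)
  fmt <- sprintf("%%-3s %%.%df %%.%df %%.%df", digits, digits, digits)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(as.character(n_atoms), con)
    writeLines(sprintf("frame %d t_ns=%.6f", f, traj$times_ns[f]), con)
    writeLines(sprintf(fmt, traj$atoms$element,
                       traj$coords[f, , 1], traj$coords[f, , 2],
                       traj$coords[f, , 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file as a trajectory
#'
#' Element symbols become atom names; frame times are assigned from
#' `stride_ps`. Frames with inconsistent atom counts are rejected.
#'
#' @param path XYZ file (count line, comment line, then `element x y z`).
#' @param stride_ps frame spacing, ps.
#' @return A [trajectory()].
#' @export
read_xyz_trajectory <- function(path, stride_ps = 50) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  i <- 1
  frames <- list()
  n_atoms <- NULL
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) .stopf("bad atom-count line at line %d", i)
    if (is.null(n_atoms)) n_atoms <- n
    if (n != n_atoms)
      .stopf("ragged XYZ: frame %d has %d atoms; expected %d",
             length(frames) + 1, n, n_atoms)
    if (i + 1 + n > length(lines))
      .stopf("truncated XYZ: frame %d incomplete", length(frames) + 1)
    body <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(body), "\\s+")
    if (any(lengths(parts) < 4)) .stopf("malformed XYZ record in frame %d",
                                        length(frames) + 1)
    el <- vapply(parts, `[`, "", 1)
    xyz <- t(vapply(parts, function(p) {
      v <- suppressWarnings(as.numeric(p[2:4]))
      if (anyNA(v)) .stopf("non-numeric coordinate in frame %d",
                           length(frames) + 1)
      v
    }, numeric(3)))
    frames[[length(frames) + 1]] <- list(el = el, xyz = xyz)
    i <- i + 2 + n
  }
  if (length(frames) == 0) .stopf("no frames in %s", path)
  coords <- array(NA_real_, c(length(frames), n_atoms, 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]$xyz
  el <- frames[[1]]$el
  atoms <- data.frame(name = el, resname = "UNK", resno = 1L, chain = "A",
                      element = el, stringsAsFactors = FALSE)
  trajectory(coords, atoms,
             times_ns = (seq_along(frames) - 1) * stride_ps / 1000,
             provenance = list(source = path, stride_ps = stride_ps))
}

## ------------------------------------------------------- event tables ----

#' Residence-event table
#'
#' One row per residence event/run: `run_id`, `duration_ns` (> 0) and
#' `censored` (TRUE if the event was still open at the censoring time).
#' When `cutoff` is finite (the batch-censoring design, every run censored
#' at the same time), censored rows must have `duration_ns == cutoff`. For
#' event streams detected inside a trajectory the censoring time varies per
#' event; record `cutoff = Inf` there.
#'
#' @param df data frame with columns `run_id`, `duration_ns`, `censored`.
#' @param cutoff common censoring time, ns, or `Inf`.
#' @return An `event_table` (a data frame with attribute `cutoff`).
#' @export
event_table <- function(df, cutoff = Inf) {
  need <- c("run_id", "duration_ns", "censored")
  if (!is.data.frame(df) || !all(need %in% names(df)))
    .stopf("event table needs columns %s", paste(need, collapse = ", "))
  df$censored <- as.logical(df$censored)
  if (anyNA(df$censored)) .stopf("censored flags must be TRUE/FALSE")
  if (anyNA(df$duration_ns) || any(df$duration_ns <= 0))
    .stopf("durations must be positive")
  if (length(cutoff) != 1 || is.na(cutoff) || cutoff <= 0)
    .stopf("cutoff must be > 0 (possibly Inf)")
  if (is.finite(cutoff) &&
      any(df$censored & abs(df$duration_ns - cutoff) > 1e-9))
    .stopf("censored rows must have duration equal to the cutoff (%g ns)",
           cutoff)
  if (any(df$duration_ns > cutoff + 1e-9))
    .stopf("durations cannot exceed the cutoff")
  out <- df[, need]
  attr(out, "cutoff") <- cutoff
  class(out) <- c("event_table", "data.frame")
  out
}

#' Cutoff of an event table
#' @param events an [event_table()].
#' @return numeric censoring time, ns (possibly `Inf`).
#' @export
event_cutoff <- function(events) attr(events, "cutoff")

#' Write an event table as TSV
#'
#' Tab-separated with a header row; a finite cutoff is recorded in a
#' `# cutoff_ns=` comment line above the header.
#'
#' @param events an [event_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  con <- file(path, "w")
  on.exit(close(con))
  co <- event_cutoff(events)
  if (is.finite(co)) writeLines(sprintf("# cutoff_ns=%.10g", co), con)
  write.table(as.data.frame(events), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an event table from TSV
#'
#' @param path TSV file with header `run_id`, `duration_ns`, `censored` and
#'   an optional `# cutoff_ns=` comment line. Without an explicit cutoff,
#'   the (unique) duration of censored rows is used; with no censored rows
#'   the table is read as uncensored (`cutoff = Inf`).
#' @return An [event_table()] (invariants enforced on read).
#' @export
read_events_tsv <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  cutoff <- Inf
  cm <- grep("^#\\s*cutoff_ns=", lines, value = TRUE)
  if (length(cm))
    cutoff <- as.numeric(sub("^#\\s*cutoff_ns=", "", cm[1]))
  df <- read.delim(text = lines[!startsWith(lines, "#")], sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("run_id", "duration_ns", "censored")
  if (!all(need %in% names(df)))
    .stopf("%s: header must contain %s", path, paste(need, collapse = ", "))
  if (!length(cm) && any(as.logical(df$censored))) {
    cd <- unique(df$duration_ns[as.logical(df$censored)])
    if (length(cd) != 1)
      .stopf("%s: censored rows have inconsistent durations and no cutoff line",
             path)
    cutoff <- cd
  }
  event_table(df, cutoff = cutoff)
}

## ------------------------------------------------------------ OpenDX ----

#' Write a scalar grid in OpenDX format
#'
#' Emits a `gridpositions`/`gridconnections`/`array` OpenDX scalar field with
#' the grid's origin, spacing and counts, data in the declared axis order
#' (last axis fastest), three values per line. Accepts a [density_grid()]
#' (writes voxel probabilities) or a [free_energy_grid()] (writes kcal/mol
#' values; masked voxels are written as `nan`).
#'
#' @param grid a [density_grid()] or [free_energy_grid()].
#' @param path output file.
#' @param what for density grids, `"probability"` (default) or `"counts"`.
#' @return `path`, invisibly.
#' @export
write_density_dx <- function(grid, path, what = c("probability", "counts")) {
  what <- match.arg(what)
  if (inherits(grid, "density_grid")) {
    vals <- if (what == "probability") grid$prob else grid$counts
    if (sum(grid$counts) == 0) .stopf("empty grid")
  } else if (inherits(grid, "free_energy_grid")) {
    vals <- grid$values
  } else .stopf("grid must be a density_grid or free_energy_grid")
  dims <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            dims[1], dims[2], dims[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", grid$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            dims[1], dims[2], dims[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(dims))), con)
  v <- as.vector(aperm(vals, c(3, 2, 1)))  # z fastest, x slowest
  vtxt <- ifelse(is.finite(v), sprintf("%.10e", v), "nan")
  n3 <- ceiling(length(vtxt) / 3) * 3
  vtxt <- c(vtxt, rep("", n3 - length(vtxt)))
  m <- matrix(vtxt, ncol = 3, byrow = TRUE)
  writeLines(trimws(paste(m[, 1], m[, 2], m[, 3])), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Write a JSON sidecar of generator/analysis settings
#'
#' @param settings a list (settings, seeds, rng identifiers, ...).
#' @param path output file (conventionally `<artifact>.json`).
#' @return `path`, invisibly.
#' @export
write_sidecar_json <- function(settings, path) {
  jsonlite::write_json(settings, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
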