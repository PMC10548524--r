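## conformation_dynamics: chi1 rotamer statistics and superposition/RMSF.

#' Rotamer time series
#'
#' @param time_ns frame times, ns.
#' @param chi1_deg chi1 dihedral per frame, degrees; wrapped to (-180, 180].
#' @param replica replica id.
#' @return A `rotamer_series` data frame with columns `time_ns`, `chi1_deg`,
#'   `state` (plus/trans/minus from [classify_rotamer()]) and `replica`.
#' @export
rotamer_series <- function(time_ns, chi1_deg, replica = 1L) {
  if (length(time_ns) != length(chi1_deg))
    .stopf("time and chi1 lengths differ")
  chi1 <- .wrap180(chi1_deg)
  df <- data.frame(time_ns = time_ns, chi1_deg = chi1,
                   state = classify_rotamer(chi1),
                   replica = as.integer(replica),
                   stringsAsFactors = FALSE)
  class(df) <- c("rotamer_series", "data.frame")
  df
}

#' Compute the chi1 (N-CA-CB-OG) series of a residue along a trajectory
#'
#' @param traj a [trajectory()].
#' @param resno residue number of the side chain.
#' @param chain chain id, or NULL for any.
#' @param atom_names the four dihedral atoms, in order (default N, CA, CB,
#'   OG for a serine).
#' @param replica replica id recorded in the output.
#' @return A [rotamer_series()]; frames with an undefined dihedral (colinear
#'   triplet) carry NA chi1 and state, flagged in column `degenerate`.
#' @export
compute_chi1 <- function(traj, resno, chain = NULL,
                         atom_names = c("N", "CA", "CB", "OG"),
                         replica = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(atom_names) != 4) .stopf("need exactly four atom names")
  at <- traj$atoms
  idx <- vapply(atom_names, function(nm) {
    hit <- trimws(at$name) == nm & at$resno == resno
    if (!is.null(chain)) hit <- hit & at$chain == chain
    w <- which(hit)
    if (length(w) != 1)
      .stopf("atom %s of residue %s: %d matches (need exactly 1)",
             nm, resno, length(w))
    w
  }, integer(1))
  nf <- n_frames(traj)
  chi1 <- rep(NA_real_, nf)
  degen <- logical(nf)
  for (f in seq_len(nf)) {
    p <- lapply(idx, function(a) traj$coords[f, a, ])
    val <- tryCatch(dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
                    error = function(e) NA_real_)
    if (is.na(val)) degen[f] <- TRUE else chi1[f] <- val
  }
  out <- rotamer_series(traj$times_ns, chi1, replica = replica)
  out$degenerate <- degen
  out
}

#' Classify chi1 angles into plus / trans / minus rotamers
#'
#' Nearest chi1 mode on the circle, with the fixed 120-degree sectors
#' \[0, 120) -> plus (+60), \[120, 180\] and (-180, -120) -> trans (180),
#' \[-120, 0) -> minus (-60). Sector boundaries are half-open towards
#' increasing angle (120 is trans, -120 is minus, 0 is plus), so every
#' finite angle belongs to exactly one state and classification is
#' invariant under 360-degree shifts.
#'
#' @param chi1 numeric vector of angles, degrees (any winding).
#' @return character vector: "plus", "trans" or "minus" (NA for NA input).
#' @export
classify_rotamer <- function(chi1) {
  if (any(is.nan(chi1) | is.infinite(chi1)))
    .stopf("chi1 must be finite")
  w <- .wrap180(chi1)
  out <- rep(NA_character_, length(w))
  out[!is.na(w) & w >= 0 & w < 120] <- "plus"
  out[!is.na(w) & (w >= 120 | w < -120)] <- "trans"
  out[!is.na(w) & w >= -120 & w < 0] <- "minus"
  out
}

#' Replica-averaged chi1 histogram
#'
#' Each replica's series is histogrammed on a common grid of `bin_width`
#' degree bins spanning (-180, 180] and normalized to unit mass; bins are
#' then averaged across replicas and their spread reported as the
#' population standard deviation (divide-by-n convention, as appropriate
#' for quoting the spread of the two values actually observed). Both the
#' per-bin probability *mass* and the per-degree *density* (mass /
#' bin_width) are returned.
#'
#' @param series_list a [rotamer_series()] or a list of them (one per
#'   replica).
#' @param bin_width bin width in degrees; must divide 360. Default 5.
#' @return data frame: `bin_lo`, `bin_hi`, `bin_mid`, `mean_mass`,
#'   `sd_mass`, `mean_density`, `sd_density`.
#' @export
rotamer_distribution <- function(series_list, bin_width = 5) {
  if (inherits(series_list, "rotamer_series"))
    series_list <- list(series_list)
  if (length(series_list) == 0) .stopf("need at least one replica")
  if (abs(360 / bin_width - round(360 / bin_width)) > 1e-9)
    .stopf("bin_width must divide 360")
  breaks <- seq(-180, 180, by = bin_width)
  masses <- vapply(series_list, function(s) {
    chi1 <- s$chi1_deg[!is.na(s$chi1_deg)]
    if (length(chi1) == 0) .stopf("empty chi1 series")
    ## (-180, 180]: right-closed bins
    h <- hist(chi1, breaks = breaks, plot = FALSE, right = TRUE,
              include.lowest = TRUE)
    h$counts / length(chi1)
  }, numeric(length(breaks) - 1))
  masses <- cbind(masses)
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             bin_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
             mean_mass = rowMeans(masses),
             sd_mass = apply(masses, 1, sd_pop),
             mean_density = rowMeans(masses) / bin_width,
             sd_density = apply(masses, 1, sd_pop) / bin_width)
}

#' Rotamer state fractions of a series
#'
#' @param series a [rotamer_series()].
#' @return named numeric: fraction of frames in plus / trans / minus.
#' @export
rotamer_state_fractions <- function(series) {
  st <- series$state[!is.na(series$state)]
  n <- length(st)
  c(plus = sum(st == "plus") / n,
    trans = sum(st == "trans") / n,
    minus = sum(st == "minus") / n)
}

#' Rotamer fractions conditioned on gas occupancy
#'
#' Splits frames by whether the coupled region is occupied and reports the
#' plus/trans/minus fractions separately on each subset.
#'
#' @param series a [rotamer_series()].
#' @param occupancy_series logical, one entry per frame.
#' @return data frame with rows `occupied` and `unoccupied`: columns
#'   `n_frames`, `plus`, `trans`, `minus` (NA fractions if a subset is
#'   empty).
#' @export
conditional_rotamer_fractions <- function(series, occupancy_series) {
  if (nrow(series) != length(occupancy_series))
    .stopf("series (%d frames) and occupancy (%d) lengths differ",
           nrow(series), length(occupancy_series))
  occ <- as.logical(occupancy_series)
  frac <- function(sub) {
    if (sum(sub) == 0) return(c(plus = NA, trans = NA, minus = NA))
    rotamer_state_fractions(series[sub, , drop = FALSE])
  }
  out <- rbind(occupied = frac(occ), unoccupied = frac(!occ))
  data.frame(n_frames = c(sum(occ), sum(!occ)), out)
}

#' Iterative superposition and per-atom RMSF
#'
#' Every frame's selected atoms are rigid-body superposed (optimal
#' least-squares rotation + translation, Kabsch) onto the mean structure of
#' the selection; the mean is recomputed and the procedure iterated until
#' the reference shifts by less than `tol` (RMS, Angstrom) or `max_iter`
#' iterations, giving the self-consistent "average structure". RMSF is the
#' root-mean-square deviation of each selected atom from its mean position
#' across superposed frames.
#'
#' @param traj a [trajectory()] with at least two frames.
#' @param selection atoms to superpose and report (indices or names),
#'   at least three and not colinear.
#' @param max_iter maximum mean-structure iterations (default 10).
#' @param tol convergence threshold on the RMS reference shift, Angstrom.
#' @return data frame: the selected atoms' identity columns plus `rmsf_A`.
#' @export
superpose_and_rmsf <- function(traj, selection, max_iter = 10, tol = 1e-6) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 2) .stopf("need at least two frames")
  idx <- .select_atoms(traj, selection)
  if (length(idx) < 3) .stopf("need at least three atoms")
  nf <- n_frames(traj)
  na <- length(idx)
  ## frames x 3n matrix in bio3d xyz layout (x1 y1 z1 x2 ...)
  xyz <- matrix(NA_real_, nf, 3 * na)
  for (k in seq_len(na)) xyz[, 3 * (k - 1) + 1:3] <- traj$coords[, idx[k], ]
  ref <- colMeans(xyz)
  refm <- matrix(ref, ncol = 3, byrow = TRUE)
  sv <- svd(sweep(refm, 2, colMeans(refm)))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    .stopf("degenerate selection: atoms are colinear or coincident")
  for (it in seq_len(max_iter)) {
    xyz <- bio3d::fit.xyz(fixed = ref, mobile = xyz,
                          fixed.inds = seq_len(3 * na),
                          mobile.inds = seq_len(3 * na))
    new_ref <- colMeans(xyz)
    shift <- sqrt(mean((new_ref - ref)^2))
    ref <- new_ref
    if (shift < tol) break
  }
  dev2 <- sweep(xyz, 2, ref)^2
  msd <- vapply(seq_len(na), function(k)
    mean(rowSums(dev2[, 3 * (k - 1) + 1:3, drop = FALSE])), numeric(1))
  out <- traj$atoms[idx, c("name", "resname", "resno", "chain")]
  out$rmsf_A <- sqrt(msd)
  rownames(out) <- NULL
  out
}
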