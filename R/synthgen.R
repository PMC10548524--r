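## synthgen: seeded generators for the synthetic study.
##
## The generators emulate the statistical structure of the MD observables the
## analysis stages consume -- a particle hopping among discrete pockets
## (continuous-time Markov chain), exponential escape from a reactive site
## with right-censoring at a cutoff, and a two-state rotamer whose switching
## rates are modulated by gas occupancy. They carry no force-field physics.

#' Pocket-hopping model
#'
#' Defines a continuous-time Markov chain over discrete pockets ("sites") in
#' 3D space. The particle dwells exponentially at each site and hops with the
#' given rates; observed positions are the site center plus isotropic
#' Gaussian noise truncated at 3 standard deviations so every frame remains
#' assignable to its generating site.
#'
#' @param site_centers numeric matrix (n_sites x 3) of site centers, Angstrom.
#' @param rate_matrix numeric (n_sites x n_sites) inter-site hopping rates in
#'   ns^-1; off-diagonal entries must be non-negative, the diagonal is
#'   ignored.
#' @param noise_sd isotropic positional spread per site, Angstrom (>= 0).
#'   Either a scalar or one value per site.
#' @param bulk_site optional index of a designated "solvent" site.
#' @return An object of class `hopping_model`.
#' @export
hopping_model <- function(site_centers, rate_matrix, noise_sd = 0.5,
                          bulk_site = NULL) {
  site_centers <- rbind(site_centers)
  if (!is.numeric(site_centers) || ncol(site_centers) != 3 ||
      nrow(site_centers) < 1 || anyNA(site_centers))
    .stopf("site_centers must be a numeric n x 3 matrix with n >= 1")
  n <- nrow(site_centers)
  rate_matrix <- as.matrix(rate_matrix)
  if (nrow(rate_matrix) != ncol(rate_matrix))
    .stopf("rate_matrix must be square (got %d x %d)",
           nrow(rate_matrix), ncol(rate_matrix))
  if (nrow(rate_matrix) != n)
    .stopf("rate_matrix dimension (%d) does not match number of sites (%d)",
           nrow(rate_matrix), n)
  off <- rate_matrix[row(rate_matrix) != col(rate_matrix)]
  if (any(!is.finite(off)) || any(off < 0))
    .stopf("off-diagonal hopping rates must be finite and non-negative")
  if (any(!is.finite(noise_sd)) || any(noise_sd < 0))
    .stopf("noise_sd must be >= 0")
  noise_sd <- rep_len(noise_sd, n)
  if (!is.null(bulk_site) && !(bulk_site %in% seq_len(n)))
    .stopf("bulk_site must index a site")
  structure(list(site_centers = site_centers, rate_matrix = rate_matrix,
                 noise_sd = noise_sd, bulk_site = bulk_site,
                 n_sites = n),
            class = "hopping_model")
}

#' Analytic stationary distribution of a hopping model
#'
#' Solves pi Q = 0 for the continuous-time Markov chain generator built from
#' the model's off-diagonal rates.
#'
#' @param model a [hopping_model()].
#' @return numeric vector of stationary site probabilities.
#' @export
stationary_distribution <- function(model) {
  stopifnot(inherits(model, "hopping_model"))
  Q <- model$rate_matrix
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  n <- nrow(Q)
  if (n == 1) return(1)
  ## solve pi Q = 0, sum(pi) = 1 via the bordered system
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi_hat <- qr.solve(A, b)
  pi_hat / sum(pi_hat)
}

## Isotropic Gaussian displacements truncated at 3 sd (radially), n x 3.
.rnoise_trunc <- function(n, sd) {
  if (sd == 0 || n == 0) return(matrix(0, n, 3))
  out <- matrix(rnorm(3 * n, sd = sd), n, 3)
  bad <- which(rowSums(out^2) > (3 * sd)^2)
  while (length(bad)) {
    out[bad, ] <- rnorm(3 * length(bad), sd = sd)
    bad <- bad[rowSums(out[bad, , drop = FALSE]^2) > (3 * sd)^2]
  }
  out
}

#' Simulate a pocket-hopping trajectory
#'
#' Simulates the continuous-time Markov chain by exact Gillespie event times
#' and samples the realized state path on a regular frame grid, so the frame
#' stride is purely an observation parameter and does not change the hopping
#' law. Each frame's position is the current site center plus truncated
#' isotropic noise.
#'
#' @param model a [hopping_model()].
#' @param duration_ns total simulated time, ns (>= stride).
#' @param stride_ps frame spacing, ps (> 0). Default 50 ps, the sampling
#'   interval used for gas-position mapping.
#' @param seed integer seed; if non-NULL, `set.seed(seed)` is called.
#' @param start_site starting site index (default 1).
#' @return A list with elements `trajectory` (a [trajectory()] holding one
#'   particle named "O1"), `sites` (integer true site label per frame) and
#'   `frame_times_ns`.
#' @export
simulate_hopping_trajectory <- function(model, duration_ns, stride_ps = 50,
                                        seed = NULL, start_site = 1L) {
  stopifnot(inherits(model, "hopping_model"))
  if (!.is_num1(stride_ps) || stride_ps <= 0) .stopf("stride_ps must be > 0")
  stride_ns <- stride_ps / 1000
  if (!.is_num1(duration_ns) || duration_ns < stride_ns)
    .stopf("duration_ns must be >= stride")
  if (!is.null(seed)) set.seed(seed)
  Q <- model$rate_matrix
  diag(Q) <- 0
  n_frames <- floor(duration_ns / stride_ns) + 1
  frame_times <- (seq_len(n_frames) - 1) * stride_ns

  ## Gillespie: jump times and the state entered at each jump
  state <- as.integer(start_site)
  jump_times <- 0
  states <- state
  t_now <- 0
  while (t_now <= duration_ns) {
    rates <- Q[state, ]
    total <- sum(rates)
    if (total <= 0) break  # absorbing state
    t_now <- t_now + rexp(1, rate = total)
    if (t_now > duration_ns) break
    state <- sample.int(model$n_sites, 1, prob = rates)
    jump_times <- c(jump_times, t_now)
    states <- c(states, state)
  }
  site_per_frame <- states[findInterval(frame_times, jump_times)]

  pos <- model$site_centers[site_per_frame, , drop = FALSE]
  for (s in unique(site_per_frame)) {
    idx <- which(site_per_frame == s)
    pos[idx, ] <- pos[idx, ] + .rnoise_trunc(length(idx), model$noise_sd[s])
  }
  coords <- array(NA_real_, c(n_frames, 1, 3))
  coords[, 1, ] <- pos
  atoms <- data.frame(name = "O1", resname = "OXY", resno = 1L,
                      chain = "A", element = "O",
                      stringsAsFactors = FALSE)
  traj <- trajectory(coords, atoms, times_ns = frame_times,
                     provenance = list(source = "synthgen:hopping",
                                       stride_ps = stride_ps,
                                       rng = RNGkind()[1], seed = seed))
  list(trajectory = traj, sites = as.integer(site_per_frame),
       frame_times_ns = frame_times)
}

#' Escape-time model
#'
#' One exponential escape time per independent run, right-censored at a
#' cutoff: runs whose drawn time reaches the cutoff are recorded as censored
#' at the cutoff. This mirrors the protocol of launching N independent
#' simulations with a particle placed at a reactive site and recording when
#' it leaves, with a fixed simulation length as the censoring time.
#'
#' @param mean_residence true mean residence time, ns (> 0).
#' @param cutoff censoring time, ns (> 0); `Inf` for no censoring.
#' @param n_runs number of independent runs (>= 1).
#' @return An object of class `escape_model`.
#' @export
escape_model <- function(mean_residence, cutoff = Inf, n_runs) {
  if (!.is_num1(mean_residence) || mean_residence <= 0)
    .stopf("mean_residence must be > 0")
  if (length(cutoff) != 1 || is.na(cutoff) || cutoff <= 0)
    .stopf("cutoff must be > 0 (possibly Inf)")
  if (!.is_count(n_runs)) .stopf("n_runs must be a positive integer")
  structure(list(mean_residence = mean_residence, cutoff = cutoff,
                 n_runs = as.integer(n_runs)),
            class = "escape_model")
}

#' Simulate censored escape events
#'
#' @param model an [escape_model()].
#' @param seed integer seed; if non-NULL, `set.seed(seed)` is called.
#' @return An [event_table()] with one row per run.
#' @export
simulate_escape_events <- function(model, seed = NULL) {
  stopifnot(inherits(model, "escape_model"))
  if (!is.null(seed)) set.seed(seed)
  t_raw <- rexp(model$n_runs, rate = 1 / model$mean_residence)
  censored <- t_raw >= model$cutoff
  duration <- ifelse(censored, model$cutoff, t_raw)
  event_table(data.frame(run_id = seq_len(model$n_runs),
                         duration_ns = duration,
                         censored = censored,
                         stringsAsFactors = FALSE),
              cutoff = model$cutoff)
}

#' Rotamer-switching model
#'
#' A hidden two-state chain between the plus (+60 deg) and trans (180 deg)
#' chi1 modes, with switching rates that may differ when the coupled region
#' is occupied by the gas particle. Emitted angles are the hidden mode plus
#' von Mises circular noise. The minus mode (-60 deg) is part of the fixed
#' classification partition but is not populated by the two-state chain,
#' matching a side chain whose minus rotamer is essentially unvisited.
#'
#' @param mode_angles named numeric, the three chi1 modes in degrees
#'   (default +60 / 180 / -60).
#' @param kappa von Mises concentration of the emission noise. The default
#'   (33) gives a circular spread of about 10 degrees per lobe.
#' @param switch_rates length-2 numeric `c(plus_to_trans, trans_to_plus)` in
#'   ns^-1, used on unoccupied frames.
#' @param occupied_switch_rates like `switch_rates`, used on frames where the
#'   coupled region is occupied; defaults to `switch_rates` (no coupling).
#' @return An object of class `rotamer_model`.
#' @export
rotamer_model <- function(mode_angles = c(plus = 60, trans = 180, minus = -60),
                          kappa = 33,
                          switch_rates = c(plus_to_trans = 1, trans_to_plus = 1),
                          occupied_switch_rates = NULL) {
  if (length(mode_angles) != 3 || anyNA(mode_angles))
    .stopf("mode_angles must be three finite angles")
  if (is.null(names(mode_angles)))
    names(mode_angles) <- c("plus", "trans", "minus")
  if (length(kappa) != 1 || is.na(kappa) || kappa < 0)
    .stopf("kappa must be >= 0 (Inf allowed for noiseless modes)")
  chk <- function(r, what) {
    if (length(r) != 2 || anyNA(r) || any(r < 0))
      .stopf("%s must be two non-negative rates (ns^-1)", what)
    as.numeric(r)
  }
  switch_rates <- chk(switch_rates, "switch_rates")
  occupied_switch_rates <- if (is.null(occupied_switch_rates)) switch_rates
    else chk(occupied_switch_rates, "occupied_switch_rates")
  structure(list(mode_angles = mode_angles, kappa = kappa,
                 switch_rates = switch_rates,
                 occupied_switch_rates = occupied_switch_rates),
            class = "rotamer_model")
}

## von Mises sampler (Best & Fisher 1979 rejection scheme), radians about 0.
.rvonmises <- function(n, kappa) {
  if (!is.finite(kappa)) return(rep(0, n))
  if (kappa == 0) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1
    }
  }
  out
}

#' Simulate an occupancy-coupled chi1 rotamer series
#'
#' The hidden plus/trans chain is propagated frame-to-frame with the exact
#' two-state transition probabilities for the rates in force on that frame
#' (occupied vs unoccupied), i.e. the rates are treated as piecewise constant
#' at frame resolution. Emitted chi1 values are the hidden mode plus von
#' Mises noise, wrapped to (-180, 180].
#'
#' @param model a [rotamer_model()].
#' @param occupancy_series logical vector, one entry per frame: is the
#'   coupled region occupied by the gas particle on that frame?
#' @param stride_ps frame spacing, ps.
#' @param seed integer seed; if non-NULL, `set.seed(seed)` is called.
#' @param replica replica id recorded in the output.
#' @return A [rotamer_series()] data frame with the true hidden state in
#'   column `hidden`.
#' @export
simulate_rotamer_series <- function(model, occupancy_series, stride_ps = 50,
                                    seed = NULL, replica = 1L) {
  stopifnot(inherits(model, "rotamer_model"))
  if (length(occupancy_series) == 0)
    .stopf("occupancy_series must have at least one frame")
  occupancy_series <- as.logical(occupancy_series)
  if (anyNA(occupancy_series)) .stopf("occupancy_series must be TRUE/FALSE")
  if (!is.null(seed)) set.seed(seed)
  n <- length(occupancy_series)
  dt <- stride_ps / 1000

  rates_for <- function(occ) if (occ) model$occupied_switch_rates else
    model$switch_rates
  ## initial state from the stationary law of the first frame's rates
  r0 <- rates_for(occupancy_series[1])
  p_trans0 <- if (sum(r0) > 0) r0[1] / sum(r0) else 0.5
  state <- integer(n)  # 1 = plus, 2 = trans
  state[1] <- if (runif(1) < p_trans0) 2L else 1L
  u <- runif(n)
  for (i in seq_len(n - 1)) {
    r <- rates_for(occupancy_series[i])
    k12 <- r[1]; k21 <- r[2]; ks <- k12 + k21
    if (ks == 0) { state[i + 1] <- state[i]; next }
    decay <- exp(-ks * dt)
    p12 <- k12 / ks * (1 - decay)  # plus -> trans over one frame
    p21 <- k21 / ks * (1 - decay)  # trans -> plus
    flip <- if (state[i] == 1L) u[i] < p12 else u[i] < p21
    state[i + 1] <- if (flip) 3L - state[i] else state[i]
  }
  modes <- c(model$mode_angles[["plus"]], model$mode_angles[["trans"]])
  chi1 <- .wrap180(modes[state] + .rvonmises(n, model$kappa) * 180 / pi)
  out <- rotamer_series(time_ns = (seq_len(n) - 1) * dt, chi1_deg = chi1,
                        replica = replica)
  out$hidden <- c("plus", "trans")[state]
  out
}

#' Build a labelled ligand-plus-diatomic structure fixture
#'
#' Constructs a planar six-membered carbon ring (atoms C1..C6, residue MQO)
#' in the z = 0 plane with the atom named C2 at the origin, and a diatomic
#' O1-O2 (residue OXY) underneath it, positioned so that the signed dihedral
#' C4-C2-O2-O1 equals `phi` exactly and the distance from O2 to the ring
#' plane equals `plane_offset` exactly. Used to validate the geometry
#' descriptors by construction.
#'
#' @param phi requested dihedral C4-C2-O2-O1, degrees in \[-180, 180\].
#' @param plane_offset requested distance (> 0) from O2 to the ring plane,
#'   Angstrom.
#' @return A `structure_model` data frame (see [structure_model()]).
#' @export
make_fixture_complex <- function(phi, plane_offset = 3.2) {
  if (!.is_num1(phi) || abs(phi) > 180) .stopf("phi must be in [-180, 180]")
  if (!.is_num1(plane_offset) || plane_offset <= 0)
    .stopf("plane_offset must be > 0")
  ctr <- c(-0.7, 1.4 * sqrt(3) / 2, 0)
  ang <- (-120 + 60 * (0:5)) * pi / 180
  ring <- cbind(ctr[1] + 1.4 * cos(ang), ctr[2] + 1.4 * sin(ang), 0)
  ## vertex 2 (name C2) sits at the origin, vertex 4 (name C4) at (0, 2.425, 0)
  beta <- (90 + phi) * pi / 180
  o2 <- c(0, 0, -plane_offset)
  o1 <- o2 + c(cos(beta), sin(beta), -0.5)
  structure_model(data.frame(
    name = c(paste0("C", 1:6), "O2", "O1"),
    resname = c(rep("MQO", 6), "OXY", "OXY"),
    resno = c(rep(1L, 6), 2L, 2L),
    chain = "A",
    element = c(rep("C", 6), "O", "O"),
    x = c(ring[, 1], o2[1], o1[1]),
    y = c(ring[, 2], o2[2], o1[2]),
    z = c(ring[, 3], o2[3], o1[3]),
    stringsAsFactors = FALSE))
}

#' Build a serine-like side-chain fixture with an exact chi1
#'
#' Places atoms N, CA, CB, OG so that the signed dihedral N-CA-CB-OG equals
#' `chi1` exactly. Used to validate chi1 computation by construction.
#'
#' @param chi1 requested dihedral, degrees in \[-180, 180\].
#' @param resno,chain residue number and chain of the fixture residue.
#' @return A `structure_model` data frame.
#' @export
make_fixture_sidechain <- function(chi1, resno = 101L, chain = "A") {
  if (!.is_num1(chi1) || abs(chi1) > 180) .stopf("chi1 must be in [-180, 180]")
  beta <- (90 + chi1) * pi / 180
  cb <- c(0, 0, -1.53)
  og <- cb + c(cos(beta), sin(beta), -0.7)
  structure_model(data.frame(
    name = c("N", "CA", "CB", "OG"),
    resname = "SER", resno = as.integer(resno), chain = chain,
    element = c("N", "C", "C", "O"),
    x = c(0, 0, cb[1], og[1]),
    y = c(1.47, 0, cb[2], og[2]),
    z = c(0, 0, cb[3], og[3]),
    stringsAsFactors = FALSE))
}

#' Simulate a fluctuating multi-atom trajectory
#'
#' Generates frames of a reference structure with independent isotropic
#' Gaussian fluctuation per atom, optionally composed with a random global
#' rigid rototranslation per frame. Used to exercise superposition and RMSF:
#' after superposition, the expected RMSF of an atom with per-coordinate
#' spread `sd` is `sqrt(3) * sd`.
#'
#' @param ref_coords numeric (n_atoms x 3) reference coordinates, Angstrom.
#' @param fluct_sd per-atom isotropic spread (scalar or per atom), Angstrom.
#' @param n_frames number of frames (>= 2).
#' @param stride_ps frame spacing, ps.
#' @param rigid_motion apply a random global rototranslation per frame?
#' @param seed integer seed; if non-NULL, `set.seed(seed)` is called.
#' @param atoms optional atom table (see [trajectory()]); defaults to CA
#'   pseudo-atoms.
#' @return A [trajectory()].
#' @export
simulate_fluctuation_trajectory <- function(ref_coords, fluct_sd, n_frames,
                                            stride_ps = 50,
                                            rigid_motion = TRUE, seed = NULL,
                                            atoms = NULL) {
  ref_coords <- rbind(ref_coords)
  n_atoms <- nrow(ref_coords)
  stopifnot(ncol(ref_coords) == 3, n_frames >= 2)
  fluct_sd <- rep_len(fluct_sd, n_atoms)
  if (!is.null(seed)) set.seed(seed)
  coords <- array(NA_real_, c(n_frames, n_atoms, 3))
  for (f in seq_len(n_frames)) {
    x <- ref_coords + matrix(rnorm(3 * n_atoms), n_atoms, 3) * fluct_sd
    if (rigid_motion) {
      R <- .random_rotation()
      x <- x %*% t(R) + matrix(runif(3, -5, 5), n_atoms, 3, byrow = TRUE)
    }
    coords[f, , ] <- x
  }
  if (is.null(atoms))
    atoms <- data.frame(name = "CA", resname = "GLY",
                        resno = seq_len(n_atoms), chain = "A", element = "C",
                        stringsAsFactors = FALSE)
  trajectory(coords, atoms,
             times_ns = (seq_len(n_frames) - 1) * stride_ps / 1000,
             provenance = list(source = "synthgen:fluctuation",
                               stride_ps = stride_ps,
                               rng = RNGkind()[1], seed = seed))
}

## Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
.random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  R <- R %*% diag(sign(d))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
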