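## occupancy_map: where does the gas particle spend its time?
##
## Positions sampled on a stride are binned on a regular voxel grid; sites
## are 26-connected components above an iso level; free energies come from
## Boltzmann inversion of the occupancy probability, and barriers between
## sites from the minimax (bottleneck) path over unmasked voxels.

#' Regular voxel grid specification
#'
#' @param origin numeric length-3, Angstrom: position of the lower corner of
#'   the first voxel.
#' @param spacing voxel edge length, Angstrom (> 0). Default 0.5 Angstrom,
#'   the analysis scale of the occupancy maps.
#' @param dims integer length-3 voxel counts per axis.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin, spacing = 0.5, dims) {
  if (length(origin) != 3 || anyNA(origin)) .stopf("origin must be length 3")
  if (!.is_num1(spacing) || spacing <= 0) .stopf("spacing must be > 0")
  dims <- as.integer(dims)
  if (length(dims) != 3 || anyNA(dims) || any(dims < 1))
    .stopf("dims must be three positive integers")
  structure(list(origin = as.numeric(origin), spacing = spacing, dims = dims),
            class = "grid_spec")
}

#' Grid specification covering a set of points
#'
#' @param points numeric n x 3 matrix, Angstrom.
#' @param spacing voxel edge, Angstrom.
#' @param padding margin added around the bounding box, Angstrom.
#' @return A [grid_spec()].
#' @export
grid_spec_from_points <- function(points, spacing = 0.5, padding = spacing) {
  points <- rbind(points)
  lo <- apply(points, 2, min) - padding
  hi <- apply(points, 2, max) + padding
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing + 1e-9)))
  grid_spec(lo, spacing, dims)
}

## voxel (i,j,k) 1-based -> linear index and back
.vox_linear <- function(ijk, dims) {
  (ijk[, 1] - 1) + dims[1] * ((ijk[, 2] - 1) + dims[2] * (ijk[, 3] - 1)) + 1
}
.vox_ijk <- function(lin, dims) {
  lin0 <- lin - 1
  i <- lin0 %% dims[1]
  j <- (lin0 %/% dims[1]) %% dims[2]
  k <- lin0 %/% (dims[1] * dims[2])
  cbind(i + 1, j + 1, k + 1)
}
.vox_centers <- function(lin, grid) {
  ijk <- .vox_ijk(lin, grid$dims)
  sweep((ijk - 0.5) * grid$spacing, 2, grid$origin, "+")
}

## Positions -> voxel linear indices; NA for out-of-grid points.
.bin_positions <- function(pos, grid) {
  ijk <- floor(sweep(pos, 2, grid$origin, "-") / grid$spacing) + 1
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= grid$dims[1] &
        ijk[, 2] >= 1 & ijk[, 2] <= grid$dims[2] &
        ijk[, 3] >= 1 & ijk[, 3] <= grid$dims[3]
  out <- rep(NA_real_, nrow(pos))
  out[ok] <- .vox_linear(ijk[ok, , drop = FALSE], grid$dims)
  out
}

.new_density_grid <- function(grid, counts, prob, n_samples) {
  structure(list(origin = grid$origin, spacing = grid$spacing,
                 dims = grid$dims, counts = counts, prob = prob,
                 n_samples = n_samples),
            class = "density_grid")
}

#' Build a density grid directly from voxel values
#'
#' Mainly for constructing analytic reference grids: `values` are taken as
#' (unnormalized) occupancy weights and normalized to probabilities.
#'
#' @param grid a [grid_spec()].
#' @param values numeric array of dimension `grid$dims`, non-negative.
#' @param n_samples nominal sample count recorded on the grid.
#' @return A [density_grid()].
#' @export
density_grid_from_values <- function(grid, values, n_samples = sum(values)) {
  stopifnot(inherits(grid, "grid_spec"))
  values <- array(values, dim = grid$dims)
  if (any(values < 0) || any(!is.finite(values)))
    .stopf("values must be finite and non-negative")
  tot <- sum(values)
  if (tot <= 0) .stopf("all-zero grid")
  .new_density_grid(grid, values, values / tot, n_samples)
}

#' Accumulate an occupancy density grid from a trajectory
#'
#' Samples the selected particle positions every `sample_stride_ps` and
#' counts them per voxel; `prob` is counts over total samples. A sampled
#' position outside the grid is an error unless `clip = TRUE` (positions are
#' then dropped from the tally).
#'
#' @param traj a [trajectory()].
#' @param selection particle selection: atom indices or atom name(s).
#' @param grid a [grid_spec()].
#' @param sample_stride_ps sampling interval, ps; must be a multiple of the
#'   trajectory stride. Default 50 ps.
#' @param clip drop out-of-grid positions instead of erroring?
#' @return An object of class `density_grid`: origin/spacing/dims plus
#'   per-voxel `counts`, normalized `prob` (sums to 1) and `n_samples`.
#' @export
accumulate_density <- function(traj, selection, grid, sample_stride_ps = 50,
                               clip = FALSE) {
  stopifnot(inherits(traj, "trajectory"), inherits(grid, "grid_spec"))
  idx <- .select_atoms(traj, selection)
  keep <- .sampled_frames(traj, sample_stride_ps)
  pos <- do.call(rbind, lapply(idx, function(a) traj$coords[keep, a, ]))
  if (n_frames(traj) == 1) pos <- matrix(pos, ncol = 3)
  lin <- .bin_positions(pos, grid)
  if (anyNA(lin)) {
    if (!clip) .stopf("%d sampled position(s) outside the grid (set clip = TRUE to drop)",
                      sum(is.na(lin)))
    lin <- lin[!is.na(lin)]
  }
  counts <- array(tabulate(lin, nbins = prod(grid$dims)), dim = grid$dims)
  n <- sum(counts)
  if (n == 0) .stopf("no samples fell inside the grid")
  .new_density_grid(grid, counts, counts / n, n)
}

## Frames retained when sampling every sample_stride_ps.
.sampled_frames <- function(traj, sample_stride_ps) {
  if (n_frames(traj) == 1) return(1L)
  stride_ps <- trajectory_stride_ns(traj) * 1000
  k <- sample_stride_ps / stride_ps
  if (abs(k - round(k)) > 1e-6 || round(k) < 1)
    .stopf("sample_stride_ps (%g) must be a positive multiple of the frame stride (%g ps)",
           sample_stride_ps, stride_ps)
  seq(1L, n_frames(traj), by = as.integer(round(k)))
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %d x %d x %d voxels @ %.3g A, %s samples\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              format(x$n_samples)))
  invisible(x)
}

## 26-neighbourhood offsets (excluding self)
.offsets26 <- local({
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

## Adjacency among a set of voxel linear indices; returns a 2-column matrix
## of edges in *positions within `lin`*.
.voxel_edges <- function(lin, dims) {
  id <- integer(prod(dims))
  id[lin] <- seq_along(lin)
  ijk <- .vox_ijk(lin, dims)
  edges <- list()
  for (r in seq_len(nrow(.offsets26))) {
    off <- .offsets26[r, ]
    nb <- sweep(ijk, 2, off, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nb_lin <- .vox_linear(nb[ok, , drop = FALSE], dims)
    hit <- id[nb_lin] > 0
    if (!any(hit)) next
    a <- which(ok)[hit]
    b <- id[nb_lin[hit]]
    keep <- a < b  # each undirected edge once
    if (any(keep)) edges[[length(edges) + 1]] <- cbind(a[keep], b[keep])
  }
  if (length(edges) == 0) matrix(integer(), 0, 2) else do.call(rbind, edges)
}

#' Detect occupancy sites as 26-connected voxel clusters
#'
#' Voxels whose probability density (probability per cubic Angstrom,
#' `prob / spacing^3`) reaches `iso_level` are grouped into 26-connected
#' components; components with fewer than `min_voxels` voxels are dropped.
#' Clusters are returned sorted by probability mass, labelled with Roman
#' numerals in that order.
#'
#' @param grid a [density_grid()].
#' @param iso_level probability density threshold, A^-3 (> 0).
#' @param min_voxels minimum cluster size in voxels.
#' @return A list of `site_cluster` objects (possibly empty); each has
#'   `label`, `voxels` (linear indices), `center` (probability-weighted,
#'   Angstrom), `volume_A3` and `mass`. See [site_table()].
#' @export
detect_sites <- function(grid, iso_level, min_voxels = 1) {
  stopifnot(inherits(grid, "density_grid"))
  if (!.is_num1(iso_level) || iso_level <= 0) .stopf("iso_level must be > 0")
  dens <- grid$prob / grid$spacing^3
  lin <- which(dens >= iso_level & grid$counts > 0)
  if (length(lin) == 0) return(list())
  edges <- .voxel_edges(lin, grid$dims)
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  sites <- lapply(split(seq_along(lin), comp), function(members) {
    vox <- lin[members]
    if (length(vox) < min_voxels) return(NULL)
    p <- grid$prob[vox]
    ctr <- colSums(.vox_centers(vox, grid) * p) / sum(p)
    list(voxels = sort(vox), center = ctr,
         volume_A3 = length(vox) * grid$spacing^3, mass = sum(p))
  })
  sites <- Filter(Negate(is.null), sites)
  if (length(sites) == 0) return(list())
  sites <- sites[order(vapply(sites, `[[`, 0, "mass"), decreasing = TRUE)]
  for (i in seq_along(sites)) {
    sites[[i]]$label <- as.character(as.roman(i))
    class(sites[[i]]) <- "site_cluster"
  }
  sites
}

#' Tabulate detected sites
#'
#' @param sites list of site clusters from [detect_sites()].
#' @return data frame: label, n_voxels, volume_A3, mass, center x/y/z.
#' @export
site_table <- function(sites) {
  if (length(sites) == 0)
    return(data.frame(label = character(), n_voxels = integer(),
                      volume_A3 = numeric(), mass = numeric(),
                      x = numeric(), y = numeric(), z = numeric()))
  do.call(rbind, lapply(sites, function(s)
    data.frame(label = s$label, n_voxels = length(s$voxels),
               volume_A3 = s$volume_A3, mass = s$mass,
               x = s$center[1], y = s$center[2], z = s$center[3],
               stringsAsFactors = FALSE)))
}

#' Boltzmann-invert an occupancy grid to free energies
#'
#' G(v) = -kB * T * ln(p(v) / p_max) per voxel with at least one count;
#' zero-count voxels are masked (NA), never imputed. The global minimum of
#' the unmasked values is 0 by construction.
#'
#' @param grid a [density_grid()].
#' @param temperature K (> 0).
#' @return An object of class `free_energy_grid`: origin/spacing/dims,
#'   `values` (kcal/mol, NA where masked), `mask` (TRUE = masked) and
#'   `temperature`.
#' @export
boltzmann_invert <- function(grid, temperature = 300) {
  stopifnot(inherits(grid, "density_grid"))
  if (!.is_num1(temperature) || temperature <= 0)
    .stopf("temperature must be > 0")
  if (sum(grid$counts) == 0) .stopf("all-zero grid")
  mask <- grid$counts == 0
  p <- grid$prob
  pmax_ <- max(p)
  values <- array(NA_real_, dim = grid$dims)
  values[!mask] <- -.kB * temperature * log(p[!mask] / pmax_)
  structure(list(origin = grid$origin, spacing = grid$spacing,
                 dims = grid$dims, values = values, mask = mask,
                 temperature = temperature),
            class = "free_energy_grid")
}

#' Reweight biased samples into an unbiased occupancy grid
#'
#' For bias-accelerated sampling (metadynamics-style), each sampled position
#' is weighted by exp(+bias / kB T) of its frame and the per-voxel weights
#' are renormalized into probabilities. With zero or constant bias this
#' reduces exactly to [accumulate_density()].
#'
#' @param traj a [trajectory()].
#' @param bias_kcal per-frame bias energy, kcal/mol; length must equal the
#'   frame count, all values finite.
#' @param grid a [grid_spec()].
#' @param temperature K.
#' @param selection particle selection (default the first atom).
#' @param sample_stride_ps sampling interval, ps.
#' @param clip drop out-of-grid positions instead of erroring?
#' @return A [density_grid()] whose `counts` hold the (relative) weights.
#' @export
reweight_biased <- function(traj, bias_kcal, grid, temperature = 300,
                            selection = 1L, sample_stride_ps = 50,
                            clip = FALSE) {
  stopifnot(inherits(traj, "trajectory"), inherits(grid, "grid_spec"))
  if (length(bias_kcal) != n_frames(traj))
    .stopf("bias length (%d) does not match frame count (%d)",
           length(bias_kcal), n_frames(traj))
  if (any(!is.finite(bias_kcal))) .stopf("bias energies must be finite")
  idx <- .select_atoms(traj, selection)
  keep <- .sampled_frames(traj, sample_stride_ps)
  w_frame <- exp((bias_kcal[keep] - max(bias_kcal[keep])) /
                 (.kB * temperature))
  pos <- do.call(rbind, lapply(idx, function(a) traj$coords[keep, a, ]))
  w <- rep(w_frame, times = length(idx))
  lin <- .bin_positions(pos, grid)
  if (anyNA(lin)) {
    if (!clip) .stopf("%d sampled position(s) outside the grid (set clip = TRUE to drop)",
                      sum(is.na(lin)))
    w <- w[!is.na(lin)]
    lin <- lin[!is.na(lin)]
  }
  wsum <- rowsum(w, lin)
  counts <- array(0, dim = grid$dims)
  counts[as.integer(rownames(wsum))] <- wsum[, 1]
  .new_density_grid(grid, counts, counts / sum(counts), length(w))
}

#' Minimax barrier between two sites on a free-energy grid
#'
#' The barrier is the bottleneck of the best path: the smallest level L such
#' that the minimum-energy voxel of `site_a` and of `site_b` are joined by a
#' 26-connected path through unmasked voxels of free energy <= L, minus the
#' free energy at the `site_a` minimum. Computed by Kruskal-style activation
#' of voxels in increasing free energy with union-find connectivity.
#'
#' Optionally converts a pair of barriers into a Boltzmann probability
#' ratio; see [boltzmann_ratio()].
#'
#' @param fe a [free_energy_grid()].
#' @param site_a,site_b `site_cluster` objects (from [detect_sites()] on the
#'   source density grid) or integer vectors of voxel linear indices.
#' @param temperature K, used only for the ratio.
#' @param reference_barrier optional competing barrier, kcal/mol; when given,
#'   the result includes `ratio = exp(-(barrier - reference)/kBT)`.
#' @return list: `barrier_kcal` (relative to the site_a minimum),
#'   `saddle_kcal` (absolute bottleneck level), `from_kcal` (site_a
#'   minimum), and `ratio_vs_reference` (or NULL).
#' @export
barrier_and_ratio <- function(fe, site_a, site_b, temperature = 300,
                              reference_barrier = NULL) {
  stopifnot(inherits(fe, "free_energy_grid"))
  vox_of <- function(s) if (inherits(s, "site_cluster")) s$voxels else
    as.integer(s)
  va <- vox_of(site_a); vb <- vox_of(site_b)
  va <- va[!fe$mask[va]]; vb <- vb[!fe$mask[vb]]
  if (length(va) == 0 || length(vb) == 0)
    .stopf("both sites must contain unmasked voxels")
  a0 <- va[which.min(fe$values[va])]
  b0 <- vb[which.min(fe$values[vb])]
  lin <- which(!fe$mask)
  vals <- fe$values[lin]
  ord <- order(vals)
  lin <- lin[ord]; vals <- vals[ord]
  pos_in_lin <- integer(prod(fe$dims))
  pos_in_lin[lin] <- seq_along(lin)
  ia <- pos_in_lin[a0]; ib <- pos_in_lin[b0]

  parent <- seq_along(lin)
  uf_find <- function(i) {  # path halving; parent lives in this frame
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  active <- logical(length(lin))
  dims <- fe$dims
  ijk_all <- .vox_ijk(lin, dims)
  saddle <- NA_real_
  for (s in seq_along(lin)) {
    active[s] <- TRUE
    ijk <- ijk_all[s, ]
    nb <- sweep(.offsets26, 2, ijk, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (any(ok)) {
      nb_pos <- pos_in_lin[.vox_linear(nb[ok, , drop = FALSE], dims)]
      nb_pos <- nb_pos[nb_pos > 0]
      for (q in nb_pos[active[nb_pos]]) {
        ra <- uf_find(s); rb <- uf_find(q)
        if (ra != rb) parent[rb] <- ra
      }
    }
    if (active[ia] && active[ib] && uf_find(ia) == uf_find(ib)) {
      saddle <- vals[s]
      break
    }
  }
  if (is.na(saddle))
    .stopf("no finite path between the sites (disconnected mask)")
  from <- fe$values[a0]
  barrier <- saddle - from
  ratio <- if (is.null(reference_barrier)) NULL else
    boltzmann_ratio(barrier, reference_barrier, temperature)
  list(barrier_kcal = barrier, saddle_kcal = saddle, from_kcal = from,
       ratio_vs_reference = ratio)
}

#' Boltzmann probability ratio of two barriers
#'
#' `exp(-(b1 - b2) / kB T)`: how much more probable is crossing barrier `b1`
#' than barrier `b2` at temperature T, if crossing statistics are controlled
#' by the barrier heights alone. Barriers of 4.1 and 6.5 kcal/mol at 300 K
#' give a ratio of about 56 in favour of the lower one.
#'
#' @param b1,b2 barriers, kcal/mol.
#' @param temperature K.
#' @return numeric ratio (> 1 when b1 < b2).
#' @export
boltzmann_ratio <- function(b1, b2, temperature = 300) {
  if (!.is_num1(temperature) || temperature <= 0)
    .stopf("temperature must be > 0")
  exp(-(b1 - b2) / (.kB * temperature))
}
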