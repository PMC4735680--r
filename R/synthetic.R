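# Ground-truthed input generators: exact Helfrich surface sampler,
# umbrella-window Metropolis sampler, and a toy bilayer/cation builder.

#' Specification for a Helfrich surface ensemble
#'
#' @param kappa Bending modulus, J (> 0).
#' @param temperature Temperature, K.
#' @param L Patch edge, nm.
#' @param N Grid size (power of two).
#' @param n_frames Number of independent frames.
#' @param seed Integer seed.
#' @return A `helfrich_spec` object.
#' @export
helfrich_spec <- function(kappa = 22.6e-20, temperature = 303, L = 25,
                          N = 32, n_frames = 500, seed = 1) {
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0")
  if (bitwAnd(N, N - 1L) != 0L) stop("N must be a power of two")
  structure(list(kappa = kappa, temperature = temperature, L = L, N = N,
                 n_frames = n_frames, seed = as.integer(seed)),
            class = "helfrich_spec")
}

#' Sample thermally fluctuating membrane surfaces with known bending modulus
#'
#' Draws each independent Fourier mode of the height field as a complex
#' Gaussian with the Helfrich variance \eqn{\langle|\hat h_{\mathbf q}|^2
#' \rangle = k_BT/(A\kappa q^4)} (A = L^2, the same normalization as
#' [spectrum_2d()]), with Hermitian symmetry enforced so h(x, y) is real.
#' Frames are i.i.d. — this is exact sampling of the stated ensemble, not
#' dynamics, so the generator's kappa is ground truth with zero model
#' error. The q = 0 mode is zero (mean-centered surfaces).
#'
#' Implementation: white real Gaussian noise is Fourier transformed (which
#' yields Hermitian complex Gaussian modes of uniform variance) and each
#' mode is rescaled to its target standard deviation.
#'
#' @param spec A [helfrich_spec()].
#' @return List of [undulation_surface()] frames; attributes `spec` and
#'   `seed`.
#' @export
sample_helfrich_surfaces <- function(spec) {
  stopifnot(inherits(spec, "helfrich_spec"))
  N <- spec$N
  A <- spec$L^2
  dq <- 2 * pi / spec$L
  ki <- .mode_index(N)
  q2 <- outer((ki * dq)^2, (ki * dq)^2, `+`)
  kT <- .KB_J * spec$temperature
  target <- kT / (A * spec$kappa * q2^2) # <|h_q|^2>, nm^2; Inf at q = 0
  target[1, 1] <- 0
  scale <- N * sqrt(target) # white-noise modes have variance 1/N^2
  set.seed(spec$seed)
  lapply(seq_len(spec$n_frames), function(f) {
    g <- matrix(rnorm(N * N), N, N)
    hq <- fft(g) / N^2 * scale
    h <- Re(fft(hq, inverse = TRUE))
    s <- undulation_surface(h, spec$L, time = f - 1, leaflet = "upper")
    attr(s, "seed") <- spec$seed
    s
  }) -> frames
  attr(frames, "spec") <- spec
  attr(frames, "seed") <- spec$seed
  frames
}

#' Sample umbrella windows from an analytic potential
#'
#' Metropolis Monte Carlo from \eqn{\exp\{-[U(z) + w_j(z)]/k_BT\}} for each
#' harmonic window \eqn{w_j(z) = k(z - c_j)^2/2}. All windows advance as one
#' vectorized chain ensemble; burn-in is discarded and the chain thinned to
#' reduce autocorrelation. If the acceptance rate falls below 5% the step
#' size is halved and sampling restarts (up to 5 times) before failing.
#'
#' @param potential Vectorized function z (nm) -> kJ/mol.
#' @param centers Window centers, nm.
#' @param spring_k Spring constant, kJ/mol/nm^2 (scalar or per window).
#' @param n_per_window Retained samples per window.
#' @param temperature K.
#' @param seed Integer seed; fixed seed gives identical samples.
#' @param step Proposal standard deviation, nm; default tuned to the
#'   restraint width.
#' @param burn_in Discarded initial sweeps (default 1000).
#' @param thin Thinning stride (default 10).
#' @return List of [umbrella_window()] objects; attribute
#'   `acceptance_rate`.
#' @export
sample_umbrella_windows <- function(potential, centers, spring_k,
                                    n_per_window, temperature = 303,
                                    seed = 1, step = NULL, burn_in = 1000,
                                    thin = 10) {
  nw <- length(centers)
  k <- rep(spring_k, length.out = nw)
  kT <- .KB * temperature
  if (is.null(step))
    step <- ifelse(k > 0, pmin(2, sqrt(kT / k) * 2), 0.5)
  step <- rep(step, length.out = nw)
  u0 <- potential(centers)
  if (any(!is.finite(u0))) stop("potential not finite at window centers")

  for (attempt in 1:5) {
    set.seed(seed)
    z <- centers
    uz <- potential(z) + 0.5 * k * (z - centers)^2
    n_iter <- burn_in + n_per_window * thin
    acc <- 0
    out <- matrix(NA_real_, n_per_window, nw)
    kept <- 0L
    for (it in seq_len(n_iter)) {
      zp <- z + step * rnorm(nw)
      up <- potential(zp) + 0.5 * k * (zp - centers)^2
      a <- log(runif(nw)) < -(up - uz) / kT
      a[!is.finite(up)] <- FALSE
      z[a] <- zp[a]
      uz[a] <- up[a]
      acc <- acc + mean(a)
      if (it > burn_in && (it - burn_in) %% thin == 0) {
        kept <- kept + 1L
        out[kept, ] <- z
      }
    }
    rate <- acc / n_iter
    if (rate >= 0.05) break
    step <- step / 2
    if (attempt == 5)
      stop("Metropolis acceptance degenerate (", signif(rate, 2),
           ") even after step-size tuning")
  }
  windows <- lapply(seq_len(nw), function(j)
    umbrella_window(centers[j], k[j], out[, j], temperature))
  attr(windows, "acceptance_rate") <- rate
  attr(windows, "seed") <- seed
  windows
}

#' The analytic double-well test potential
#'
#' \eqn{U(z) = 4 (z^2 - 1)^2} kJ/mol: two minima at z = +/-1 nm separated by
#' a 4 kJ/mol barrier, the standard oracle for the WHAM round trip.
#'
#' @param z Position(s), nm.
#' @return kJ/mol.
#' @export
double_well_potential <- function(z) 4 * (z^2 - 1)^2

#' Specification for a toy bilayer construction
#'
#' @param lipids_per_leaflet Lipids in each leaflet.
#' @param area_per_lipid nm^2 (default 0.65, a fluid-phase
#'   phosphatidylcholine value).
#' @param n_cations Imidazolium cations.
#' @param inserted_fraction Length-2 numeric `(upper, lower)` in [0, 1]:
#'   fraction of the cations placed with their ring bead inside each
#'   leaflet; the remainder goes to the upper water slab (the one-sided
#'   exposure scenario).
#' @param tail_n Cation alkyl chain length (4 = butyl, 10 = decyl).
#' @param nacl_pairs Extra Na+/Cl- pairs in water.
#' @param lipid_tail_beads Beads per lipid tail (5 gives the 13-bead
#'   mapping).
#' @param seed Integer seed.
#' @return A `toy_bilayer_spec` object.
#' @export
toy_bilayer_spec <- function(lipids_per_leaflet = 64, area_per_lipid = 0.65,
                             n_cations = 0,
                             inserted_fraction = c(0, 0), tail_n = 4,
                             nacl_pairs = 0, lipid_tail_beads = 5,
                             seed = 1) {
  inserted_fraction <- rep(inserted_fraction, length.out = 2)
  if (any(inserted_fraction < 0 | inserted_fraction > 1))
    stop("inserted fractions must lie in [0, 1]")
  if (sum(inserted_fraction) > 1)
    stop("inserted fractions must sum to <= 1")
  if (lipids_per_leaflet < 1 || n_cations < 0 || nacl_pairs < 0)
    stop("counts must be non-negative (>= 1 lipid per leaflet)")
  structure(list(lipids_per_leaflet = as.integer(lipids_per_leaflet),
                 area_per_lipid = area_per_lipid,
                 n_cations = as.integer(n_cations),
                 inserted_fraction = inserted_fraction,
                 tail_n = as.integer(tail_n),
                 nacl_pairs = as.integer(nacl_pairs),
                 lipid_tail_beads = as.integer(lipid_tail_beads),
                 seed = as.integer(seed)),
            class = "toy_bilayer_spec")
}

.place_nonoverlapping <- function(n, Lx, Ly, zlo, zhi, occupied, min_dist,
                                  max_attempts = 1e4) {
  pts <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      p <- c(runif(1, 0, Lx), runif(1, 0, Ly), runif(1, zlo, zhi))
      if (nrow(occupied)) {
        dx <- abs(occupied[, 1] - p[1]); dx <- pmin(dx, Lx - dx)
        dy <- abs(occupied[, 2] - p[2]); dy <- pmin(dy, Ly - dy)
        dz <- occupied[, 3] - p[3]
        if (min(dx^2 + dy^2 + dz^2) < min_dist^2) next
      }
      ok <- TRUE
      break
    }
    if (!ok) stop("packing failure: no room after ", max_attempts,
                  " rejection attempts (density error)")
    pts[i, ] <- p
    occupied <- rbind(occupied, p)
  }
  list(points = pts, occupied = occupied)
}

#' Build a toy bilayer + cation configuration with known ground truth
#'
#' Places lipids on two opposing square lattices at the prescribed area per
#' lipid (tails inward), inserts the prescribed number of cations with
#' their ring beads between the midplane and the phosphate plane of each
#' leaflet, puts the remaining cations plus charge-balancing chloride and
#' any NaCl in the upper water slab with minimum-distance rejection, and
#' records the construction labels (leaflet of every lipid, insertion state
#' of every cation) as attribute `"ground_truth"`. Total charge is zero by
#' construction.
#'
#' @param spec A [toy_bilayer_spec()].
#' @param params A [parameter_set()] resolving all bead types (defaults to
#'   [example_parameter_set()]).
#' @return A [system_configuration()] with attributes `ground_truth`,
#'   `spec` and `seed`.
#' @export
build_toy_bilayer <- function(spec, params = example_parameter_set()) {
  stopifnot(inherits(spec, "toy_bilayer_spec"))
  set.seed(spec$seed)
  lt <- lipid_template(spec$lipid_tail_beads)
  ct <- cation_template(spec$tail_n)
  nl <- spec$lipids_per_leaflet
  n_side <- ceiling(sqrt(nl))
  L <- n_side * sqrt(spec$area_per_lipid)
  # phosphate plane sits one tail length above the midplane plus a 0.2 nm
  # clearance so opposing tail ends never overlap at construction
  d_ph <- 0.4 + 0.45 * spec$lipid_tail_beads + 0.2
  water_depth <- 3.0
  Lz <- 2 * (d_ph + max(lt$z_offsets)) + 2 * water_depth + 2
  zmid <- Lz / 2
  z_up <- zmid + d_ph
  z_lo <- zmid - d_ph

  sp <- L / n_side
  site <- expand.grid(ix = seq_len(n_side) - 1L, iy = seq_len(n_side) - 1L)
  site <- site[seq_len(nl), ]

  pos <- NULL
  top <- NULL
  gt_leaflet <- character(0)
  mol <- 0L
  for (leaf in c("upper", "lower")) {
    off <- if (leaf == "upper") c(sp / 4, sp / 4) else c(-sp / 4, -sp / 4)
    for (i in seq_len(nl)) {
      mol <- mol + 1L
      x <- (site$ix[i] + 0.5) * sp + off[1] + runif(1, -0.05, 0.05)
      y <- (site$iy[i] + 0.5) * sp + off[2] + runif(1, -0.05, 0.05)
      zoff <- if (leaf == "upper") lt$z_offsets else -lt$z_offsets
      zref <- if (leaf == "upper") z_up else z_lo
      nb <- length(lt$bead_types)
      # spread the two tails in x (0.4 nm apart, ~sigma) so no pair starts
      # on the steep repulsive wall
      dx <- rep(0, nb)
      tail1 <- 4:(3 + spec$lipid_tail_beads)
      tail2 <- (4 + spec$lipid_tail_beads):nb
      dx[tail1] <- -0.2; dx[tail2] <- 0.2
      pos <- rbind(pos, cbind(x + dx, y, zref + zoff))
      top <- rbind(top, data.frame(molecule_id = mol, species = lt$species,
                                   bead_type = lt$bead_types))
      gt_leaflet <- c(gt_leaflet, leaf)
    }
  }

  occupied <- pos
  n_up <- round(spec$inserted_fraction[1] * spec$n_cations)
  n_dn <- round(spec$inserted_fraction[2] * spec$n_cations)
  n_free <- spec$n_cations - n_up - n_dn
  gt_cation <- c(rep("upper", n_up), rep("lower", n_dn),
                 rep("none", n_free))
  cat_z <- list(c(zmid + 0.4, z_up - 0.4), c(z_lo + 0.4, zmid - 0.4),
                c(z_up + 1.0, z_up + water_depth))
  counts <- c(n_up, n_dn, n_free)
  ncb <- length(ct$bead_types)
  for (g in 1:3) {
    if (counts[g] == 0) next
    pl <- .place_nonoverlapping(counts[g], L, L, cat_z[[g]][1],
                                cat_z[[g]][2], occupied, 0.4)
    occupied <- pl$occupied
    for (i in seq_len(counts[g])) {
      mol <- mol + 1L
      p <- pl$points[i, ]
      # ring at the sampled point, tail extending toward the midplane for
      # inserted cations, downward (toward the interface) for free ones
      zdir <- if (g == 1) -1 else if (g == 2) 1 else -1
      zoff <- abs(ct$z_offsets) * zdir
      pos <- rbind(pos, cbind(p[1], p[2], p[3] + zoff))
      top <- rbind(top, data.frame(molecule_id = mol, species = ct$species,
                                   bead_type = ct$bead_types))
    }
  }

  n_cl <- spec$n_cations + spec$nacl_pairs
  n_na <- spec$nacl_pairs
  ion_bt <- c(rep("CL", n_cl), rep("NA", n_na))
  if (length(ion_bt)) {
    pl <- .place_nonoverlapping(length(ion_bt), L, L, z_up + 1.0,
                                z_up + water_depth, occupied, 0.35)
    for (i in seq_along(ion_bt)) {
      mol <- mol + 1L
      pos <- rbind(pos, matrix(pl$points[i, ], 1, 3))
      top <- rbind(top, data.frame(molecule_id = mol,
                                   species = if (ion_bt[i] == "CL") "CL"
                                   else "NA+",
                                   bead_type = ion_bt[i]))
    }
  }

  pos[, 1] <- pos[, 1] %% L
  pos[, 2] <- pos[, 2] %% L
  cfg <- system_configuration(pos, top, c(L, L, Lz))
  attr(cfg, "ground_truth") <- list(
    lipid_leaflet = gt_leaflet,
    cation_state = gt_cation,
    inserted_upper = n_up, inserted_lower = n_dn,
    lipids_per_leaflet = nl)
  attr(cfg, "spec") <- spec
  attr(cfg, "seed") <- spec$seed
  cfg
}

#' Initialize Maxwell-Boltzmann velocities
#'
#' @param config A [system_configuration()].
#' @param params A [parameter_set()] (for the bead masses).
#' @param temperature K.
#' @param seed Integer seed.
#' @return The configuration with velocities drawn at `temperature` and the
#'   center-of-mass drift removed.
#' @export
initialize_velocities <- function(config, params, temperature = 303,
                                  seed = 1) {
  set.seed(seed)
  ti <- .type_index(config, params) + 1L
  m <- params$tables$mass[ti]
  n <- nrow(config$positions)
  v <- matrix(rnorm(3 * n), n, 3) * sqrt(.KB * temperature / m)
  p <- colSums(v * m)
  v <- sweep(v, 2, p / sum(m)) # remove center-of-mass drift
  config$velocities <- v
  config
}
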