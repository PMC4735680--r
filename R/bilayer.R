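# Headline observables: leaflet assignment, inserted-cations-per-lipid
# accounting, leaflet height surfaces, undulation spectra and Helfrich
# bending-modulus fits.

#' Construct an undulation surface
#'
#' @param h N x N height grid, nm (N a power of two), mean-centered.
#' @param L Box edge, nm (square membrane patch).
#' @param time Frame time, ps.
#' @param leaflet `"upper"` or `"lower"`.
#' @return An `undulation_surface` object.
#' @export
undulation_surface <- function(h, L, time = NA_real_, leaflet = "upper") {
  h <- as.matrix(h)
  N <- nrow(h)
  if (ncol(h) != N) stop("height grid must be square")
  if (bitwAnd(N, N - 1L) != 0L) stop("grid size must be a power of two")
  if (any(!is.finite(h))) stop("height grid contains non-finite cells")
  structure(list(h = h, L = L, time = time, leaflet = leaflet),
            class = "undulation_surface")
}

# Extract phosphate / cation-ring bead rows. Roles come from the parameter
# set when given; otherwise the conventional type names PH / RG are used.
.role_beads <- function(config, role, params = NULL,
                        fallback = c("lipid-phosphate" = "PH",
                                     "cation-ring" = "RG")) {
  bt <- config$topology$bead_type
  if (!is.null(params)) {
    roles <- vapply(params$bead_types, `[[`, "", "role")
    which(bt %in% names(roles)[roles == role])
  } else {
    which(bt == fallback[[role]])
  }
}

# Bin scattered (x, y, z) onto an N x N periodic grid; average duplicates,
# fill empty cells by iterative (Jacobi) 4-neighbor averaging.
.grid_surface <- function(x, y, z, Lx, Ly, N, max_empty_frac = 0.5) {
  ix <- floor((x %% Lx) / Lx * N) + 1L
  iy <- floor((y %% Ly) / Ly * N) + 1L
  ix[ix > N] <- N; iy[iy > N] <- N
  g <- matrix(NA_real_, N, N)
  cnt <- matrix(0, N, N)
  for (k in seq_along(z)) {
    if (cnt[ix[k], iy[k]] == 0) g[ix[k], iy[k]] <- 0
    g[ix[k], iy[k]] <- g[ix[k], iy[k]] + z[k]
    cnt[ix[k], iy[k]] <- cnt[ix[k], iy[k]] + 1
  }
  g[cnt > 0] <- g[cnt > 0] / cnt[cnt > 0]
  frac_empty <- mean(cnt == 0)
  if (frac_empty > max_empty_frac)
    stop(sprintf(
      "%.0f%% of grid cells empty; reduce the grid size N", 100 * frac_empty))
  up <- function(m) m[c(N, seq_len(N - 1)), , drop = FALSE]
  dn <- function(m) m[c(seq_len(N - 1) + 1, 1), , drop = FALSE]
  lf <- function(m) m[, c(N, seq_len(N - 1)), drop = FALSE]
  rt <- function(m) m[, c(seq_len(N - 1) + 1, 1), drop = FALSE]
  while (anyNA(g)) {
    filled <- !is.na(g)
    gz <- g; gz[!filled] <- 0
    fn <- filled + 0
    s <- up(gz) + dn(gz) + lf(gz) + rt(gz)
    n <- up(fn) + dn(fn) + lf(fn) + rt(fn)
    new <- is.na(g) & n > 0
    g[new] <- s[new] / n[new]
  }
  g
}

# bilinear-free cell lookup of a grid surface at scattered (x, y)
.grid_at <- function(g, x, y, Lx, Ly) {
  N <- nrow(g)
  ix <- floor((x %% Lx) / Lx * N) + 1L
  iy <- floor((y %% Ly) / Ly * N) + 1L
  ix[ix > N] <- N; iy[iy > N] <- N
  g[cbind(ix, iy)]
}

#' Assign lipids to bilayer leaflets
#'
#' Starts from a global-mean split of the phosphate z coordinates, builds
#' smoothed upper and lower candidate surfaces on a coarse periodic grid,
#' and re-assigns each lipid by the sign of its phosphate height relative to
#' the grid-local midplane (the average of the two candidate surfaces). One
#' refinement iteration from the global split; deterministic. The grid-local
#' midplane handles strongly bent bilayers; `method = "global"` uses the
#' global mean only.
#'
#' @param config A [system_configuration()] frame with the bilayer roughly
#'   centered in z (not wrapped across the boundary).
#' @param params Optional [parameter_set()] used to resolve bead roles;
#'   otherwise phosphate beads are those typed `"PH"`.
#' @param grid_n Coarse grid size for the local midplane (default 8).
#' @param method `"local"` (default) or `"global"`.
#' @return A `leaflet_assignment`: `lipid_ids`, `leaflet` (factor
#'   upper/lower per lipid), `phosphate_bead` (bead index per lipid),
#'   `upper_surface`, `lower_surface`, `midplane` (grid_n x grid_n absolute
#'   z grids, nm), `grid_n`, `box`.
#' @export
assign_leaflets <- function(config, params = NULL, grid_n = 8,
                            method = c("local", "global")) {
  method <- match.arg(method)
  ph <- .role_beads(config, "lipid-phosphate", params)
  if (length(ph) < 2) stop("need >= 2 lipids with phosphate beads")
  lip_id <- config$topology$molecule_id[ph]
  if (anyDuplicated(lip_id)) stop("multiple phosphate beads per lipid")
  x <- config$positions[ph, 1]; y <- config$positions[ph, 2]
  z <- config$positions[ph, 3]
  Lx <- config$box[1]; Ly <- config$box[2]
  upper <- z >= mean(z)
  if (all(upper) || !any(upper))
    stop("degenerate bilayer: all lipids on one side of the midplane")
  if (method == "local") {
    # refine from the global split until the labels stop changing (a
    # single pass suffices for moderate bending; deep folds need a few)
    for (iter in 1:10) {
      gu <- .grid_surface(x[upper], y[upper], z[upper], Lx, Ly, grid_n,
                          max_empty_frac = 1)
      gl <- .grid_surface(x[!upper], y[!upper], z[!upper], Lx, Ly, grid_n,
                          max_empty_frac = 1)
      mid <- (gu + gl) / 2
      new_upper <- z >= .grid_at(mid, x, y, Lx, Ly)
      if (all(new_upper) || !any(new_upper))
        stop("degenerate bilayer: all lipids on one side of the midplane")
      changed <- any(new_upper != upper)
      upper <- new_upper
      if (!changed) break
    }
  } else {
    mid <- matrix(mean(z), grid_n, grid_n)
  }
  gu <- .grid_surface(x[upper], y[upper], z[upper], Lx, Ly, grid_n,
                      max_empty_frac = 1)
  gl <- .grid_surface(x[!upper], y[!upper], z[!upper], Lx, Ly, grid_n,
                      max_empty_frac = 1)
  structure(list(lipid_ids = lip_id,
                 leaflet = factor(ifelse(upper, "upper", "lower"),
                                  levels = c("upper", "lower")),
                 phosphate_bead = ph,
                 upper_surface = gu, lower_surface = gl,
                 midplane = (gu + gl) / 2,
                 grid_n = grid_n, box = config$box),
            class = "leaflet_assignment")
}

#' Count inserted cations per leaflet
#'
#' A cation is inserted in the upper leaflet iff its ring bead lies between
#' the grid-local midplane (inclusive: the boundary is closed on the upper
#' side, the documented tie-break) and the local upper phosphate surface
#' (inclusive); symmetrically for the lower leaflet with an open bound at
#' the midplane. Ratios are counts divided by the number of lipids in that
#' leaflet.
#'
#' @param config A [system_configuration()] frame.
#' @param assignment A [assign_leaflets()] result for the same frame.
#' @param params Optional [parameter_set()] for role resolution (ring beads
#'   default to type `"RG"`).
#' @param time Frame time, ps.
#' @return One-row data frame with columns `time_ps`, `inserted_upper`,
#'   `inserted_lower`, `lipids_upper`, `lipids_lower`, `ratio_upper`,
#'   `ratio_lower`.
#' @export
count_inserted_cations <- function(config, assignment, params = NULL,
                                   time = NA_real_) {
  rg <- .role_beads(config, "cation-ring", params)
  Lx <- config$box[1]; Ly <- config$box[2]
  nu <- sum(assignment$leaflet == "upper")
  nl <- sum(assignment$leaflet == "lower")
  iu <- il <- 0L
  if (length(rg)) {
    x <- config$positions[rg, 1]; y <- config$positions[rg, 2]
    z <- config$positions[rg, 3]
    mid <- .grid_at(assignment$midplane, x, y, Lx, Ly)
    us <- .grid_at(assignment$upper_surface, x, y, Lx, Ly)
    ls <- .grid_at(assignment$lower_surface, x, y, Lx, Ly)
    iu <- sum(z >= mid & z <= us)
    il <- sum(z < mid & z >= ls)
  }
  data.frame(time_ps = time, inserted_upper = iu, inserted_lower = il,
             lipids_upper = nu, lipids_lower = nl,
             ratio_upper = iu / nu, ratio_lower = il / nl)
}

#' Build an insertion time series over trajectory frames
#'
#' @param frames List of [system_configuration()] frames.
#' @param params Optional [parameter_set()].
#' @param grid_n Midplane grid size passed to [assign_leaflets()].
#' @param times Frame times, ps (defaults to the frames' `time` attributes
#'   or the frame index).
#' @return An `insertion_series` object.
#' @export
insertion_series_from_frames <- function(frames, params = NULL, grid_n = 8,
                                         times = NULL) {
  if (is.null(times)) {
    times <- vapply(seq_along(frames), function(i) {
      t <- attr(frames[[i]], "time")
      if (is.null(t) || is.na(t)) as.numeric(i - 1) else t
    }, 0)
  }
  rows <- lapply(seq_along(frames), function(i) {
    a <- assign_leaflets(frames[[i]], params, grid_n = grid_n)
    count_inserted_cations(frames[[i]], a, params, time = times[i])
  })
  df <- do.call(rbind, rows)
  structure(list(time = df$time_ps, inserted_upper = df$inserted_upper,
                 inserted_lower = df$inserted_lower,
                 lipids_upper = df$lipids_upper,
                 lipids_lower = df$lipids_lower,
                 ratio_upper = df$ratio_upper,
                 ratio_lower = df$ratio_lower),
            class = "insertion_series")
}

#' Detect an insertion saturation plateau
#'
#' The plateau is the mean ratio over the final `window` frames, accepted
#' only if the slope of a linear fit over that window is statistically zero
#' (|slope| below `slope_z` standard errors; the default 1.96 is the
#' conventional 95% criterion — a 1-SE rule would reject a true plateau
#' about a third of the time by construction). The onset is the first
#' frame whose ratio comes within 5% of the plateau.
#'
#' @param series An `insertion_series`.
#' @param window Plateau window length in frames; the series must be at
#'   least twice as long.
#' @param leaflet `"upper"` (default) or `"lower"`.
#' @param slope_z Acceptance threshold in units of the slope's standard
#'   error (default 1.96).
#' @return List with `saturated` (logical), `saturation` (ratio, `NA` when
#'   undefined), `onset_frame` (1-based), `onset_time`, `slope`,
#'   `slope_se`.
#' @export
detect_saturation <- function(series, window, leaflet = c("upper", "lower"),
                              slope_z = 1.96) {
  leaflet <- match.arg(leaflet)
  r <- if (leaflet == "upper") series$ratio_upper else series$ratio_lower
  n <- length(r)
  if (n < 2 * window) stop("series must be at least twice the window")
  tail_idx <- (n - window + 1):n
  rv <- r[tail_idx]
  if (var(rv) == 0) {
    slope <- 0; se <- 0; flat <- TRUE
  } else {
    # slope and its standard error by hand (avoids lm's perfect-fit
    # warnings on noiseless series)
    tc <- tail_idx - mean(tail_idx)
    sxx <- sum(tc^2)
    slope <- sum(tc * rv) / sxx
    res <- rv - mean(rv) - slope * tc
    se <- sqrt(sum(res^2) / (window - 2) / sxx)
    flat <- abs(slope) < slope_z * se
  }
  if (!flat)
    return(list(saturated = FALSE, saturation = NA_real_,
                onset_frame = NA_integer_, onset_time = NA_real_,
                slope = unname(slope), slope_se = unname(se)))
  plateau <- mean(rv)
  onset <- which(abs(r - plateau) <= 0.05 * abs(plateau))[1]
  if (plateau == 0) onset <- which(r == 0)[1]
  list(saturated = TRUE, saturation = plateau,
       onset_frame = onset, onset_time = series$time[onset],
       slope = unname(slope), slope_se = unname(se))
}

#' Reconstruct a leaflet height surface
#'
#' Bins the leaflet's phosphate z coordinates by (x, y) into an N x N
#' periodic grid, averages duplicates, fills empty cells by iterative
#' nearest-neighbor averaging, and subtracts the surface mean.
#'
#' @param config A [system_configuration()] frame.
#' @param assignment A [assign_leaflets()] result.
#' @param N Grid size, power of two (default 32).
#' @param leaflet `"upper"` or `"lower"`.
#' @param params Optional [parameter_set()].
#' @param time Frame time, ps.
#' @return An [undulation_surface()].
#' @export
reconstruct_surface <- function(config, assignment, N = 32,
                                leaflet = c("upper", "lower"),
                                params = NULL, time = NA_real_) {
  leaflet <- match.arg(leaflet)
  if (bitwAnd(N, N - 1L) != 0L) stop("N must be a power of two")
  sel <- assignment$leaflet == leaflet
  if (!any(sel)) stop("no lipids in the ", leaflet, " leaflet")
  ph <- assignment$phosphate_bead[sel]
  g <- .grid_surface(config$positions[ph, 1], config$positions[ph, 2],
                     config$positions[ph, 3], config$box[1], config$box[2],
                     N)
  undulation_surface(g - mean(g), config$box[1], time = time,
                     leaflet = leaflet)
}

# fftfreq-style integer mode indices for an N grid
.mode_index <- function(N) {
  k <- 0:(N - 1)
  ifelse(k <= N / 2, k, k - N)
}

#' Two-dimensional undulation mode intensities
#'
#' Per-mode spectral intensity \eqn{S(\mathbf q) = A \langle |\hat h_{\mathbf
#' q}|^2 \rangle} with \eqn{\hat h(\mathbf q) = N^{-2} \sum h\, e^{-i \mathbf
#' q \cdot \mathbf r}} and \eqn{A = L^2}, averaged over frames.
#'
#' @param surfaces List of [undulation_surface()] objects sharing N and L.
#' @return List with `qx`, `qy` (nm^-1 mode vectors), `intensity` (N x N,
#'   nm^4), `n_frames`, `L`, `N`, and `per_frame` (list of per-frame N x N
#'   intensities).
#' @export
spectrum_2d <- function(surfaces) {
  if (!length(surfaces)) stop("need >= 1 surface")
  N <- nrow(surfaces[[1]]$h)
  L <- surfaces[[1]]$L
  same <- vapply(surfaces, function(s)
    nrow(s$h) == N && isTRUE(all.equal(s$L, L)), TRUE)
  if (!all(same)) stop("all surfaces must share grid size and box edge")
  A <- L^2
  per_frame <- lapply(surfaces, function(s) {
    hq <- fft(s$h) / N^2
    A * Mod(hq)^2
  })
  acc <- Reduce(`+`, per_frame) / length(per_frame)
  dq <- 2 * pi / L
  list(qx = .mode_index(N) * dq, qy = .mode_index(N) * dq,
       intensity = acc, n_frames = length(surfaces), L = L, N = N,
       per_frame = per_frame)
}

#' Radially binned undulation spectrum
#'
#' Frame-averaged mode intensities from [spectrum_2d()], grouped into radial
#' bins of exact mode radius (all modes sharing the same integer
#' \eqn{k_x^2 + k_y^2} share a bin, so each bin sits at an exact |q| and the
#' q^-4 Helfrich fit carries no radial-smearing bias). The q = 0 mode is
#' excluded; bins above the axis Nyquist radius (|k| > N/2) are dropped.
#' Per-bin standard errors are computed across frames.
#'
#' @param surfaces List of [undulation_surface()] objects.
#' @return A `fluctuation_spectrum`: `q_values` (nm^-1), `intensity` (nm^4),
#'   `stderr`, `n_modes` per bin, `n_frames`.
#' @export
undulation_spectrum <- function(surfaces) {
  sp <- spectrum_2d(surfaces)
  N <- sp$N
  ki <- .mode_index(N)
  k2 <- outer(ki^2, ki^2, `+`)
  keep <- k2 > 0 & k2 <= (N / 2)^2
  groups <- sort(unique(k2[keep]))
  dq <- 2 * pi / sp$L
  qv <- dq * sqrt(groups)
  bin_of <- match(k2, groups)
  idx <- which(keep)
  bins <- bin_of[idx]
  # per-frame bin means, then across-frame mean and SE
  pf <- vapply(sp$per_frame, function(p)
    as.numeric(tapply(p[idx], bins, mean)), numeric(length(groups)))
  pf <- matrix(pf, length(groups), sp$n_frames)
  intensity <- rowMeans(pf)
  se <- if (sp$n_frames > 1) apply(pf, 1, sd) / sqrt(sp$n_frames)
  else rep(NA_real_, length(groups))
  structure(list(q_values = qv, intensity = intensity, stderr = se,
                 n_modes = as.integer(table(bins)),
                 n_frames = sp$n_frames),
            class = "fluctuation_spectrum")
}

#' @export
print.fluctuation_spectrum <- function(x, ...) {
  cat("Fluctuation spectrum:", length(x$q_values), "q bins on [",
      signif(min(x$q_values), 4), ",", signif(max(x$q_values), 4),
      "] nm^-1,", x$n_frames, "frames\n")
  invisible(x)
}

#' @export
plot.fluctuation_spectrum <- function(x, ...) {
  graphics::plot(x$q_values, x$intensity, log = "xy",
                 xlab = expression(q ~ (nm^-1)),
                 ylab = expression(S(q) ~ (nm^4)), ...)
}

#' Fit the Helfrich bending modulus
#'
#' Fits the pure-bending undulation law \eqn{S(q) = k_BT/(\kappa q^4)} to
#' the low-q bins: a weighted least-squares fit of \eqn{\log S} vs
#' \eqn{\log q} with the slope fixed at -4, whose intercept gives
#' \eqn{\kappa}. Optionally includes a surface-tension term
#' (\eqn{S = k_BT/(\kappa q^4 + \gamma q^2)}) fitted by nonlinear least
#' squares.
#'
#' @param spectrum A `fluctuation_spectrum`.
#' @param temperature Temperature, K.
#' @param q_max Upper fit bound, nm^-1 (default 1.0, the bending-dominated
#'   regime for ~nm lipids).
#' @param tension Include a gamma q^2 tension term (default `FALSE`).
#' @return A `bending_fit`: `kappa` (J), `kappa_1e20` (units of 1e-20 J),
#'   `kappa_error` (J, propagated from per-bin standard errors),
#'   `q_fit_range` (nm^-1), `r_squared` (of the fixed-slope log-log fit),
#'   `n_bins`, and `gamma` (J/nm^2 equivalent, only with `tension`).
#' @export
fit_bending_modulus <- function(spectrum, temperature = 303, q_max = 1.0,
                                tension = FALSE) {
  sel <- spectrum$q_values < q_max & is.finite(spectrum$intensity) &
    spectrum$intensity > 0
  if (sum(sel) < 3) stop("need >= 3 q bins below q_max")
  q <- spectrum$q_values[sel]
  S <- spectrum$intensity[sel]
  se <- spectrum$stderr[sel]
  kT <- .KB_J * temperature
  y <- log(S) + 4 * log(q) # = log(kT/kappa) under the pure-bending law
  w <- if (all(is.finite(se)) && all(se > 0)) (S / se)^2
  else rep(1, length(q))
  ybar <- sum(w * y) / sum(w)
  var_ybar <- if (all(is.finite(se)) && all(se > 0))
    1 / sum(w) # weights are 1/var(y)
  else var(y) / length(y)
  kappa <- kT / exp(ybar)
  kappa_err <- kappa * sqrt(var_ybar)
  ls <- log(S); lq <- log(q)
  resid <- ls - (ybar - 4 * lq)
  r2 <- 1 - sum(resid^2) / sum((ls - mean(ls))^2)
  gamma <- NULL
  if (tension) {
    fn <- function(p) {
      k <- exp(p[1]); g <- exp(p[2])
      sum(w * (log(kT / (k * q^4 + g * q^2)) - log(S))^2)
    }
    op <- optim(c(log(kappa), log(kappa * min(q)^2 * 1e-2)), fn)
    kappa <- exp(op$par[1]); gamma <- exp(op$par[2])
  }
  structure(list(kappa = kappa, kappa_1e20 = kappa / 1e-20,
                 kappa_error = kappa_err, q_fit_range = range(q),
                 r_squared = r2, n_bins = length(q), gamma = gamma,
                 temperature = temperature),
            class = "bending_fit")
}

#' @export
print.bending_fit <- function(x, ...) {
  cat(sprintf(
    "Bending modulus: %.2f +/- %.2f x 1e-20 J (%d bins, q in [%.3g, %.3g] nm^-1, R^2 = %.3f)\n",
    x$kappa_1e20, x$kappa_error / 1e-20, x$n_bins, x$q_fit_range[1],
    x$q_fit_range[2], x$r_squared))
  invisible(x)
}

#' Bending modulus with block-averaged uncertainty
#'
#' Splits the frames into contiguous blocks, fits the modulus per block, and
#' reports the mean of the block moduli with their standard error (the
#' "plus/minus" convention used for the headline numbers).
#'
#' @param surfaces List of [undulation_surface()] frames.
#' @param temperature Temperature, K.
#' @param q_max Fit bound, nm^-1.
#' @param n_blocks Number of frame blocks (default 5).
#' @return A `bending_fit` whose `kappa_error` is the block standard error;
#'   extra field `block_kappas`.
#' @export
bending_modulus_blocks <- function(surfaces, temperature = 303, q_max = 1.0,
                                   n_blocks = 5) {
  ba <- block_average(seq_along(surfaces), n_blocks) # reuse the splitter
  blocks <- attr(ba, "blocks")
  kap <- vapply(blocks, function(ix)
    fit_bending_modulus(undulation_spectrum(surfaces[ix]),
                        temperature, q_max)$kappa, 0)
  fit <- fit_bending_modulus(undulation_spectrum(surfaces), temperature,
                             q_max)
  fit$kappa <- mean(kap)
  fit$kappa_1e20 <- mean(kap) / 1e-20
  fit$kappa_error <- sd(kap) / sqrt(length(kap))
  fit$block_kappas <- kap
  fit
}

#' Block average of a scalar series
#'
#' Splits the series into `n_blocks` contiguous equal-length blocks (any
#' remainder frames at the start are dropped) and returns the mean of the
#' block means with their standard error.
#'
#' @param series Numeric vector.
#' @param n_blocks Number of blocks (>= 2).
#' @return List with `mean`, `se`, `block_means`; attribute `"blocks"` holds
#'   the index sets.
#' @export
block_average <- function(series, n_blocks = 5) {
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  n <- length(series)
  if (n < n_blocks) stop("series shorter than n_blocks")
  bl <- n %/% n_blocks
  start <- n - n_blocks * bl # drop remainder at the start
  blocks <- lapply(seq_len(n_blocks), function(b)
    start + ((b - 1) * bl + 1):(b * bl))
  bm <- vapply(blocks, function(ix) mean(series[ix]), 0)
  structure(list(mean = mean(bm), se = sd(bm) / sqrt(n_blocks),
                 block_means = bm),
            blocks = blocks)
}
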