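# Umbrella sampling / WHAM reconstruction of the cation-insertion free
# energy, and the PMF-matching refinement of cation-lipid cross
# interactions.

#' Construct an umbrella window
#'
#' @param center Restraint center along the bilayer normal z, nm.
#' @param spring_k Harmonic spring constant, kJ/mol/nm^2 (> 0; 0 is allowed
#'   for an unbiased window).
#' @param samples Numeric vector of sampled z values, nm.
#' @param temperature Sampling temperature, K.
#' @return An `umbrella_window` object.
#' @export
umbrella_window <- function(center, spring_k, samples, temperature = 303) {
  if (!is.finite(spring_k) || spring_k < 0) stop("spring_k must be >= 0")
  if (!length(samples) || any(!is.finite(samples)))
    stop("need >= 1 finite sample")
  structure(list(center = center, spring_k = spring_k,
                 samples = as.numeric(samples), temperature = temperature),
            class = "umbrella_window")
}

#' Construct a PMF profile
#'
#' @param z_grid Strictly increasing bin centers, nm.
#' @param free_energy Free energy per bin, kJ/mol (`Inf` marks unsampled
#'   bins).
#' @param error Optional per-bin standard error, kJ/mol.
#' @param reference_zero z value (or `"min"`) at which the profile is
#'   anchored to zero.
#' @return A `pmf_profile` object.
#' @export
pmf_profile <- function(z_grid, free_energy, error = NULL,
                        reference_zero = NA) {
  z_grid <- as.numeric(z_grid)
  if (is.unsorted(z_grid, strictly = TRUE))
    stop("z_grid must be strictly increasing")
  if (length(free_energy) != length(z_grid))
    stop("free_energy length must match z_grid")
  if (is.null(error)) error <- rep(NA_real_, length(z_grid))
  structure(list(z_grid = z_grid, free_energy = as.numeric(free_energy),
                 error = as.numeric(error), reference_zero = reference_zero),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  ok <- is.finite(x$free_energy)
  cat("PMF profile:", length(x$z_grid), "bins on [",
      min(x$z_grid), ",", max(x$z_grid), "] nm;",
      sum(ok), "sampled; range",
      if (any(ok)) paste(signif(range(x$free_energy[ok]), 4),
                         collapse = " .. ") else "-", "kJ/mol\n")
  invisible(x)
}

.logsumexp <- function(m) {
  # row-wise log-sum-exp of a matrix
  mx <- apply(m, 1, max)
  bad <- !is.finite(mx)
  out <- mx + log(rowSums(exp(m - mx)))
  out[bad] <- -Inf
  out
}

#' Solve WHAM over a set of umbrella windows
#'
#' Self-consistent iteration of the standard weighted-histogram equations:
#' \deqn{P(z) \propto \frac{\sum_i n_i(z)}{\sum_j N_j \exp[(F_j -
#'   w_j(z))/k_BT]}, \qquad
#'   F_j = -k_BT \ln \sum_z P(z) e^{-w_j(z)/k_BT},}
#' with harmonic biases \eqn{w_j(z) = k_j (z - c_j)^2 / 2}, iterated until
#' the maximum relative change of the window free energies drops below
#' `tol`. The window free energies are gauge-fixed to \eqn{F_1 = 0}, so the
#' solution is invariant to a constant added to all biases. The returned
#' profile is \eqn{-k_BT \ln P(z)} anchored at its minimum (or at a given
#' z), with `Inf` in unsampled bins.
#'
#' @param windows List of [umbrella_window()] objects (all at the same
#'   temperature).
#' @param z_grid Strictly increasing bin centers, nm. Samples outside the
#'   grid span are dropped.
#' @param tol Relative convergence tolerance on the window free energies
#'   (default 1e-8).
#' @param max_iter Iteration cap (default 1e5). Exceeding it raises a
#'   condition of class `wham_convergence_error` carrying the last iterate
#'   in field `profile`.
#' @param reference_zero `"min"` (default) or a z value to anchor at.
#' @return A [pmf_profile()] with attributes `window_free_energies`,
#'   `iterations` and `bin_counts`.
#' @export
wham_solve <- function(windows, z_grid, tol = 1e-8, max_iter = 1e5,
                       reference_zero = "min") {
  stopifnot(length(windows) >= 1)
  # canonical window order: output is bitwise independent of input order
  ord <- order(vapply(windows, `[[`, 0, "center"),
               vapply(windows, `[[`, 0, "spring_k"))
  windows <- windows[ord]
  temps <- vapply(windows, `[[`, 0, "temperature")
  if (diff(range(temps)) > 1e-9)
    stop("all windows must share one temperature")
  kT <- .KB * temps[1]
  z <- as.numeric(z_grid)
  if (is.unsorted(z, strictly = TRUE)) stop("z_grid must be increasing")
  nb <- length(z)
  dz <- if (nb > 1) diff(z)[1] else 1
  lo <- z[1] - dz / 2
  nw <- length(windows)

  # histogram counts: bins x windows
  counts <- matrix(0, nb, nw)
  for (j in seq_len(nw)) {
    s <- windows[[j]]$samples
    bin <- floor((s - lo) / dz) + 1L
    keep <- bin >= 1L & bin <= nb
    counts[, j] <- tabulate(bin[keep], nbins = nb)
  }
  Nj <- colSums(counts)
  if (any(Nj == 0))
    warning("window(s) ", paste(which(Nj == 0), collapse = ", "),
            " have no samples on the grid")
  .check_window_overlap(counts)

  # bias matrix, bins x windows, in units of kT
  wb <- vapply(seq_len(nw), function(j)
    0.5 * windows[[j]]$spring_k * (z - windows[[j]]$center)^2 / kT,
    numeric(nb))
  wb <- matrix(wb, nb, nw)

  ntot <- rowSums(counts)
  log_ntot <- ifelse(ntot > 0, log(ntot), -Inf)
  logNj <- ifelse(Nj > 0, log(Nj), -Inf)

  Fj <- numeric(nw) # in kT units
  it <- 0L
  repeat {
    it <- it + 1L
    # log denominator per bin
    logden <- .logsumexp(sweep(-wb, 2, logNj + Fj, `+`))
    logP <- log_ntot - logden
    Fn <- -.logsumexp(t(sweep(-wb, 1, logP, `+`)))
    Fn <- Fn - Fn[1]
    delta <- max(abs(Fn - Fj)) / max(1, max(abs(Fn)))
    Fj <- Fn
    if (delta < tol) break
    if (it >= max_iter) {
      prof <- .wham_profile(z, logP, kT, reference_zero)
      cond <- structure(class = c("wham_convergence_error", "error",
                                  "condition"),
                        list(message = sprintf(
                          "WHAM did not converge in %d iterations (delta %.3g)",
                          max_iter, delta),
                          call = sys.call(-1), profile = prof))
      stop(cond)
    }
  }
  prof <- .wham_profile(z, logP, kT, reference_zero)
  attr(prof, "window_free_energies") <- Fj * kT
  attr(prof, "iterations") <- it
  attr(prof, "bin_counts") <- ntot
  prof
}

.wham_profile <- function(z, logP, kT, reference_zero) {
  G <- -kT * logP
  if (identical(reference_zero, "min")) {
    G <- G - min(G[is.finite(G)])
  } else {
    i <- which.min(abs(z - reference_zero))
    if (!is.finite(G[i])) stop("reference_zero bin is unsampled")
    G <- G - G[i]
  }
  pmf_profile(z, G, reference_zero = reference_zero)
}

.check_window_overlap <- function(counts) {
  nw <- ncol(counts)
  if (nw < 2) return(invisible())
  # order windows by mean sampled bin, then check adjacent histogram overlap
  centers <- apply(counts, 2, function(c)
    if (sum(c)) sum(c * seq_along(c)) / sum(c) else NA_real_)
  ord <- order(centers)
  for (k in seq_len(nw - 1)) {
    a <- counts[, ord[k]]; b <- counts[, ord[k + 1]]
    ov <- sum(pmin(a / max(1, sum(a)), b / max(1, sum(b))))
    if (ov < 0.05)
      warning(sprintf(
        "windows %d and %d overlap by only %.1f%% of samples; WHAM may be ill-conditioned",
        ord[k], ord[k + 1], 100 * ov))
  }
  invisible()
}

#' Anchor a PMF to its bulk-water plateau
#'
#' Subtracts the mean free energy over a plateau window centered at
#' `z_bulk`; a window straddling the grid edge is truncated (with a
#' message).
#'
#' @param profile A [pmf_profile()].
#' @param z_bulk Center of the bulk plateau, nm; must lie inside the grid.
#' @param width Plateau width, nm (default 0.5).
#' @return Re-anchored [pmf_profile()].
#' @export
anchor_pmf <- function(profile, z_bulk, width = 0.5) {
  z <- profile$z_grid
  if (z_bulk < min(z) || z_bulk > max(z))
    stop("z_bulk outside the profile grid")
  sel <- z >= z_bulk - width / 2 & z <= z_bulk + width / 2
  if (z_bulk - width / 2 < min(z) || z_bulk + width / 2 > max(z))
    message("anchor window truncated at the grid edge")
  g <- profile$free_energy[sel]
  g <- g[is.finite(g)]
  if (!length(g)) stop("no finite bins in the anchor window")
  profile$free_energy <- profile$free_energy - mean(g)
  profile$reference_zero <- z_bulk
  profile
}

#' RMS discrepancy between two PMF profiles
#'
#' Linearly interpolates `ref` onto the grid of `cg` and returns the RMS
#' difference over `z_range`. Both profiles must already be anchored to the
#' same convention.
#'
#' @param cg,ref [pmf_profile()] objects.
#' @param z_range Length-2 range, nm; defaults to the grid overlap.
#' @return RMS difference, kJ/mol.
#' @export
pmf_discrepancy <- function(cg, ref, z_range = NULL) {
  lo <- max(min(cg$z_grid), min(ref$z_grid))
  hi <- min(max(cg$z_grid), max(ref$z_grid))
  if (lo >= hi) stop("profiles have disjoint z grids")
  if (is.null(z_range)) z_range <- c(lo, hi)
  z_range <- c(max(z_range[1], lo), min(z_range[2], hi))
  sel <- cg$z_grid >= z_range[1] & cg$z_grid <= z_range[2] &
    is.finite(cg$free_energy)
  if (!any(sel)) stop("no usable bins in z_range")
  ok <- is.finite(ref$free_energy)
  refi <- stats::approx(ref$z_grid[ok], ref$free_energy[ok],
                        xout = cg$z_grid[sel], rule = 2)$y
  sqrt(mean((cg$free_energy[sel] - refi)^2))
}

#' Refine cation-lipid cross interactions by PMF matching
#'
#' Derivative-free minimization of the RMS discrepancy between a
#' coarse-grained insertion PMF and an atomistic reference PMF over
#' per-pair epsilon scaling factors. The evaluator maps a scaling vector to
#' a [pmf_profile()] (for the real pipeline it re-runs CG umbrella sampling
#' with [apply_cross_scalings()]; tests use analytic surrogates). Because
#' the refined scalings attach to bead types, they transfer unchanged to
#' longer-tail cations built from the same types (e.g. a decyl cation built
#' from butyl-calibrated tail beads).
#'
#' @param evaluator Function `scalings -> pmf_profile`, deterministic for a
#'   fixed seed.
#' @param ref Reference [pmf_profile()], anchored like the evaluator output.
#' @param initial_scalings Named numeric vector of starting scale factors in
#'   `[0.2, 5]`.
#' @param budget Maximum number of objective evaluations (default 500).
#' @param z_range Optional z window for the objective, nm.
#' @return A `match_result`: `scalings`, `objective` (kJ/mol RMS),
#'   `initial_objective`, `trace` (data frame of accepted best-so-far
#'   iterates, objective non-increasing), `converged`, `n_eval`.
#' @export
optimize_cross_parameters <- function(evaluator, ref, initial_scalings,
                                      budget = 500, z_range = NULL) {
  s0 <- initial_scalings
  if (any(s0 < 0.2 | s0 > 5)) stop("initial scalings must lie in [0.2, 5]")
  env <- new.env()
  env$n <- 0L
  env$best <- Inf
  env$trace <- list()
  obj <- function(s) {
    if (any(s < 0.2 | s > 5)) return(1e6 + sum(pmax(0, s - 5, 0.2 - s)^2))
    env$n <- env$n + 1L
    v <- pmf_discrepancy(evaluator(s), ref, z_range)
    if (v < env$best) {
      env$best <- v
      env$trace[[length(env$trace) + 1L]] <-
        c(eval = env$n, objective = v, s)
    }
    v
  }
  f0 <- obj(s0)
  if (length(s0) == 1L) {
    fit <- optim(s0, obj, method = "Brent", lower = 0.2, upper = 5,
                 control = list(maxit = budget))
  } else {
    fit <- optim(s0, obj, method = "Nelder-Mead",
                 control = list(maxit = budget, reltol = 1e-12))
  }
  par <- fit$par
  val <- fit$value
  if (val > f0) { par <- s0; val <- f0 } # never worse than the start
  names(par) <- names(s0)
  tr <- as.data.frame(do.call(rbind, env$trace))
  structure(list(scalings = par, objective = val, initial_objective = f0,
                 trace = tr, converged = fit$convergence == 0,
                 n_eval = env$n),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("PMF match:", sprintf("objective %.4g kJ/mol (from %.4g) after %d evaluations%s\n",
      x$objective, x$initial_objective, x$n_eval,
      if (x$converged) "" else " [budget exhausted]"))
  print(x$scalings)
  invisible(x)
}

#' Bootstrap per-bin PMF uncertainty
#'
#' Resamples every window's samples with replacement, re-solves WHAM, and
#' returns the per-bin standard deviation across replicates (computed over
#' replicates where the bin is finite; `NA` where fewer than 2 are).
#'
#' @param windows List of [umbrella_window()] objects.
#' @param z_grid Bin centers, nm.
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param seed Integer seed; the result is reproducible for a fixed seed.
#' @param ... Passed to [wham_solve()].
#' @return Numeric vector of per-bin standard deviations, kJ/mol.
#' @export
bootstrap_pmf_error <- function(windows, z_grid, n_boot = 20, seed = 1,
                                ...) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  set.seed(seed)
  reps <- matrix(NA_real_, length(z_grid), n_boot)
  for (b in seq_len(n_boot)) {
    wb <- lapply(windows, function(w) {
      w$samples <- sample(w$samples, length(w$samples), replace = TRUE)
      w
    })
    reps[, b] <- suppressWarnings(wham_solve(wb, z_grid, ...))$free_energy
  }
  apply(reps, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) NA_real_ else sd(v)
  })
}
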