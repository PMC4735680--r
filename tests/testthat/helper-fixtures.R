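# Shared fixtures and independent brute-force oracles. The oracles are pure
# R and deliberately naive; they never call the package's compiled path.

KB <- 0.0083144621
FCOUL <- 138.935485

# one- and two-type parameter sets for focused tests
single_type_params <- function(eps = 1, sigma = 0.45, charge = 0,
                               cutoff = 1.5, dielectric = 16) {
  parameter_set(
    list(bead_type("X", 42, charge, "lipid-tail")),
    list(mie_pair("X", "X", eps, sigma, "9-6")),
    dielectric = dielectric, cutoff = cutoff)
}

dimer_config <- function(r, box = c(6, 6, 6), type = "X", vel = FALSE) {
  top <- data.frame(molecule_id = 1:2, species = "M", bead_type = type)
  pos <- rbind(c(box[1] / 2, box[2] / 2, box[3] / 2),
               c(box[1] / 2 + r, box[2] / 2, box[3] / 2))
  cfg <- system_configuration(pos, top, box)
  if (vel) cfg$velocities <- matrix(0, 2, 3)
  cfg
}

random_config <- function(n, box = c(5, 5, 5), types = "X", seed = 1,
                          species = "M") {
  set.seed(seed)
  top <- data.frame(molecule_id = seq_len(n), species = species,
                    bead_type = sample(types, n, replace = TRUE))
  system_configuration(matrix(runif(3 * n, 0, min(box)), n, 3), top, box)
}

# brute-force O(N^2) shifted Mie + Coulomb energy, pure R
brute_force_energy <- function(config, params) {
  pos <- config$positions
  n <- nrow(pos)
  box <- config$box
  rc <- params$cutoff
  tb <- params$tables
  ti <- match(config$topology$bead_type, tb$type_names)
  mie <- function(r, eps, sig, form) {
    if (eps == 0) return(0)
    sr <- sig / r
    if (form == 0L) 27 / 4 * eps * (sr^9 - sr^6)
    else 3 * sqrt(3) / 2 * eps * (sr^12 - sr^4)
  }
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- pos[i, ] - pos[j, ]
    if (config$periodic) d <- d - box * round(d / box)
    r <- sqrt(sum(d^2))
    if (r >= rc) next
    a <- ti[i]; b <- ti[j]
    e <- e + mie(r, tb$eps[a, b], tb$sig[a, b], tb$form[a, b]) -
      mie(rc, tb$eps[a, b], tb$sig[a, b], tb$form[a, b])
    qq <- tb$charge[[a]] * tb$charge[[b]]
    if (qq != 0)
      e <- e + FCOUL * qq / params$dielectric * (1 / r - 1 / rc)
  }
  unname(e)
}

# brute-force neighbor enumeration
brute_force_pairs <- function(config, rlist) {
  pos <- config$positions
  n <- nrow(pos)
  box <- config$box
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- pos[i, ] - pos[j, ]
    if (config$periodic) d <- d - box * round(d / box)
    if (sum(d^2) < rlist^2) out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# flat synthetic bilayer frame: phosphates at +/- d, optional height field
# h(x, y) added to both leaflets; returns config + construction labels
synthetic_bilayer_frame <- function(n_side = 8, L = 8, d = 2, zmid = 5,
                                    hfun = NULL, cation_z = numeric(0),
                                    cation_xy = NULL) {
  xy <- expand.grid(x = (seq_len(n_side) - 0.5) * L / n_side,
                    y = (seq_len(n_side) - 0.5) * L / n_side)
  nl <- nrow(xy)
  h <- if (is.null(hfun)) 0 else hfun(xy$x, xy$y)
  pos <- rbind(cbind(xy$x, xy$y, zmid + d + h),
               cbind(xy$x, xy$y, zmid - d + h))
  top <- data.frame(molecule_id = seq_len(2 * nl), species = "POPC",
                    bead_type = "PH")
  labels <- rep(c("upper", "lower"), each = nl)
  if (length(cation_z)) {
    ncat <- length(cation_z)
    if (is.null(cation_xy))
      cation_xy <- cbind(runif(ncat, 0, L), runif(ncat, 0, L))
    pos <- rbind(pos, cbind(cation_xy[, 1], cation_xy[, 2], cation_z))
    top <- rbind(top, data.frame(molecule_id = 2 * nl + seq_len(ncat),
                                 species = "C4M", bead_type = "RG"))
  }
  cfg <- system_configuration(pos, top, c(L, L, 2 * zmid))
  attr(cfg, "labels") <- labels
  cfg
}
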