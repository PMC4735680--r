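# Coarse-grained chemical system: bead types, Mie pair table, bonded terms,
# and the energy/force evaluators.

.BEAD_ROLES <- c("lipid-head", "lipid-phosphate", "lipid-glycerol",
                 "lipid-tail", "water", "cation-ring", "cation-tail",
                 "anion", "sodium")

#' Define a coarse-grained bead type
#'
#' @param name Short label, e.g. `"PH"` for the lipid phosphate bead.
#' @param mass Bead mass in amu. Must be positive.
#' @param charge Partial charge in elementary charges.
#' @param role One of `"lipid-head"`, `"lipid-phosphate"`, `"lipid-glycerol"`,
#'   `"lipid-tail"`, `"water"`, `"cation-ring"`, `"cation-tail"`, `"anion"`,
#'   `"sodium"`. The role drives the Mie form selection (12-4 for any pair
#'   involving water, 9-6 otherwise) and the bilayer analysis (phosphate and
#'   ring beads are the reference beads).
#' @return A `bead_type` object.
#' @export
bead_type <- function(name, mass, charge = 0, role) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.finite(mass) || mass <= 0) stop("bead mass must be > 0")
  if (!is.finite(charge)) stop("bead charge must be finite")
  role <- match.arg(role, .BEAD_ROLES)
  structure(list(name = name, mass = mass, charge = charge, role = role),
            class = "bead_type")
}

#' Define a Mie pair interaction
#'
#' The two Mie forms used by SDK-style coarse-grained lipid models, with
#' prefactors chosen so that `epsilon` is the literal well depth:
#' \deqn{U_{9\text{-}6}(r) = \tfrac{27}{4}\,\epsilon\left[(\sigma/r)^9 -
#'   (\sigma/r)^6\right], \qquad
#'   U_{12\text{-}4}(r) = \tfrac{3\sqrt3}{2}\,\epsilon\left[(\sigma/r)^{12} -
#'   (\sigma/r)^4\right].}
#' The 12-4 form is reserved for pairs involving a water bead.
#'
#' @param type_a,type_b Bead type names.
#' @param epsilon Well depth in kJ/mol (>= 0).
#' @param sigma Zero-crossing distance in nm (> 0).
#' @param form `"9-6"` or `"12-4"`.
#' @return A `mie_pair` object.
#' @export
mie_pair <- function(type_a, type_b, epsilon, sigma, form = c("9-6", "12-4")) {
  form <- match.arg(form)
  if (!is.finite(epsilon) || epsilon < 0) stop("epsilon must be >= 0")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  structure(list(type_a = type_a, type_b = type_b, epsilon = epsilon,
                 sigma = sigma, form = form), class = "mie_pair")
}

#' Define a harmonic bonded term
#'
#' @param kind `"bond"` or `"angle"`.
#' @param beads Integer bead indices within the molecule template (2 for a
#'   bond, 3 for an angle with the apex second).
#' @param eq Equilibrium bond length (nm) or angle (degrees).
#' @param k Force constant, kJ/mol/nm^2 or kJ/mol/rad^2 (>= 0).
#' @return A `bonded_term` object.
#' @export
bonded_term <- function(kind = c("bond", "angle"), beads, eq, k) {
  kind <- match.arg(kind)
  beads <- as.integer(beads)
  nb <- if (kind == "bond") 2L else 3L
  if (length(beads) != nb || anyDuplicated(beads))
    stop("bonded term needs ", nb, " distinct bead indices")
  if (!is.finite(k) || k < 0) stop("force constant must be >= 0")
  structure(list(kind = kind, beads = beads, eq = eq, k = k),
            class = "bonded_term")
}

.pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Assemble a coarse-grained parameter set
#'
#' Validates that the pair table covers every unordered bead-type pair exactly
#' once, that duplicated entries are rejected, and that the Mie form matches
#' the role rule (12-4 iff at least one partner is water).
#'
#' @param bead_types List of [bead_type()] objects.
#' @param pairs List of [mie_pair()] objects covering every unordered pair.
#' @param bonded Named list (by molecule species) of lists of [bonded_term()]
#'   templates.
#' @param dielectric Relative permittivity for the screened Coulomb term
#'   (default 16, the implicit-screening value for this model family).
#' @param cutoff Nonbonded cutoff in nm (default 1.5). The potential is
#'   shifted to zero at the cutoff.
#' @return A `parameter_set` object.
#' @export
parameter_set <- function(bead_types, pairs, bonded = list(),
                          dielectric = 16, cutoff = 1.5) {
  names(bead_types) <- vapply(bead_types, `[[`, "", "name")
  if (anyDuplicated(names(bead_types))) stop("duplicate bead type names")
  if (!is.finite(dielectric) || dielectric <= 0) stop("dielectric must be > 0")
  tn <- names(bead_types)
  keys <- vapply(pairs, function(p) .pair_key(p$type_a, p$type_b), "")
  if (anyDuplicated(keys))
    stop("duplicate pair table entries: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  need <- outer(tn, tn, .pair_key)
  need <- unique(need[upper.tri(need, diag = TRUE)])
  missing <- setdiff(need, keys)
  if (length(missing))
    stop("pair table incomplete; missing: ", paste(missing, collapse = ", "))
  unknown <- setdiff(keys, need)
  if (length(unknown))
    stop("pair table references unknown types: ",
         paste(unknown, collapse = ", "))
  roles <- vapply(bead_types, `[[`, "", "role")
  for (p in pairs) {
    has_water <- any(roles[c(p$type_a, p$type_b)] == "water")
    want <- if (has_water) "12-4" else "9-6"
    if (p$form != want)
      stop("pair (", p$type_a, ", ", p$type_b, ") must use the ", want,
           " form")
  }
  sig_max <- max(vapply(pairs, `[[`, 0, "sigma"))
  if (cutoff <= sig_max)
    stop("cutoff (", cutoff, " nm) must exceed the largest sigma (",
         sig_max, " nm)")
  ps <- structure(list(bead_types = bead_types, pairs = pairs,
                       bonded = bonded, dielectric = dielectric,
                       cutoff = cutoff), class = "parameter_set")
  ps$tables <- .pair_tables(ps)
  ps
}

# Dense ntype x ntype lookup tables for the kernel.
.pair_tables <- function(ps) {
  tn <- names(ps$bead_types)
  nt <- length(tn)
  eps <- sig <- matrix(0, nt, nt, dimnames = list(tn, tn))
  form <- matrix(0L, nt, nt, dimnames = list(tn, tn))
  for (p in ps$pairs) {
    i <- match(p$type_a, tn); j <- match(p$type_b, tn)
    eps[i, j] <- eps[j, i] <- p$epsilon
    sig[i, j] <- sig[j, i] <- p$sigma
    form[i, j] <- form[j, i] <- if (p$form == "9-6") 0L else 1L
  }
  list(eps = eps, sig = sig, form = form, type_names = tn,
       charge = vapply(ps$bead_types, `[[`, 0, "charge"),
       mass = vapply(ps$bead_types, `[[`, 0, "mass"))
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Coarse-grained parameter set\n")
  cat("  bead types:", paste(names(x$bead_types), collapse = ", "), "\n")
  cat("  pairs:", length(x$pairs),
      " dielectric:", x$dielectric, " cutoff:", x$cutoff, "nm\n")
  invisible(x)
}

#' Construct a system configuration
#'
#' @param positions N x 3 matrix of bead positions in nm.
#' @param topology Data frame with one row per bead: columns `molecule_id`,
#'   `species` (molecule name, e.g. `"POPC"`), `bead_type` (resolving in the
#'   parameter set). Row order matches `positions`.
#' @param box Length-3 box edges (Lx, Ly, Lz) in nm. For semi-isotropic
#'   systems Lx = Ly is enforced by the barostat, not here.
#' @param velocities Optional N x 3 matrix in nm/ps.
#' @param periodic Logical; minimum-image convention applied when `TRUE`.
#' @return A `system_configuration` object.
#' @export
system_configuration <- function(positions, topology, box,
                                 velocities = NULL, periodic = TRUE) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3 || !all(is.finite(positions)))
    stop("positions must be a finite N x 3 matrix")
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box edges must be 3 positive numbers")
  need <- c("molecule_id", "species", "bead_type")
  if (!all(need %in% names(topology)))
    stop("topology must have columns ", paste(need, collapse = ", "))
  if (nrow(topology) != nrow(positions))
    stop("topology rows must match position rows")
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    stopifnot(identical(dim(velocities), dim(positions)))
  }
  structure(list(positions = positions, velocities = velocities,
                 topology = topology, box = as.numeric(box),
                 periodic = isTRUE(periodic)),
            class = "system_configuration")
}

#' @export
print.system_configuration <- function(x, ...) {
  cat("System configuration:", nrow(x$positions), "beads,",
      length(unique(x$topology$molecule_id)), "molecules, box",
      paste(signif(x$box, 5), collapse = " x "), "nm\n")
  invisible(x)
}

#' Mie pair energy
#'
#' Evaluates the unshifted Mie potential at separation `r`. Both conventions
#' place the single minimum at depth exactly `-epsilon`: at
#' `r = (3/2)^(1/3) sigma` for the 9-6 form and `r = 3^(1/8) sigma` for 12-4.
#'
#' @param r Separation(s), nm; must be > 0.
#' @param param A [mie_pair()] object.
#' @return Energy in kJ/mol (vectorized over `r`).
#' @export
mie_energy <- function(r, param) {
  if (any(r <= 0)) stop("r must be > 0")
  sr <- param$sigma / r
  if (param$form == "9-6") {
    27 / 4 * param$epsilon * (sr^9 - sr^6)
  } else {
    3 * sqrt(3) / 2 * param$epsilon * (sr^12 - sr^4)
  }
}

#' Screened Coulomb pair energy
#'
#' `f * q1 * q2 / (dielectric * r)` with `f = 138.935485` kJ mol^-1 nm e^-2.
#' The dielectric constant models the implicit screening by unrepresented
#' water degrees of freedom (default 16 for this model family).
#'
#' @param r Separation(s), nm; must be > 0.
#' @param q1,q2 Charges in e.
#' @param dielectric Relative permittivity (> 0).
#' @return Energy in kJ/mol.
#' @export
coulomb_energy <- function(r, q1, q2, dielectric = 16) {
  if (any(r <= 0)) stop("r must be > 0")
  if (dielectric <= 0) stop("dielectric must be > 0")
  .FCOUL * q1 * q2 / (dielectric * r)
}

# Resolve bead types of a configuration against a parameter set; returns
# 0-based type indices for the kernel.
.type_index <- function(config, params) {
  tn <- params$tables$type_names
  idx <- match(config$topology$bead_type, tn)
  if (anyNA(idx)) {
    bad <- unique(config$topology$bead_type[is.na(idx)])
    stop("bead types not in parameter set: ", paste(bad, collapse = ", "))
  }
  idx - 1L
}

# Expand per-species bonded templates to absolute bead indices (1-based) for
# the whole configuration. Returns list(bonds=, b0=, kb=, angles=, th0=, kth=).
.instantiate_bonded <- function(config, params) {
  top <- config$topology
  bonds <- matrix(integer(0), 0, 2); b0 <- kb <- numeric(0)
  angles <- matrix(integer(0), 0, 3); th0 <- kth <- numeric(0)
  if (length(params$bonded)) {
    split_idx <- split(seq_len(nrow(top)), top$molecule_id)
    for (idx in split_idx) {
      sp <- top$species[idx[1]]
      terms <- params$bonded[[sp]]
      if (is.null(terms)) next
      for (tm in terms) {
        gi <- idx[tm$beads]
        if (anyNA(gi)) stop("bonded term bead index out of range for ", sp)
        if (tm$kind == "bond") {
          bonds <- rbind(bonds, gi); b0 <- c(b0, tm$eq); kb <- c(kb, tm$k)
        } else {
          angles <- rbind(angles, gi)
          th0 <- c(th0, tm$eq * pi / 180); kth <- c(kth, tm$k)
        }
      }
    }
  }
  list(bonds = bonds, b0 = b0, kb = kb, angles = angles, th0 = th0, kth = kth)
}

# Nonbonded exclusions: 1-2 pairs from bonds and 1-3 pairs from angles.
.exclusions <- function(bonded) {
  ex <- bonded$bonds
  if (nrow(bonded$angles))
    ex <- rbind(ex, bonded$angles[, c(1, 3), drop = FALSE])
  if (!nrow(ex)) return(matrix(integer(0), 0, 2))
  ex - 1L # 0-based for the kernel
}

.energy_forces <- function(config, params) {
  if (params$cutoff >= min(config$box) / 2 && config$periodic)
    stop("cutoff must be < half the smallest box edge")
  ti <- .type_index(config, params)
  bd <- .instantiate_bonded(config, params)
  tb <- params$tables
  nb <- nb_energy_forces_cpp(config$positions, config$box, ti,
                             tb$eps, tb$sig, tb$form,
                             tb$charge[ti + 1L], params$dielectric,
                             params$cutoff, .exclusions(bd),
                             config$periodic)
  bo <- bonded_energy_forces_cpp(config$positions, config$box,
                                 bd$bonds - 1L, bd$b0, bd$kb,
                                 bd$angles - 1L, bd$th0, bd$kth,
                                 config$periodic)
  list(energy = nb$energy + bo$energy,
       nonbonded = nb$energy, bonded = bo$energy,
       forces = nb$forces + bo$forces,
       virial = nb$virial + bo$virial)
}

#' Total nonbonded energy
#'
#' Sum of shifted Mie + screened Coulomb energies over unique bead pairs
#' within the cutoff under the minimum-image convention, excluding
#' bonded-neighbor (1-2 and 1-3) pairs. The potential is shifted so each pair
#' term vanishes at the cutoff.
#'
#' @param config A [system_configuration()].
#' @param params A [parameter_set()].
#' @return Energy in kJ/mol.
#' @export
total_nonbonded_energy <- function(config, params) {
  if (params$cutoff >= min(config$box) / 2 && config$periodic)
    stop("cutoff must be < half the smallest box edge")
  ti <- .type_index(config, params)
  bd <- .instantiate_bonded(config, params)
  tb <- params$tables
  nb_energy_forces_cpp(config$positions, config$box, ti,
                       tb$eps, tb$sig, tb$form,
                       tb$charge[ti + 1L], params$dielectric,
                       params$cutoff, .exclusions(bd),
                       config$periodic)$energy
}

#' Total potential energy (nonbonded + bonded)
#'
#' @inheritParams total_nonbonded_energy
#' @return Energy in kJ/mol.
#' @export
total_energy <- function(config, params) .energy_forces(config, params)$energy

#' Analytic forces
#'
#' Gradient of the total (nonbonded + bonded) potential. For an isolated
#' periodic system the net force sums to zero to machine precision because
#' every contribution is applied pairwise.
#'
#' @inheritParams total_nonbonded_energy
#' @return N x 3 matrix of forces in kJ/mol/nm.
#' @export
compute_forces <- function(config, params) .energy_forces(config, params)$forces

#' Neighbor list by cell decomposition
#'
#' Returns every bead pair within `cutoff + skin`, computed with a periodic
#' cell list when the box admits one (>= 3 cells per edge) and an O(N^2)
#' minimum-image scan otherwise. The list is a superset of the within-cutoff
#' pairs and a subset of the within-(cutoff+skin) pairs.
#'
#' @param config A [system_configuration()].
#' @param cutoff Interaction cutoff, nm.
#' @param skin Extra margin, nm (default 0.2).
#' @return Two-column integer matrix of 1-based bead index pairs (i < j),
#'   ordered by (i, j).
#' @export
build_neighbor_list <- function(config, cutoff, skin = 0.2) {
  pr <- neighbor_pairs_cpp(config$positions, config$box, cutoff + skin,
                           config$periodic)
  if (nrow(pr)) pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  pr
}

#' Wrap positions into the primary box
#'
#' @param positions N x 3 matrix, nm.
#' @param box Length-3 box edges, nm.
#' @return Wrapped N x 3 matrix with all coordinates in [0, L).
#' @export
wrap_positions <- function(positions, box) {
  for (d in 1:3) positions[, d] <- positions[, d] -
      box[d] * floor(positions[, d] / box[d])
  positions
}
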