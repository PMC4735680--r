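# Molecule templates (SDK-style CG mapping) and a documented example
# parameter set. The published SDK / imidazolium base values live in their
# original references; the set below is a schema-complete, physically
# plausible example, with the cation-lipid cross interactions exposed as
# scaling knobs for PMF matching.

#' Coarse-grained lipid template
#'
#' SDK-style mapping of a phosphatidylcholine lipid: one choline head bead,
#' one phosphate bead, one glycerol/ester bead and two hydrocarbon tails.
#' The default `n_tail = 5` gives the 13-bead mapping used for POPC.
#'
#' @param n_tail Beads per tail (default 5).
#' @param species Molecule species label (default `"POPC"`).
#' @return List with `species`, `bead_types` (per-bead type labels, head to
#'   tail), `bonded` (list of [bonded_term()]), and `z_offsets` (construction
#'   heights of each bead relative to the phosphate plane, nm, positive
#'   toward water).
#' @export
lipid_template <- function(n_tail = 5, species = "POPC") {
  stopifnot(n_tail >= 1)
  bt <- c("NC", "PH", "GL", rep("CT", 2 * n_tail))
  bonded <- list(bonded_term("bond", c(1, 2), 0.47, 1250),
                 bonded_term("bond", c(2, 3), 0.47, 1250))
  tail_spacing <- 0.45
  z <- c(0.5, 0, -0.4, rep(NA_real_, 2 * n_tail))
  for (t in 0:1) {
    first <- 4L + t * n_tail
    bonded <- c(bonded, list(bonded_term("bond", c(3, first), 0.47, 1250)))
    for (k in seq_len(n_tail)) {
      idx <- first + k - 1L
      z[idx] <- -0.4 - tail_spacing * k
      if (k > 1)
        bonded <- c(bonded, list(bonded_term("bond", c(idx - 1L, idx),
                                             0.45, 1250)))
      if (k > 2)
        bonded <- c(bonded, list(bonded_term("angle", c(idx - 2L, idx - 1L,
                                                        idx), 175, 25)))
    }
  }
  list(species = species, bead_types = bt, bonded = bonded, z_offsets = z)
}

#' Coarse-grained imidazolium cation template
#'
#' Maps a 1-n-alkyl-3-methylimidazolium cation to one charged ring bead plus
#' `round(n/3)` neutral tail beads (three heavy atoms per tail bead).
#'
#' @param n Alkyl chain length (e.g. 4 for the butyl, 10 for the decyl
#'   cation).
#' @return List as in [lipid_template()]; species is `"C<n>M"`.
#' @export
cation_template <- function(n = 4) {
  stopifnot(n >= 1)
  ntail <- max(1L, as.integer(round(n / 3)))
  bt <- c("RG", rep("CA", ntail))
  bonded <- list()
  for (k in seq_len(ntail))
    bonded <- c(bonded, list(bonded_term("bond", c(k, k + 1L), 0.45, 1250)))
  if (ntail >= 2)
    for (k in seq_len(ntail - 1))
      bonded <- c(bonded, list(bonded_term("angle", c(k, k + 1L, k + 2L),
                                           175, 25)))
  z <- c(0, -0.45 * seq_len(ntail))
  list(species = paste0("C", n, "M"), bead_types = bt, bonded = bonded,
       z_offsets = z)
}

.EXAMPLE_TYPES <- list(
  # name, mass (amu), charge (e), role, sigma_self (nm), eps_self (kJ/mol)
  list("NC", 87.2, +1, "lipid-head",      0.59, 1.50),
  list("PH", 94.0, -1, "lipid-phosphate", 0.55, 1.50),
  list("GL", 41.1,  0, "lipid-glycerol",  0.50, 1.40),
  list("CT", 42.1,  0, "lipid-tail",      0.45, 1.80),
  list("W",  54.0,  0, "water",           0.47, 1.30),
  list("RG", 81.1, +1, "cation-ring",     0.50, 1.60),
  list("CA", 42.1,  0, "cation-tail",     0.45, 1.80),
  list("CL", 35.5, -1, "anion",           0.44, 1.40),
  list("NA", 23.0, +1, "sodium",          0.35, 1.40))

#' Example coarse-grained parameter set
#'
#' A schema-complete parameter set for POPC + imidazolium chloride + NaCl in
#' implicit-screened water. Self terms are plausible SDK-scale values;
#' unlike-pair terms use Lorentz-Berthelot combination (arithmetic sigma,
#' geometric epsilon), with the 12-4 form for any pair involving water and
#' 9-6 otherwise. Cation-lipid cross interactions can be rescaled through
#' `cross_scalings`, the knob set refined by PMF matching
#' ([optimize_cross_parameters()]).
#'
#' This is an example set documenting the schema, not a claim of identity
#' with any published file.
#'
#' @param cross_scalings Named numeric vector of epsilon scale factors keyed
#'   as `"A|B"` with alphabetically ordered type names, e.g.
#'   `c("PH|RG" = 1.2)`. Defaults to no rescaling.
#' @param dielectric,cutoff Passed to [parameter_set()].
#' @return A [parameter_set()].
#' @export
example_parameter_set <- function(cross_scalings = numeric(),
                                  dielectric = 16, cutoff = 1.5) {
  bts <- lapply(.EXAMPLE_TYPES, function(t)
    bead_type(t[[1]], t[[2]], t[[3]], t[[4]]))
  names(bts) <- vapply(bts, `[[`, "", "name")
  roles <- vapply(bts, `[[`, "", "role")
  sig <- vapply(.EXAMPLE_TYPES, function(t) t[[5]], 0)
  eps <- vapply(.EXAMPLE_TYPES, function(t) t[[6]], 0)
  names(sig) <- names(eps) <- names(bts)
  tn <- names(bts)
  pairs <- list()
  for (i in seq_along(tn)) for (j in i:length(tn)) {
    a <- tn[i]; b <- tn[j]
    form <- if (any(roles[c(a, b)] == "water")) "12-4" else "9-6"
    e <- sqrt(eps[a] * eps[b])
    key <- .pair_key(a, b)
    if (key %in% names(cross_scalings)) e <- e * cross_scalings[[key]]
    pairs <- c(pairs, list(mie_pair(a, b, e, (sig[a] + sig[b]) / 2, form)))
  }
  parameter_set(bts, pairs, bonded = list(), dielectric = dielectric,
                cutoff = cutoff)
}

#' Attach bonded templates for given molecule templates
#'
#' @param params A [parameter_set()].
#' @param templates List of templates from [lipid_template()] /
#'   [cation_template()].
#' @return The parameter set with `bonded` populated per species.
#' @export
with_bonded_templates <- function(params, templates) {
  for (tp in templates) params$bonded[[tp$species]] <- tp$bonded
  params
}

#' Rescale cation-lipid cross interactions
#'
#' Multiplies the epsilon of selected unordered type pairs, the operation the
#' PMF-matching refinement optimizes over. By default the refined pairs are
#' ring-head, ring-phosphate and cation-tail/lipid-tail.
#'
#' @param params A [parameter_set()].
#' @param scalings Named numeric vector keyed `"A|B"` (alphabetical order),
#'   values in a sane range (0.2 to 5).
#' @return New parameter set with rescaled epsilons.
#' @export
apply_cross_scalings <- function(params, scalings) {
  if (!length(scalings)) return(params)
  if (any(scalings < 0.2 | scalings > 5))
    stop("cross scalings must lie in [0.2, 5]")
  keys <- vapply(params$pairs, function(p) .pair_key(p$type_a, p$type_b), "")
  unknown <- setdiff(names(scalings), keys)
  if (length(unknown))
    stop("unknown pair keys: ", paste(unknown, collapse = ", "))
  for (nm in names(scalings)) {
    k <- which(keys == nm)
    params$pairs[[k]]$epsilon <- params$pairs[[k]]$epsilon * scalings[[nm]]
  }
  params$tables <- .pair_tables(params)
  params
}

#' Default refined cross-pair keys
#'
#' @return Character vector of the pair keys refined by default:
#'   ring-head, ring-phosphate, and cation-tail/lipid-tail.
#' @export
default_cross_pairs <- function() {
  c(.pair_key("RG", "NC"), .pair_key("RG", "PH"), .pair_key("CA", "CT"))
}
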