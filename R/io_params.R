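# Parameter files: YAML or JSON with sections bead_types, pairs, bonds,
# angles, globals(dielectric, cutoff, temperature).

#' Read a parameter file (YAML or JSON)
#'
#' @param path File path; dialect chosen by extension (`.json` vs
#'   `.yml`/`.yaml`).
#' @return A [parameter_set()]; the `globals.temperature` entry, if present,
#'   is attached as attribute `"temperature"`.
#' @export
read_parameter_file <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  bts <- lapply(raw$bead_types, function(b)
    bead_type(b$name, b$mass, b$charge %||% 0, b$role))
  pairs <- lapply(raw$pairs, function(p)
    mie_pair(p$a, p$b, p$epsilon, p$sigma, p$form %||% "9-6"))
  bonded <- list()
  for (b in raw$bonds)
    bonded[[b$species]] <- c(bonded[[b$species]],
                             list(bonded_term("bond", unlist(b$beads),
                                              b$eq, b$k)))
  for (a in raw$angles)
    bonded[[a$species]] <- c(bonded[[a$species]],
                             list(bonded_term("angle", unlist(a$beads),
                                              a$eq, a$k)))
  g <- raw$globals %||% list()
  ps <- parameter_set(bts, pairs, bonded = bonded,
                      dielectric = g$dielectric %||% 16,
                      cutoff = g$cutoff %||% 1.5)
  attr(ps, "temperature") <- g$temperature %||% 303
  ps
}

#' Write a parameter set to YAML or JSON
#'
#' @param params A [parameter_set()].
#' @param path Output path; dialect by extension.
#' @param temperature Optional temperature (K) stored in `globals`.
#' @return `path`, invisibly.
#' @export
write_parameter_file <- function(params, path, temperature = 303) {
  raw <- list(
    bead_types = lapply(unname(params$bead_types), function(b)
      list(name = b$name, mass = b$mass, charge = b$charge, role = b$role)),
    pairs = lapply(params$pairs, function(p)
      list(a = p$type_a, b = p$type_b, epsilon = p$epsilon,
           sigma = p$sigma, form = p$form)),
    bonds = list(), angles = list(),
    globals = list(dielectric = params$dielectric, cutoff = params$cutoff,
                   temperature = temperature))
  for (sp in names(params$bonded)) for (tm in params$bonded[[sp]]) {
    rec <- list(species = sp, beads = as.list(tm$beads), eq = tm$eq,
                k = tm$k)
    if (tm$kind == "bond") raw$bonds <- c(raw$bonds, list(rec))
    else raw$angles <- c(raw$angles, list(rec))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else yaml::write_yaml(raw, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
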