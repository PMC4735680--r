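# Tabular IO: PMF profiles, fluctuation spectra, insertion series as TSV
# with unit-carrying headers; undulation surfaces as CSV grids with a JSON
# header sidecar; run manifests as JSON.

.TSV_HEADERS <- list(
  pmf_profile = c("z_nm", "free_energy_kJ_mol", "error_kJ_mol"),
  fluctuation_spectrum = c("q_nm_inv", "intensity_nm4", "stderr_nm4",
                           "n_modes"),
  insertion_series = c("time_ps", "inserted_upper", "inserted_lower",
                       "lipids_upper", "lipids_lower", "ratio_upper",
                       "ratio_lower"))

#' Write a typed table (PMF profile, spectrum, insertion series) to TSV
#'
#' The header row carries the column units; [read_tsv_profile()] refuses a
#' file whose header does not match the expected unit-annotated names for
#' the requested type, and matches columns by name so column order is free.
#' Floats are written at full precision; `NA` error bins round-trip as `NA`.
#'
#' @param x Object of class `pmf_profile`, `fluctuation_spectrum` or
#'   `insertion_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_profile <- function(x, path) {
  type <- intersect(class(x), names(.TSV_HEADERS))
  if (!length(type)) stop("unsupported table type: ", class(x)[1])
  type <- type[1]
  df <- switch(type,
    pmf_profile = data.frame(z_nm = x$z_grid,
                             free_energy_kJ_mol = x$free_energy,
                             error_kJ_mol = x$error),
    fluctuation_spectrum = data.frame(q_nm_inv = x$q_values,
                                      intensity_nm4 = x$intensity,
                                      stderr_nm4 = x$stderr,
                                      n_modes = x$n_modes),
    insertion_series = data.frame(time_ps = x$time,
                                  inserted_upper = x$inserted_upper,
                                  inserted_lower = x$inserted_lower,
                                  lipids_upper = x$lipids_upper,
                                  lipids_lower = x$lipids_lower,
                                  ratio_upper = x$ratio_upper,
                                  ratio_lower = x$ratio_lower))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  fmt <- vapply(df, function(col) if (is.integer(col)) "%d" else "%.17g", "")
  body <- do.call(paste, c(lapply(seq_along(df), function(k) {
    v <- df[[k]]
    out <- ifelse(is.na(v), "NA", sprintf(fmt[k], v))
    out
  }), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read a typed TSV table
#'
#' @param path File path.
#' @param type One of `"pmf_profile"`, `"fluctuation_spectrum"`,
#'   `"insertion_series"`.
#' @return The corresponding object.
#' @export
read_tsv_profile <- function(path,
                             type = c("pmf_profile", "fluctuation_spectrum",
                                      "insertion_series")) {
  type <- match.arg(type)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  want <- .TSV_HEADERS[[type]]
  if (!all(want %in% names(df)))
    stop("header mismatch for ", type, ": expected columns ",
         paste(want, collapse = ", "), " (units are part of the contract)")
  switch(type,
    pmf_profile = pmf_profile(df$z_nm, df$free_energy_kJ_mol,
                              error = df$error_kJ_mol),
    fluctuation_spectrum = structure(
      list(q_values = df$q_nm_inv, intensity = df$intensity_nm4,
           stderr = df$stderr_nm4, n_modes = df$n_modes,
           n_frames = attr(df, "n_frames")),
      class = "fluctuation_spectrum"),
    insertion_series = structure(
      list(time = df$time_ps, inserted_upper = df$inserted_upper,
           inserted_lower = df$inserted_lower,
           lipids_upper = df$lipids_upper, lipids_lower = df$lipids_lower,
           ratio_upper = df$ratio_upper, ratio_lower = df$ratio_lower),
      class = "insertion_series"))
}

#' Write / read an undulation surface as CSV grid + JSON header
#'
#' The CSV holds the N x N height grid (nm); `<path>.json` records the box
#' edge, frame time and leaflet.
#'
#' @param surface An `undulation_surface`.
#' @param path CSV path.
#' @return `path` (write) or the surface (read).
#' @export
write_surface <- function(surface, path) {
  write.table(surface$h, path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  jsonlite::write_json(list(L = surface$L, time = surface$time,
                            leaflet = surface$leaflet,
                            N = nrow(surface$h)),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  h <- as.matrix(read.table(path, sep = ","))
  dimnames(h) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  undulation_surface(h, meta$L, time = meta$time %||% NA_real_,
                     leaflet = meta$leaflet %||% "upper")
}

#' Write a run manifest
#'
#' Records everything needed to trace an output back to its inputs: the
#' resolved configuration, seed, package version and md5 of every input
#' file.
#'
#' @param path Manifest path (JSON).
#' @param config Named list of settings as resolved for the run.
#' @param seed Integer seed used.
#' @param inputs Character vector of input file paths to hash.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, inputs = character()) {
  hashes <- if (length(inputs))
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  jsonlite::write_json(list(
    package = "ilbilayer",
    version = as.character(packageVersion("ilbilayer")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, config = config, input_md5 = hashes),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
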