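# GRO-format coordinate IO (fixed columns, nm) plus a topology TSV sidecar.
# GRO is the coordinate dialect because the surrounding ecosystem is
# GROMACS-based; precision is the format's 3 decimals for positions and 4
# for velocities.

#' Read a (multi-frame) GRO file
#'
#' Parses fixed-column GRO records. The molecule id, species and bead type of
#' every bead are taken from the residue number, residue name and atom name
#' fields, so a GRO written by [write_gro()] round-trips without a sidecar;
#' an explicit topology (from [read_topology()]) overrides them when given.
#'
#' @param path File path.
#' @param topology Optional topology data frame applied to every frame.
#' @return List of [system_configuration()] frames (possibly empty). Frame
#'   times parsed from a `t=` token in the title line are stored as
#'   attribute `"time"`.
#' @export
read_gro <- function(path, topology = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    if (i + 1L > length(lines)) stop("truncated GRO file at line ", i)
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 0)
      stop("bad atom count at line ", i + 1L, ": ", lines[i + 1L])
    if (i + 1L + nat + 1L > length(lines))
      stop("truncated frame: expected ", nat, " atom lines after line ",
           i + 1L)
    at <- if (nat > 0L) lines[(i + 2L):(i + 1L + nat)] else character(0)
    boxline <- lines[i + 2L + nat]
    box <- suppressWarnings(as.numeric(strsplit(trimws(boxline),
                                                "\\s+")[[1]]))
    if (length(box) < 3 || anyNA(box[1:3]))
      stop("missing or malformed box line at line ", i + 2L + nat)
    if (nat > 0L) {
      w <- nchar(at)
      if (any(w < 44))
        stop("malformed GRO atom record (line ",
             i + 1L + which(w < 44)[1], "): expected >= 44 columns")
      resid <- as.integer(substr(at, 1, 5))
      resname <- trimws(substr(at, 6, 10))
      atname <- trimws(substr(at, 11, 15))
      x <- as.numeric(substr(at, 21, 28))
      y <- as.numeric(substr(at, 29, 36))
      z <- as.numeric(substr(at, 37, 44))
      if (anyNA(x) || anyNA(y) || anyNA(z) || anyNA(resid))
        stop("malformed GRO atom record near line ", i + 2L)
      pos <- cbind(x, y, z)
      vel <- NULL
      if (all(w >= 68)) {
        vx <- suppressWarnings(as.numeric(substr(at, 45, 52)))
        vy <- suppressWarnings(as.numeric(substr(at, 53, 60)))
        vz <- suppressWarnings(as.numeric(substr(at, 61, 68)))
        if (!anyNA(vx) && !anyNA(vy) && !anyNA(vz)) vel <- cbind(vx, vy, vz)
      }
      top <- if (is.null(topology))
        data.frame(molecule_id = resid, species = resname,
                   bead_type = atname, stringsAsFactors = FALSE)
      else topology
      cfg <- system_configuration(pos, top, box[1:3], velocities = vel)
    } else {
      cfg <- NULL
    }
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (!is.null(cfg)) {
      attr(cfg, "time") <- if (length(tm))
        as.numeric(sub("t=\\s*", "", tm)) else NA_real_
      frames[[length(frames) + 1L]] <- cfg
    }
    i <- i + nat + 3L
  }
  frames
}

#' Write one or more frames to a GRO file
#'
#' @param config A [system_configuration()] or list of them.
#' @param path Output path.
#' @param append Append frames instead of overwriting.
#' @param time Optional frame time(s), ps, written into the title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(config, path, append = FALSE, time = NULL) {
  if (inherits(config, "system_configuration")) config <- list(config)
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  for (f in seq_along(config)) {
    cfg <- config[[f]]
    n <- nrow(cfg$positions)
    t <- if (!is.null(time)) time[min(f, length(time))] else NA_real_
    title <- if (is.na(t)) "ilbilayer frame"
    else sprintf("ilbilayer frame t= %.4f", t)
    writeLines(c(title, sprintf("%5d", n)), con)
    top <- cfg$topology
    resid <- top$molecule_id %% 100000L
    if (is.null(cfg$velocities)) {
      rec <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     resid, substr(top$species, 1, 5),
                     substr(top$bead_type, 1, 5), seq_len(n) %% 100000L,
                     cfg$positions[, 1], cfg$positions[, 2],
                     cfg$positions[, 3])
    } else {
      rec <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f%8.4f%8.4f%8.4f",
                     resid, substr(top$species, 1, 5),
                     substr(top$bead_type, 1, 5), seq_len(n) %% 100000L,
                     cfg$positions[, 1], cfg$positions[, 2],
                     cfg$positions[, 3], cfg$velocities[, 1],
                     cfg$velocities[, 2], cfg$velocities[, 3])
    }
    writeLines(rec, con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", cfg$box[1], cfg$box[2],
                       cfg$box[3]), con)
  }
  invisible(path)
}

#' Write / read a topology sidecar TSV
#'
#' Columns: `bead` (1-based index), `molecule_id`, `species`, `bead_type`.
#'
#' @param topology Topology data frame.
#' @param path File path.
#' @return `path` (write) or the topology data frame (read).
#' @export
write_topology <- function(topology, path) {
  out <- data.frame(bead = seq_len(nrow(topology)),
                    molecule_id = topology$molecule_id,
                    species = topology$species,
                    bead_type = topology$bead_type)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("bead", "molecule_id", "species", "bead_type")
  if (!all(need %in% names(df)))
    stop("topology TSV must have columns ", paste(need, collapse = ", "))
  df <- df[order(df$bead), c("molecule_id", "species", "bead_type")]
  rownames(df) <- NULL
  df
}

#' Read/write plain XYZ coordinates (fallback format)
#'
#' @param path File path.
#' @param config A [system_configuration()] (write only).
#' @return For reads, a list with `positions` and `labels`; XYZ carries no
#'   box, so callers must supply one.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  at <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  labels <- vapply(at, `[[`, "", 1)
  pos <- t(vapply(at, function(a) as.numeric(a[2:4]), numeric(3)))
  list(positions = pos, labels = labels)
}

#' @rdname read_xyz
#' @export
write_xyz <- function(config, path) {
  n <- nrow(config$positions)
  lines <- c(as.character(n), "ilbilayer xyz",
             sprintf("%s %.6f %.6f %.6f", config$topology$bead_type,
                     config$positions[, 1], config$positions[, 2],
                     config$positions[, 3]))
  writeLines(lines, path)
  invisible(path)
}
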