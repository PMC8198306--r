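# Input/output layer: a minimal CIF dialect, CSV peak and echo tables, and
# a flat JSON configuration. Angle units in files are always degrees;
# radians exist only inside the analysis functions.

#' Default ionic radii table
#'
#' Shannon-style ionic radii (Angstrom) used when importing structures whose
#' files do not carry radii: Ca 1.00, O 1.40, P 0.38, OH (as one sphere)
#' 1.37. Hydrogen is ignored (radius 0 entries are rejected, so H sites
#' should be absorbed into OH or omitted). Override any entry via the
#' `radii` argument of [read_cif()] or a JSON file of `species: radius`
#' pairs.
#'
#' @return A named numeric vector of radii in Angstrom.
#' @export
default_radii <- function() {
  c(Ca = 1.00, O = 1.40, P = 0.38, OH = 1.37)
}

strip_esd <- function(x) as.numeric(sub("\\(.*\\)", "", x))

# "Ca2+", "Ca1" -> "Ca"; "OH" kept as is.
species_from_label <- function(label) {
  s <- sub("[0-9+'-].*$", "", label)
  if (s == "") label else s
}

#' Read a minimal CIF file
#'
#' Parses `_cell_length_a`, `_cell_length_c` and the `_atom_site_*` loop
#' (label, optional type symbol, fractional coordinates). Symmetry
#' operators are not expanded: the atom list is taken as an explicit P1
#' list, which is the documented limitation of this dialect.
#'
#' @param path Path to the CIF file.
#' @param radii Named numeric vector mapping species to radii (Angstrom);
#'   see [default_radii()].
#' @return A [crystal_structure()].
#' @export
read_cif <- function(path, radii = default_radii()) {
  lines <- readLines(path, warn = FALSE)
  get_scalar <- function(tag) {
    hit <- grep(paste0("^\\s*", tag, "\\b"), lines)
    if (length(hit) == 0L)
      stop(sprintf("CIF parse error: missing %s", tag), call. = FALSE)
    val <- strsplit(trimws(lines[hit[1]]), "\\s+")[[1]][2]
    strip_esd(val)
  }
  a <- get_scalar("_cell_length_a")
  c_ <- get_scalar("_cell_length_c")

  # locate the atom_site loop
  loop_starts <- grep("^\\s*loop_\\s*$", lines)
  site_block <- NULL
  for (ls in loop_starts) {
    tags <- character()
    i <- ls + 1
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, trimws(lines[i]))
      i <- i + 1
    }
    if (any(grepl("^_atom_site_fract_x", tags))) {
      site_block <- list(tags = tags, first_row = i)
      break
    }
  }
  if (is.null(site_block))
    stop("CIF parse error: no atom_site loop found", call. = FALSE)
  tags <- site_block$tags
  need <- c("_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z")
  if (!all(need %in% tags))
    stop("CIF parse error: atom_site loop lacks fractional coordinates",
         call. = FALSE)
  lab_col <- match("_atom_site_label", tags)
  if (is.na(lab_col)) lab_col <- match("_atom_site_type_symbol", tags)
  if (is.na(lab_col))
    stop("CIF parse error: atom_site loop lacks labels", call. = FALSE)
  cols <- match(need, tags)

  rows <- list()
  i <- site_block$first_row
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^(loop_|_|#|data_)", ln)) break
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) < length(tags))
      stop(sprintf("CIF parse error at line %d: expected %d fields", i,
                   length(tags)), call. = FALSE)
    rows[[length(rows) + 1L]] <- f
    i <- i + 1
  }
  if (length(rows) == 0L)
    stop("CIF parse error: empty atom_site loop", call. = FALSE)
  lab <- vapply(rows, `[`, character(1), lab_col)
  species <- vapply(lab, species_from_label, character(1), USE.NAMES = FALSE)
  uvw <- t(vapply(rows, function(f) strip_esd(f[cols]), numeric(3)))
  miss <- setdiff(unique(species), names(radii))
  if (length(miss) > 0L)
    stop("no radius tabulated for species: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sites <- data.frame(species = species, u = uvw[, 1], v = uvw[, 2],
                      w = uvw[, 3], radius = unname(radii[species]))
  crystal_structure(sites, lattice = hex_lattice(a, c_))
}

#' Write a minimal CIF file
#'
#' Emits the dialect [read_cif()] parses (hexagonal cell, explicit P1 atom
#' list). The radius column is not part of CIF and is re-attached from the
#' radii table on reading.
#'
#' @param structure A hexagonal [crystal_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cif <- function(structure, path) {
  stopifnot(inherits(structure, "crystal_structure"))
  if (is.null(structure$lattice))
    stop("only hexagonal structures can be written as CIF", call. = FALSE)
  s <- structure$sites
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "data_usdmwh",
    sprintf("_cell_length_a    %.6f", structure$lattice$a),
    sprintf("_cell_length_b    %.6f", structure$lattice$a),
    sprintf("_cell_length_c    %.6f", structure$lattice$c),
    "_cell_angle_alpha 90",
    "_cell_angle_beta  90",
    "_cell_angle_gamma 120",
    "loop_",
    "_atom_site_label",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    sprintf("%s %.8f %.8f %.8f", s$species, s$u, s$v, s$w)), con)
  invisible(path)
}

#' Read an XRD peak table
#'
#' CSV with the exact header `h,k,l,two_theta_deg,fwhm_deg`. Invalid rows
#' (the (0,0,0) plane, angles outside (0, 180), non-positive FWHM) are
#' rejected with the offending row number.
#'
#' @param path Path to the CSV file.
#' @return A [peak_table()].
#' @export
read_peaks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("h", "k", "l", "two_theta_deg", "fwhm_deg")
  if (!identical(names(df)[seq_along(need)], need))
    stop("peak CSV must have header h,k,l,two_theta_deg,fwhm_deg",
         call. = FALSE)
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({
      as_miller(c(df$h[i], df$k[i], df$l[i]))
      df$two_theta_deg[i] > 0 && df$two_theta_deg[i] < 180 &&
        df$fwhm_deg[i] > 0
    }, error = function(e) FALSE)
    if (!isTRUE(ok))
      stop(sprintf("invalid peak record at row %d of %s", i, path),
           call. = FALSE)
  }
  peak_table(df$h, df$k, df$l, df$two_theta_deg, df$fwhm_deg)
}

#' Write an XRD peak table
#'
#' @param peaks A [peak_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  utils::write.csv(
    peaks[, c("h", "k", "l", "two_theta_deg", "fwhm_deg")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ultrasonic measurement table
#'
#' CSV with header `replicate,ts_us,tl_us,L_mm`; each row must satisfy
#' `ts > tl > 0` and `L > 0`.
#'
#' @param path Path to the CSV file.
#' @return A data.frame usable by [replicate_summary()].
#' @export
read_echoes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("replicate", "ts_us", "tl_us", "L_mm")
  if (!identical(names(df)[seq_along(need)], need))
    stop("echo CSV must have header replicate,ts_us,tl_us,L_mm",
         call. = FALSE)
  for (i in seq_len(nrow(df))) {
    if (!(df$ts_us[i] > df$tl_us[i] && df$tl_us[i] > 0 && df$L_mm[i] > 0))
      stop(sprintf("invalid echo record at row %d of %s", i, path),
           call. = FALSE)
  }
  df
}

#' Write an ultrasonic measurement table
#'
#' @param echoes A data.frame with columns `replicate,ts_us,tl_us,L_mm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_echoes <- function(echoes, path) {
  utils::write.csv(echoes[, c("replicate", "ts_us", "tl_us", "L_mm")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' Bundles the cross-cutting defaults: X-ray wavelength (Cu K-alpha1),
#' Scherrer factor, instrumental broadening, supercell factor and the radii
#' table. [read_config()] loads a flat JSON file with any subset of these
#' keys; unknown keys are rejected.
#'
#' @param wavelength X-ray wavelength (Angstrom).
#' @param K Scherrer shape factor.
#' @param instrumental_deg Instrumental broadening (degrees).
#' @param supercell Supercell replication factor.
#' @param radii Named radii table (Angstrom).
#' @return A list of class `usdm_config`.
#' @export
usdm_config <- function(wavelength = 1.5406, K = 0.9,
                        instrumental_deg = 0.02, supercell = 2,
                        radii = default_radii()) {
  stopifnot(wavelength > 0, K > 0, instrumental_deg >= 0, supercell >= 1,
            is.numeric(radii), !is.null(names(radii)), all(radii > 0))
  structure(list(wavelength = wavelength, K = K,
                 instrumental_deg = instrumental_deg,
                 supercell = as.integer(supercell), radii = radii),
            class = "usdm_config")
}

#' @rdname usdm_config
#' @param path Path to a flat JSON configuration file.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("wavelength", "K", "instrumental_deg", "supercell", "radii")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L)
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$radii)) raw$radii <- unlist(raw$radii)
  do.call(usdm_config, raw)
}
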