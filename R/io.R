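#' Read and write multilayer configurations as GRO-dialect files
#'
#' The writer emits fixed-column GRO coordinate records (positions in nm,
#' 0.001 nm precision) with one residue per lipid. The residue name encodes
#' the layer as `L000`, `L001`, ...; atom names encode the bead role: `H`
#' (head), `T1`, `T2`, ... (tail), `TE` (terminal). The box lengths go on the
#' trailer line. The reader reconstructs the lipid, layer and role labels
#' from those conventions, so a write-read cycle round-trips to the file
#' precision (0.001 nm = 0.01 Angstrom).
#'
#' @param config A [lipid_configuration].
#' @param path File path.
#' @param title Title line written to the file.
#' @return `read_gro()` returns a [lipid_configuration]; `write_gro()`
#'   returns `path` invisibly.
#' @examples
#' cfg <- simulate_multilayer(n_layers = 2, lipids_per_layer = 9, seed = 1)
#' f <- tempfile(fileext = ".gro")
#' write_gro(cfg, f)
#' cfg2 <- read_gro(f)
#' @export
write_gro <- function(config, path, title = "lamellaflex multilayer") {
  beads <- tibble::as_tibble(config)
  box <- attr(config, "box")
  role_rank <- c(head = 0L, tail = 1L, terminal = 2L)
  beads <- beads[order(beads$lipid_id, role_rank[beads$bead_role]), ]
  # per-lipid atom names: H, T1..Tk, TE
  counts <- table(beads$lipid_id)[as.character(unique(beads$lipid_id))]
  name_one <- function(n) c("H", if (n > 2) paste0("T", seq_len(n - 2)), "TE")
  atom_names <- unlist(lapply(as.integer(counts), name_one), use.names = FALSE)
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   beads$lipid_id %% 100000L,
                   sprintf("L%03d", beads$layer_index),
                   atom_names,
                   seq_len(nrow(beads)) %% 100000L,
                   beads$x / 10, beads$y / 10, beads$z / 10)
  writeLines(c(title, sprintf("%d", nrow(beads)), lines,
               sprintf("%10.5f%10.5f%10.5f", box[1] / 10, box[2] / 10,
                       box[3] / 10)),
             path)
  invisible(path)
}

#' @rdname write_gro
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) {
    rlang::abort("not a GRO file: fewer than three lines",
                 class = "lamellaflex_format_error")
  }
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || length(lines) < n + 3) {
    rlang::abort("malformed GRO file: bad atom count or missing box line",
                 class = "lamellaflex_format_error")
  }
  atoms <- lines[3:(n + 2)]
  field <- function(s, a, b) substr(s, a, b)
  num <- function(v, what, lineno) {
    out <- suppressWarnings(as.numeric(v))
    if (anyNA(out)) {
      bad <- lineno[which(is.na(out))[1]]
      rlang::abort(sprintf("malformed %s in GRO line %d", what, bad),
                   class = "lamellaflex_parse_error")
    }
    out
  }
  lineno <- 3:(n + 2)
  resid <- num(field(atoms, 1, 5), "residue id", lineno)
  resname <- trimws(field(atoms, 6, 10))
  atomname <- trimws(field(atoms, 11, 15))
  x <- num(field(atoms, 21, 28), "x coordinate", lineno) * 10
  y <- num(field(atoms, 29, 36), "y coordinate", lineno) * 10
  z <- num(field(atoms, 37, 44), "z coordinate", lineno) * 10
  layer <- suppressWarnings(as.integer(sub("^L", "", resname)))
  if (anyNA(layer)) {
    rlang::abort("residue names do not follow the L000 layer convention",
                 class = "lamellaflex_format_error")
  }
  role <- dplyr::case_when(
    atomname == "H" ~ "head",
    atomname == "TE" ~ "terminal",
    grepl("^T[0-9]+$", atomname) ~ "tail",
    TRUE ~ NA_character_)
  if (anyNA(role)) {
    rlang::abort("atom names do not follow the H/T#/TE role convention",
                 class = "lamellaflex_format_error")
  }
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3]),
                                               "\\s+")[[1]]))
  if (length(boxv) < 3 || anyNA(boxv[1:3])) {
    rlang::abort("missing or malformed box line",
                 class = "lamellaflex_format_error")
  }
  # residue ids wrap at 100000 in the format; unwrap by detecting decreases
  resid <- unwrap_ids(resid)
  lipid_configuration(
    tibble::tibble(x = x, y = y, z = z,
                   lipid_id = as.integer(resid),
                   layer_index = layer, bead_role = role),
    box = boxv[1:3] * 10)
}

unwrap_ids <- function(ids) {
  jumps <- c(0, cumsum(diff(ids) < 0)) * 100000
  ids + jumps
}

#' Read and write configurations as labeled XYZ
#'
#' An extended XYZ dialect: first line the bead count, second line
#' `box <bx> <by> <bz> A`, then one line per bead:
#' `<role-name> <x> <y> <z> <lipid_id> <layer_index>` with coordinates in
#' Angstrom. Role names follow the H/T#/TE convention of [write_gro()].
#'
#' @inheritParams write_gro
#' @return `read_xyz_labeled()` returns a [lipid_configuration];
#'   `write_xyz_labeled()` returns `path` invisibly.
#' @export
write_xyz_labeled <- function(config, path) {
  beads <- tibble::as_tibble(config)
  box <- attr(config, "box")
  role_rank <- c(head = 0L, tail = 1L, terminal = 2L)
  beads <- beads[order(beads$lipid_id, role_rank[beads$bead_role]), ]
  counts <- table(beads$lipid_id)[as.character(unique(beads$lipid_id))]
  name_one <- function(n) c("H", if (n > 2) paste0("T", seq_len(n - 2)), "TE")
  atom_names <- unlist(lapply(as.integer(counts), name_one), use.names = FALSE)
  writeLines(c(
    sprintf("%d", nrow(beads)),
    sprintf("box %.6f %.6f %.6f A", box[1], box[2], box[3]),
    sprintf("%-4s %14.6f %14.6f %14.6f %8d %4d",
            atom_names, beads$x, beads$y, beads$z,
            beads$lipid_id, beads$layer_index)),
    path)
  invisible(path)
}

#' @rdname write_xyz_labeled
#' @export
read_xyz_labeled <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) {
    rlang::abort("not a labeled-XYZ file", class = "lamellaflex_format_error")
  }
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  boxv <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (is.na(n) || boxv[1] != "box" || length(boxv) < 4) {
    rlang::abort("labeled-XYZ header must be count then 'box bx by bz A'",
                 class = "lamellaflex_format_error")
  }
  rows <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  if (any(lengths(rows) < 6)) {
    rlang::abort("malformed labeled-XYZ atom line",
                 class = "lamellaflex_parse_error")
  }
  m <- do.call(rbind, rows)
  role <- dplyr::case_when(
    m[, 1] == "H" ~ "head",
    m[, 1] == "TE" ~ "terminal",
    grepl("^T[0-9]+$", m[, 1]) ~ "tail",
    TRUE ~ NA_character_)
  if (anyNA(role)) {
    rlang::abort("atom names do not follow the H/T#/TE role convention",
                 class = "lamellaflex_format_error")
  }
  lipid_configuration(
    tibble::tibble(x = as.numeric(m[, 2]), y = as.numeric(m[, 3]),
                   z = as.numeric(m[, 4]),
                   lipid_id = as.integer(m[, 5]),
                   layer_index = as.integer(m[, 6]),
                   bead_role = role),
    box = as.numeric(boxv[2:4]))
}

#' Read a multilayer configuration file, GRO or labeled-XYZ
#'
#' Dispatches on the file extension: `.gro` to [read_gro()], `.xyz` to
#' [read_xyz_labeled()].
#'
#' @param path File path.
#' @return A [lipid_configuration].
#' @export
read_configuration_file <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path),
                 class = "lamellaflex_format_error")
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         gro = read_gro(path),
         xyz = read_xyz_labeled(path),
         rlang::abort("unsupported configuration format (use .gro or .xyz)",
                      class = "lamellaflex_format_error"))
}

#' Read and write 1D scattering profiles as two-column text
#'
#' Whitespace- or comma-separated `q intensity` columns with `#` comment
#' lines; q in inverse Angstrom.
#'
#' @param profile A `scattering_profile`.
#' @param path File path.
#' @return `read_scattering_profile()` returns a `scattering_profile`;
#'   the writer returns `path` invisibly.
#' @export
write_scattering_profile <- function(profile, path) {
  writeLines(c(
    sprintf("# label: %s", attr(profile, "label") %||% ""),
    "# q_invA  intensity",
    sprintf("%.8g  %.8g", profile$q, profile$intensity)),
    path)
  invisible(path)
}

#' @rdname write_scattering_profile
#' @export
read_scattering_profile <- function(path) {
  lines <- readLines(path)
  label <- ""
  lab <- grep("^#\\s*label:", lines, value = TRUE)
  if (length(lab) > 0) label <- trimws(sub("^#\\s*label:", "", lab[1]))
  data_lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(data_lines) < 8) {
    rlang::abort("profile file must contain at least 8 data rows",
                 class = "lamellaflex_format_error")
  }
  sep_comma <- grepl(",", data_lines[1])
  parts <- strsplit(trimws(data_lines),
                    if (sep_comma) "\\s*,\\s*" else "\\s+")
  m <- do.call(rbind, lapply(parts, function(p) as.numeric(p[1:2])))
  if (anyNA(m)) {
    rlang::abort("non-numeric entries in profile data",
                 class = "lamellaflex_parse_error")
  }
  scattering_profile(m[, 1], m[, 2], label = label)
}

#' Read and write topography maps
#'
#' CSV writes the bare height grid (nm). TIFF writes a 32-bit float image
#' whose samples are the heights affinely mapped to `[0, 1]`; the mapping
#' (`offset`, `scale`, both nm) and the pixel size are recorded in a JSON
#' sidecar at `<path>.json`, which the reader uses to restore physical
#' heights. The format is chosen from the file extension. For CSV the pixel
#' size must be supplied when reading.
#'
#' @param topo A `topography_map`.
#' @param path File path ending in `.csv` or `.tif`/`.tiff`.
#' @param pixel_size Pixel size in nm; required when reading CSV, optional
#'   (overrides the sidecar) for TIFF.
#' @return `read_topography()` returns a `topography_map`; the writer
#'   returns `path` invisibly.
#' @export
write_topography <- function(topo, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.table(topo$heights, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else if (ext %in% c("tif", "tiff")) {
    h <- topo$heights
    offset <- min(h)
    scale <- max(h) - offset
    norm <- if (scale > 0) (h - offset) / scale else h * 0
    tiff::writeTIFF(norm, path, bits.per.sample = 32, reduce = FALSE)
    jsonlite::write_json(
      list(offset_nm = offset, scale_nm = scale,
           pixel_size_nm = topo$pixel_size),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    rlang::abort("unsupported topography format (use .csv or .tif)",
                 class = "lamellaflex_format_error")
  }
  invisible(path)
}

#' @rdname write_topography
#' @export
read_topography <- function(path, pixel_size = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    if (is.null(pixel_size)) {
      rlang::abort("pixel_size is required when reading CSV topography",
                   class = "lamellaflex_invalid_parameter")
    }
    h <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = FALSE)
    if (is.list(img)) img <- img[[1]]
    if (length(dim(img)) == 3) img <- img[, , 1]
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      img <- img * meta$scale_nm + meta$offset_nm
      if (is.null(pixel_size)) pixel_size <- meta$pixel_size_nm
    }
    if (is.null(pixel_size)) {
      rlang::abort("pixel_size missing: no sidecar found for TIFF topography",
                   class = "lamellaflex_invalid_parameter")
    }
    h <- img
  } else {
    rlang::abort("unsupported topography format (use .csv or .tif)",
                 class = "lamellaflex_format_error")
  }
  dimnames(h) <- NULL
  topography_map(h, pixel_size)
}

#' Read and write buckle-geometry tables
#'
#' Tab-separated text with the header `lambda_nm<TAB>t_nm<TAB>strain`.
#'
#' @param obs A data frame with columns `lambda_nm`, `t_nm`, `strain`.
#' @param path File path.
#' @return `read_buckles()` returns a tibble with those three columns; the
#'   writer returns `path` invisibly.
#' @export
write_buckles <- function(obs, path) {
  utils::write.table(obs[, c("lambda_nm", "t_nm", "strain")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_buckles
#' @export
read_buckles <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  required <- c("lambda_nm", "t_nm", "strain")
  if (!all(required %in% names(df))) {
    rlang::abort("buckle table must have columns lambda_nm, t_nm, strain",
                 class = "lamellaflex_format_error")
  }
  tibble::as_tibble(df[, required])
}
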