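CONTAINER_MAGIC <- "PHFLIM01"

#' Canonical single-file FLIM container
#'
#' `write_container` / `read_container` implement the package's neutral
#' on-disk format for both kinds of pixel data. The layout is a single
#' binary file:
#' \enumerate{
#'   \item 8-byte ASCII magic `"PHFLIM01"`;
#'   \item little-endian int32: byte length of the metadata block;
#'   \item UTF-8 JSON metadata holding `kind` (`"decay_stack"` or
#'     `"phasor_field"`), `rep_rate` (Hz), `dims`, and for decay stacks
#'     `harmonic` + `bin_centers` (s), for phasor rasters the `harmonics`
#'     vector present in the file;
#'   \item float64 little-endian data planes: `counts` (column-major,
#'     `(time, row, col)`) for decay stacks; `intensity` then, per
#'     harmonic, `phase` (rad) and `mod` planes for phasor rasters.
#' }
#' Invalid phasor pixels are stored with zero intensity; validity is
#' recovered as `intensity > 0`.
#'
#' @param x A [decay_stack()], a `phasor_field`, or a list of
#'   `phasor_field`s at different harmonics of one acquisition.
#' @param path File path.
#' @return `write_container` returns `path` invisibly; `read_container`
#'   returns the stored object (for multi-harmonic rasters, the field at
#'   `harmonic`).
#' @export
write_container <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (inherits(x, "decay_stack")) {
    meta <- list(
      kind = "decay_stack",
      rep_rate = x$params$rep_rate,
      harmonic = x$params$harmonic,
      dims = dim(x$counts),
      bin_centers = x$bin_centers
    )
    planes <- as.numeric(x$counts)
  } else {
    fields <- if (inherits(x, "phasor_field")) list(x) else x
    if (!all(vapply(fields, inherits, TRUE, "phasor_field"))) {
      stop("`x` must be a decay_stack, phasor_field, or list of phasor_fields",
           call. = FALSE)
    }
    f1 <- fields[[1]]
    meta <- list(
      kind = "phasor_field",
      rep_rate = f1$params$rep_rate,
      dims = dim(f1$g),
      harmonics = vapply(fields, function(f) f$params$harmonic, integer(1))
    )
    intensity <- f1$intensity
    intensity[!f1$valid] <- 0
    planes <- as.numeric(intensity)
    for (f in fields) {
      phase <- atan2(f$s, f$g); mod <- sqrt(f$g^2 + f$s^2)
      phase[!f$valid] <- 0; mod[!f$valid] <- 0
      planes <- c(planes, as.numeric(phase), as.numeric(mod))
    }
  }
  mjson <- charToRaw(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  writeChar(CONTAINER_MAGIC, con, nchars = 8L, eos = NULL)
  writeBin(length(mjson), con, size = 4L, endian = "little")
  writeBin(mjson, con)
  writeBin(planes, con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_container
#' @param harmonic For multi-harmonic phasor containers, which harmonic to
#'   return (default: the first stored).
#' @export
read_container <- function(path, harmonic = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 8L, useBytes = TRUE)
  if (!identical(magic, CONTAINER_MAGIC)) {
    stop("format error: bad magic (not a phasorflim container): ", path,
         call. = FALSE)
  }
  mlen <- readBin(con, "integer", size = 4L, endian = "little")
  meta <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", mlen)))
  for (fld in c("kind", "rep_rate", "dims")) {
    if (is.null(meta[[fld]])) {
      stop("format error: metadata field missing: ", fld, call. = FALSE)
    }
  }
  if (!is.numeric(meta$rep_rate) || meta$rep_rate <= 0) {
    stop("format error: rep_rate must be > 0", call. = FALSE)
  }
  if (identical(meta$kind, "decay_stack")) {
    for (fld in c("harmonic", "bin_centers")) {
      if (is.null(meta[[fld]])) {
        stop("format error: metadata field missing: ", fld, call. = FALSE)
      }
    }
    d <- as.integer(meta$dims)
    counts <- readBin(con, "numeric", prod(d), size = 8L, endian = "little")
    if (length(counts) != prod(d)) {
      stop("format error: truncated counts block", call. = FALSE)
    }
    decay_stack(array(counts, d), meta$bin_centers,
                acquisition_params(meta$rep_rate, meta$harmonic))
  } else if (identical(meta$kind, "phasor_field")) {
    if (is.null(meta$harmonics)) {
      stop("format error: metadata field missing: harmonics", call. = FALSE)
    }
    d <- as.integer(meta$dims)
    np <- prod(d)
    nh <- length(meta$harmonics)
    planes <- readBin(con, "numeric", np * (1 + 2 * nh), size = 8L,
                      endian = "little")
    if (length(planes) != np * (1 + 2 * nh)) {
      stop("format error: truncated plane block", call. = FALSE)
    }
    if (is.null(harmonic)) harmonic <- meta$harmonics[1]
    hix <- match(harmonic, meta$harmonics)
    if (is.na(hix)) {
      stop("harmonic ", harmonic, " not stored (available: ",
           paste(meta$harmonics, collapse = ", "), ")", call. = FALSE)
    }
    intensity <- matrix(planes[seq_len(np)], d[1], d[2])
    off <- np + (hix - 1) * 2 * np
    phase <- matrix(planes[off + seq_len(np)], d[1], d[2])
    mod <- matrix(planes[off + np + seq_len(np)], d[1], d[2])
    valid <- intensity > 0
    g <- mod * cos(phase); s <- mod * sin(phase)
    g[!valid] <- NA_real_; s[!valid] <- NA_real_
    phasor_field_new(g, s, intensity, valid,
                     acquisition_params(meta$rep_rate, harmonic))
  } else {
    stop("format error: unknown container kind: ", meta$kind, call. = FALSE)
  }
}

#' Read a SimFCS-style `.ref` phasor raster
#'
#' Best-effort reader for the `.ref` dialect: consecutive 32-bit
#' little-endian float planes in raster (row-major) order, by default
#' `intensity, phase(h1), mod(h1), phase(h2), mod(h2), ...`, with phase
#' stored in degrees. Every assumption (image dims, plane order, phase
#' unit) is exposed as an argument because the layout is not formally
#' documented; validate against files from your own instrument.
#'
#' @param path File path.
#' @param dims `c(rows, cols)`; default `c(256, 256)`.
#' @param rep_rate Laser repetition rate (Hz) to attach; default 80e6.
#' @param harmonic Which stored harmonic to return; default 1.
#' @param phase_unit `"degrees"` (default) or `"radians"`.
#' @param plane_order Order of the per-harmonic pair; default
#'   `c("phase", "mod")`.
#' @return A `phasor_field` (`g = m cos(phi)`, `s = m sin(phi)`;
#'   `valid = intensity > 0`).
#' @export
read_ref <- function(path, dims = c(256L, 256L), rep_rate = 80e6,
                     harmonic = 1L, phase_unit = c("degrees", "radians"),
                     plane_order = c("phase", "mod")) {
  phase_unit <- match.arg(phase_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  np <- prod(dims)
  sz <- file.size(path)
  nplanes <- sz / (4 * np)
  if (nplanes != round(nplanes) || nplanes < 3 || nplanes %% 2 != 1) {
    stop(sprintf(
      paste0(".ref dialect error: file holds %.2f planes of %d x %d float32; ",
             "expected an odd count >= 3 (intensity + phase/mod pairs)"),
      nplanes, dims[1], dims[2]), call. = FALSE)
  }
  nh <- (nplanes - 1) / 2
  if (harmonic > nh) {
    stop("harmonic ", harmonic, " not stored: file has ", nh, " harmonic(s)",
         call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", np * nplanes, size = 4L, endian = "little")
  plane <- function(i) {
    matrix(raw[(i - 1) * np + seq_len(np)], dims[1], dims[2], byrow = TRUE)
  }
  intensity <- plane(1)
  base <- 2 + (harmonic - 1) * 2
  a <- plane(base); b <- plane(base + 1)
  if (identical(plane_order, c("phase", "mod"))) { phase <- a; mod <- b }
  else if (identical(plane_order, c("mod", "phase"))) { phase <- b; mod <- a }
  else stop("`plane_order` must be a permutation of c('phase','mod')",
            call. = FALSE)
  if (phase_unit == "degrees") phase <- phase * pi / 180
  valid <- intensity > 0
  g <- mod * cos(phase); s <- mod * sin(phase)
  g[!valid] <- NA_real_; s[!valid] <- NA_real_
  phasor_field_new(g, s, intensity, valid,
                   acquisition_params(rep_rate, as.integer(harmonic)))
}

#' Write a phasor field in the `.ref` dialect
#'
#' Counterpart of [read_ref()] with the same default layout assumptions
#' (row-major float32 planes; phase in degrees). Mostly used to build
#' test fixtures and to exchange data with SimFCS-compatible tools.
#'
#' @param field A `phasor_field`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ref <- function(field, path) {
  if (!inherits(field, "phasor_field")) {
    stop("`field` must be a phasor_field", call. = FALSE)
  }
  intensity <- field$intensity
  intensity[!field$valid] <- 0
  phase <- atan2(field$s, field$g) * 180 / pi
  mod <- sqrt(field$g^2 + field$s^2)
  phase[!field$valid] <- 0; mod[!field$valid] <- 0
  con <- file(path, "wb")
  on.exit(close(con))
  for (m in list(intensity, phase, mod)) {
    writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Vendor-format adapter registry
#'
#' `.R64` and `.ifli` are compressed / undocumented vendor layouts this
#' package does not decode. Users with a working decoder can register a
#' reader (`function(path, ...) -> phasor_field`) for an extension;
#' [read_flim_input()] dispatches on extension across the canonical
#' container, `.ref`, and any registered adapters.
#'
#' @param extension File extension without the dot (e.g. `"r64"`).
#' @param reader A function `(path, ...)` returning a `phasor_field` or
#'   `decay_stack`.
#' @export
register_flim_reader <- function(extension, reader) {
  stopifnot(is.function(reader))
  .flim_readers[[tolower(extension)]] <- reader
  invisible(NULL)
}

.flim_readers <- new.env(parent = emptyenv())

#' @rdname register_flim_reader
#' @param path Input file.
#' @param ... Passed to the dispatched reader (e.g. `dims` for `.ref`).
#' @export
read_flim_input <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ref") return(read_ref(path, ...))
  if (ext %in% c("flim", "pfc")) return(read_container(path, ...))
  rd <- .flim_readers[[ext]]
  if (!is.null(rd)) return(rd(path, ...))
  if (ext %in% c("r64", "ifli")) {
    stop("unsupported dialect '.", ext, "': vendor binary layout is not ",
         "decoded; register an adapter with register_flim_reader()",
         call. = FALSE)
  }
  stop("unknown FLIM input extension: .", ext, call. = FALSE)
}

#' Parse a `date_name_replica` file name
#'
#' File names follow `date_sample name_replica` (the sample name may
#' contain spaces and underscores are split from the outside in): the
#' replica number is the last underscore-delimited field, the date the
#' first, the sample name everything in between.
#'
#' @param path A file name or path (extension is stripped).
#' @return A list with `date`, `sample_name`, `replica` (integer >= 1).
#' @examples
#' parse_sample_name("2023_experiment 1_1.ref")
#' @export
parse_sample_name <- function(path) {
  base <- tools::file_path_sans_ext(basename(path))
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  if (length(parts) < 3L) {
    stop("file name '", base, "' does not match date_name_replica",
         call. = FALSE)
  }
  replica <- suppressWarnings(as.integer(parts[length(parts)]))
  if (is.na(replica) || replica < 1L) {
    stop("replica field of '", base, "' is not a positive integer",
         call. = FALSE)
  }
  list(
    date = parts[1],
    sample_name = paste(parts[-c(1, length(parts))], collapse = "_"),
    replica = replica
  )
}

#' Read / write a binary pixel mask as single-plane TIFF
#'
#' Masks are 8-bit single-plane TIFFs; any nonzero pixel is kept.
#'
#' @param path File path.
#' @return `read_mask`: a logical matrix (TRUE = keep).
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0
}

#' @rdname read_mask
#' @param mask Logical or 0/1 numeric matrix.
#' @export
write_mask <- function(mask, path) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  tiff::writeTIFF(m, path, bits.per.sample = 8L)
  invisible(path)
}

#' Export a raster map as 32-bit float TIFF
#'
#' Absent values (`NA`) are written as the sentinel `-1`, which cannot be
#' a lifetime or intensity.
#'
#' @param map Numeric matrix (e.g. from [lifetime_map()]).
#' @param path Output path.
#' @export
write_map <- function(map, path) {
  m <- map
  m[!is.finite(m)] <- -1
  # physical values (ns, counts) are stored as-is in float32 samples;
  # the tiff package warns about the [0,1] display convention only
  withCallingHandlers(
    tiff::writeTIFF(m, path, bits.per.sample = 32L, reduce = FALSE),
    warning = function(w) {
      if (grepl("outside the \\[0, 1\\] range", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  invisible(path)
}

#' Read a species definition table
#'
#' Delimited text with header columns `name`, `tau_ns`, `epsilon`, `qy`
#' and optional `g`, `s` overrides for measured pure-species phasors.
#'
#' @param path CSV path.
#' @param params [acquisition_params()] used for closed-form phasors of
#'   species without an override.
#' @return A list of [flim_species()] objects, named by species.
#' @export
read_species_table <- function(path, params = acquisition_params()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "tau_ns", "epsilon", "qy")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("species table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    g <- if ("g" %in% names(df)) df$g[i] else NA_real_
    s <- if ("s" %in% names(df)) df$s[i] else NA_real_
    flim_species(df$name[i], df$tau_ns[i], df$epsilon[i], df$qy[i],
                 params = params,
                 g = if (is.finite(g)) g else NULL,
                 s = if (is.finite(s)) s else NULL)
  })
  names(out) <- df$name
  out
}

#' Serialize / read a region set as delimited text
#'
#' One vertex per row with columns `region_id`, `kind`
#' (`perimeter`/`phasor`), `parent`, `point_count`, `g`, `s`, under a
#' versioned comment header.
#'
#' @param regions A `region_set` from [detect_regions()].
#' @param path Output path.
#' @export
write_regions <- function(regions, path) {
  rows <- list()
  for (i in seq_along(regions$perimeters)) {
    p <- regions$perimeters[[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      region_id = i, kind = "perimeter", parent = NA_integer_,
      point_count = p$count, g = p$polygon[, 1], s = p$polygon[, 2]
    )
  }
  for (i in seq_along(regions$phasors)) {
    p <- regions$phasors[[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      region_id = i, kind = "phasor", parent = p$parent,
      point_count = p$count, g = p$polygon[, 1], s = p$polygon[, 2]
    )
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region_id = integer(0), kind = character(0),
               parent = integer(0), point_count = integer(0),
               g = numeric(0), s = numeric(0))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# phasorflim-regions v1", con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# phasorflim-regions")) {
    stop("not a phasorflim regions file: ", path, call. = FALSE)
  }
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
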