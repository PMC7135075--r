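#' Labeled bone surface model
#'
#' Container for one bone's surface as a bare point set in millimetres, with
#' the anatomical side and named region labels ("head", "neck", "lunate").
#' Mesh connectivity is deliberately not retained: every computation in this
#' package operates on vertices only.
#'
#' @param points n x 3 numeric matrix of coordinates in mm.
#' @param side `"left"` or `"right"`.
#' @param labels named list of integer vectors (1-based point indices).
#'   Recognised regions are `"head"`, `"neck"` and `"lunate"`; any subset may
#'   be present.
#' @param frame three-letter axis-convention tag (see [axis_convention()]).
#'   Default `"RAI"`: +x towards the patient's right, +y anterior,
#'   +z inferior.
#' @return An object of class `surface_model`.
#' @export
surface_model <- function(points, side, labels = list(), frame = "RAI") {
  points <- as_points(points)
  side <- check_side(side)
  axis_convention(frame)  # validates the tag
  if (length(labels)) {
    if (is.null(names(labels)) || any(!nzchar(names(labels))))
      abort_validation("labels must be a named list")
    labels <- lapply(labels, function(ix) {
      ix <- as.integer(ix)
      if (any(is.na(ix)) || any(ix < 1L) || any(ix > nrow(points)))
        abort_validation("label index out of range")
      sort(unique(ix))
    })
    for (reg in c("head", "lunate"))
      if (reg %in% names(labels) && length(labels[[reg]]) == 0L)
        abort_validation(sprintf("region \"%s\" is present but empty", reg))
  }
  structure(list(points = points, side = side, labels = labels, frame = frame),
            class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("<surface_model> %d points, side=%s, frame=%s\n",
              nrow(x$points), x$side, x$frame))
  if (length(x$labels))
    cat("  regions:", paste(sprintf("%s(%d)", names(x$labels),
                                    vapply(x$labels, length, 1L)),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Extract a labeled region's points
#'
#' @param model a [surface_model()].
#' @param region region name.
#' @return matrix of the region's points.
#' @export
region_points <- function(model, region) {
  if (!region %in% names(model$labels))
    abort_validation(sprintf("model has no \"%s\" region label", region))
  model$points[model$labels[[region]], , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Mesh vertex readers. Only vertices are extracted; faces are parsed just far
# enough to be skipped. Supported: PLY (ascii, binary_little_endian), STL
# (ascii, binary), OBJ (ascii).

ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

read_ply_vertices <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) abort_io("not a PLY file")
  fmt <- NULL; elements <- list(); cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) abort_io("unterminated PLY header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) abort_io("PLY property before element")
      if (tok[2] == "list")
        elements[[cur]]$props[[tok[5]]] <- list(list = TRUE,
                                                count_type = tok[3],
                                                item_type = tok[4])
      else
        elements[[cur]]$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
    } else if (tok[1] == "end_header") break
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    abort_io(sprintf("unsupported PLY format \"%s\"", fmt %||% "?"))
  if (!"vertex" %in% names(elements)) abort_io("PLY has no vertex element")

  read_binary_element <- function(el, want_xyz) {
    props <- el$props
    if (any(vapply(props, `[[`, TRUE, "list"))) {
      # element with list properties (faces): read record-by-record
      for (i in seq_len(el$count)) {
        for (p in props) {
          if (p$list) {
            n <- read_scalar_bin(con, p$count_type)
            if (n > 0) readBin(con, "raw", n * ply_type_size[[p$item_type]])
          } else readBin(con, "raw", ply_type_size[[p$type]])
        }
      }
      return(NULL)
    }
    rec <- sum(vapply(props, function(p) ply_type_size[[p$type]], 1L))
    raw <- readBin(con, "raw", rec * el$count)
    if (length(raw) < rec * el$count) abort_io("truncated PLY payload")
    if (!want_xyz) return(NULL)
    off <- 0L; out <- matrix(NA_real_, el$count, 3L)
    for (nm in names(props)) {
      sz <- ply_type_size[[props[[nm]]$type]]
      if (nm %in% c("x", "y", "z")) {
        idx <- rep(off + seq_len(sz), el$count) +
          rep((seq_len(el$count) - 1L) * rec, each = sz)
        vals <- decode_ply_column(raw[idx], props[[nm]]$type, el$count)
        out[, match(nm, c("x", "y", "z"))] <- vals
      }
      off <- off + sz
    }
    out
  }

  if (fmt == "ascii") {
    body <- readLines(con)
    pos <- 0L; verts <- NULL
    for (nm in names(elements)) {
      el <- elements[[nm]]
      block <- body[pos + seq_len(el$count)]
      pos <- pos + el$count
      if (nm == "vertex") {
        scalar <- names(el$props)
        cols <- match(c("x", "y", "z"), scalar)
        if (any(is.na(cols))) abort_io("PLY vertex element lacks x/y/z")
        toks <- strsplit(trimws(block), "\\s+")
        verts <- t(vapply(toks, function(tk) as.numeric(tk[cols]),
                          numeric(3L)))
      }
    }
    verts
  } else {
    verts <- NULL
    for (nm in names(elements)) {
      v <- read_binary_element(elements[[nm]], want_xyz = nm == "vertex")
      if (nm == "vertex") {
        if (is.null(v)) abort_io("PLY vertex element has list properties")
        verts <- v
      }
    }
    verts
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_scalar_bin <- function(con, type) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32")) readBin(con, "double", 1L, size = 4L, endian = "little")
  else if (type %in% c("double", "float64")) readBin(con, "double", 1L, size = 8L, endian = "little")
  else if (type %in% c("uchar", "uint8", "ushort", "uint16"))
    readBin(con, "integer", 1L, size = sz, signed = FALSE, endian = "little")
  else readBin(con, "integer", 1L, size = sz, endian = "little")
}

decode_ply_column <- function(raw, type, n) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32"))
    readBin(raw, "double", n, size = 4L, endian = "little")
  else if (type %in% c("double", "float64"))
    readBin(raw, "double", n, size = 8L, endian = "little")
  else if (type %in% c("uchar", "uint8", "ushort", "uint16"))
    as.numeric(readBin(raw, "integer", n, size = sz, signed = FALSE, endian = "little"))
  else as.numeric(readBin(raw, "integer", n, size = sz, endian = "little"))
}

read_stl_vertices <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", 80L)
  is_binary <- FALSE
  if (sz >= 84) {
    ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(ntri) == 1L && !is.na(ntri) && ntri >= 0 && sz == 84 + 50 * ntri)
      is_binary <- TRUE
  }
  if (is_binary) {
    raw <- readBin(con, "raw", 50L * ntri)
    # 50-byte records: normal (3 floats), 3 vertices (9 floats), 2-byte attr
    idx <- rep(seq_len(48L), ntri) + rep((seq_len(ntri) - 1L) * 50L, each = 48L)
    f <- readBin(raw[idx], "double", 12L * ntri, size = 4L, endian = "little")
    m <- matrix(f, ncol = 12L, byrow = TRUE)
    # per-facet vertex order preserved: v1, v2, v3 of facet 1, then facet 2...
    out <- matrix(NA_real_, 3L * ntri, 3L)
    out[seq(1L, by = 3L, length.out = ntri), ] <- m[, 4:6]
    out[seq(2L, by = 3L, length.out = ntri), ] <- m[, 7:9]
    out[seq(3L, by = 3L, length.out = ntri), ] <- m[, 10:12]
    out
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vl) == 0L) abort_io("no vertices found in STL file")
    toks <- strsplit(trimws(vl), "\\s+")
    t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3L)))
  }
}

read_obj_vertices <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  if (length(vl) == 0L) abort_io("no vertices found in OBJ file")
  toks <- strsplit(trimws(vl), "\\s+")
  t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3L)))
}

#' Read a surface model from a mesh file
#'
#' Extracts the vertex set of a PLY, STL or OBJ surface (format inferred from
#' the file extension; PLY may be ascii or binary little-endian, STL ascii or
#' binary). Duplicate vertices closer than 1e-9 mm are merged, keeping first
#' occurrences; region labels from the sidecar are remapped accordingly.
#' Connectivity is discarded — the downstream estimators are point-based.
#'
#' All coordinates are taken to be millimetres; no unit detection is
#' attempted.
#'
#' @param path mesh file path.
#' @param labels_path optional JSON sidecar: an object mapping region name to
#'   an array of 0-based vertex indices (indices refer to the file's vertex
#'   order, before de-duplication).
#' @param side `"left"` or `"right"`.
#' @param frame axis-convention tag, see [axis_convention()].
#' @return a [surface_model()].
#' @export
read_surface <- function(path, labels_path = NULL, side, frame = "RAI") {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  verts <- switch(ext,
    ply = read_ply_vertices(path),
    stl = read_stl_vertices(path),
    obj = read_obj_vertices(path),
    abort_io(sprintf("unsupported mesh format \".%s\" (PLY/STL/OBJ)", ext)))
  if (is.null(verts) || nrow(verts) == 0L) abort_io("mesh has no vertices")
  if (!all(is.finite(verts))) abort_io("mesh contains non-finite vertices")

  # merge vertices identical to within 1e-9 mm (STL repeats each vertex per
  # facet); `map` sends original file index -> merged index
  key <- paste(round(verts[, 1] * 1e9), round(verts[, 2] * 1e9),
               round(verts[, 3] * 1e9))
  first <- !duplicated(key)
  map <- match(key, key[first])
  points <- verts[first, , drop = FALSE]

  labels <- list()
  if (!is.null(labels_path)) {
    if (!file.exists(labels_path))
      abort_io(sprintf("label sidecar not found: %s", labels_path))
    raw <- jsonlite::read_json(labels_path, simplifyVector = TRUE)
    labels <- lapply(raw, function(ix) {
      ix <- as.integer(ix)
      if (any(is.na(ix)) || any(ix < 0L) || any(ix >= nrow(verts)))
        abort_validation("label sidecar index out of range")
      sort(unique(map[ix + 1L]))
    })
  }
  surface_model(points, side = side, labels = labels, frame = frame)
}

#' Write a surface model to a mesh file
#'
#' Writes vertices as ascii PLY, OBJ, or ascii STL (each vertex emitted as a
#' degenerate facet — STL carries no standalone vertices). An optional JSON
#' label sidecar (0-based indices) is written alongside.
#'
#' @param model a [surface_model()].
#' @param path output path; extension selects the format.
#' @param labels_path optional path for the JSON label sidecar.
#' @return `path`, invisibly.
#' @export
write_surface <- function(model, path, labels_path = NULL) {
  stopifnot(inherits(model, "surface_model"))
  p <- model$points
  ext <- tolower(tools::file_ext(path))
  fmt_row <- function(m) apply(m, 1L, function(r)
    paste(sprintf("%.9f", r), collapse = " "))
  if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(p)),
             "property double x", "property double y", "property double z",
             "end_header")
    writeLines(c(hdr, fmt_row(p)), path)
  } else if (ext == "obj") {
    writeLines(paste("v", fmt_row(p)), path)
  } else if (ext == "stl") {
    n <- nrow(p)
    tri <- character(0)
    for (i in seq_len(n)) {
      v <- sprintf("    vertex %s", paste(sprintf("%.9f", p[i, ]), collapse = " "))
      tri <- c(tri, "  facet normal 0 0 0", "    outer loop", v, v, v,
               "    endloop", "  endfacet")
    }
    writeLines(c("solid model", tri, "endsolid model"), path)
  } else abort_io(sprintf("unsupported output format \".%s\"", ext))
  if (!is.null(labels_path)) {
    # sidecar indices refer to the file's vertex stream; ascii STL repeats
    # each point three times (one degenerate facet per point)
    mult <- if (ext == "stl") 3L else 1L
    lab0 <- lapply(model$labels, function(ix) as.integer((ix - 1L) * mult))
    jsonlite::write_json(lab0, labels_path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Result records

#' Per-hip result record
#'
#' Bundles the femoral head fit, the acetabular fit, the congruity indices,
#' the parameters used and any warnings for one hip, for serialization.
#'
#' @param id character identifier for the hip.
#' @param side `"left"` or `"right"`.
#' @param head_fit,acet_fit [sphere_fit] objects.
#' @param indices a [congruity_indices()] object.
#' @param params list of run parameters (search spec, band, thresholds...).
#' @param warnings character vector.
#' @param excluded logical: head flagged aspherical, so the hip would be
#'   excluded from a cohort evaluation.
#' @return An object of class `hip_result_record`.
#' @export
result_record <- function(id, side, head_fit, acet_fit, indices,
                          params = list(), warnings = character(0),
                          excluded = FALSE) {
  structure(list(id = as.character(id), side = check_side(side),
                 head_fit = head_fit, acet_fit = acet_fit,
                 indices = indices, params = params,
                 warnings = as.character(warnings),
                 excluded = isTRUE(excluded)),
            class = "hip_result_record")
}

record_to_list <- function(rec) {
  fit_l <- function(f) list(center = f$center, radius = f$radius, sd = f$sd,
                            n_points = f$n_points, rounds = f$rounds,
                            converged = f$converged, aspherical = f$aspherical)
  ind <- rec$indices
  list(id = rec$id, side = rec$side,
       head_fit = fit_l(rec$head_fit), acet_fit = fit_l(rec$acet_fit),
       indices = list(mismatch_ratio = ind$mismatch_ratio,
                      cd_distance = ind$cd_distance,
                      cd_unit = if (is.null(ind$cd_unit)) NULL else
                        as.numeric(ind$cd_unit)),
       params = rec$params, warnings = rec$warnings, excluded = rec$excluded)
}

#' Write a result record to JSON
#'
#' The record round-trips losslessly (full double precision) through
#' [read_results()]. Lengths are mm, the mismatch ratio dimensionless, the
#' direction unit vector in (mediolateral, posteroanterior, superoinferior)
#' components.
#'
#' @param record a [result_record()].
#' @param path output path (JSON).
#' @return `path`, invisibly.
#' @export
write_results <- function(record, path) {
  stopifnot(inherits(record, "hip_result_record"))
  ok <- try(jsonlite::write_json(record_to_list(record), path,
                                 auto_unbox = TRUE, digits = NA,
                                 null = "null"), silent = TRUE)
  if (inherits(ok, "try-error")) abort_io(sprintf("cannot write %s", path))
  invisible(path)
}

#' Read a result record back from JSON
#'
#' @param path JSON file written by [write_results()].
#' @return a [result_record()].
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit_f <- function(f) structure(
    list(center = as.numeric(f$center), radius = f$radius, sd = f$sd,
         n_points = as.integer(f$n_points), rounds = as.integer(f$rounds),
         converged = isTRUE(f$converged), aspherical = isTRUE(f$aspherical)),
    class = "sphere_fit")
  ind <- structure(list(mismatch_ratio = x$indices$mismatch_ratio,
                        cd_distance = x$indices$cd_distance,
                        cd_unit = if (is.null(x$indices$cd_unit)) NULL else
                          as.numeric(x$indices$cd_unit),
                        side = x$side),
                   class = "congruity_indices")
  result_record(x$id, x$side, fit_f(x$head_fit), fit_f(x$acet_fit), ind,
                params = as.list(x$params), warnings = x$warnings,
                excluded = isTRUE(x$excluded))
}

#' Flatten result records into a cohort table
#'
#' One row per hip with stable column names: `id, side, group, rf, ra, head_sd,
#' acet_sd, ratio, cd_distance, cd_ml, cd_pa, cd_si, aspherical, excluded`.
#' Radii and distances in mm; `cd_*` are the unit-vector components
#' (NA when the centers coincide).
#'
#' @param records list of [result_record()]s.
#' @param group optional character vector of group names (recycled).
#' @return a data.frame.
#' @export
cohort_table <- function(records, group = NA_character_) {
  if (inherits(records, "hip_result_record")) records <- list(records)
  group <- rep_len(group, length(records))
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    u <- r$indices$cd_unit %||% c(NA_real_, NA_real_, NA_real_)
    data.frame(id = r$id, side = r$side, group = group[i],
               rf = r$head_fit$radius, ra = r$acet_fit$radius,
               head_sd = r$head_fit$sd, acet_sd = r$acet_fit$sd,
               ratio = r$indices$mismatch_ratio,
               cd_distance = r$indices$cd_distance,
               cd_ml = u[1], cd_pa = u[2], cd_si = u[3],
               aspherical = r$head_fit$aspherical, excluded = r$excluded,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a cohort CSV
#'
#' @param records list of [result_record()]s.
#' @param path output CSV path.
#' @param group optional group names, see [cohort_table()].
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path, group = NA_character_) {
  utils::write.csv(cohort_table(records, group), path, row.names = FALSE)
  invisible(path)
}
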