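#' Read a contour point cloud
#'
#' Reads a 3D point cloud (mm) from a CSV file with an `x,y,z` header or
#' from an ASCII PLY file with at least `x`, `y`, `z` vertex properties.
#' The format is chosen by extension.
#'
#' @param path File path (`.csv` or `.ply`).
#' @return A tibble with columns `x`, `y`, `z` (mm).
#' @export
read_point_cloud <- function(path) {
  if (!file.exists(path)) abort_contract(sprintf("File not found: %s", path))
  if (file.size(path) == 0) {
    rlang::abort(sprintf("Empty input file: %s", path),
                 class = "contourfit_error_empty_input")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") return(read_ply_vertices(path))
  tb <- suppressWarnings(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE)
  )
  probs <- readr::problems(tb)
  if (nrow(probs) > 0) {
    rlang::abort(
      sprintf("Malformed point-cloud row at line %d of %s: %s",
              probs$row[1] + 1, path, probs$expected[1]),
      class = "contourfit_error_parse"
    )
  }
  if (nrow(tb) == 0) {
    rlang::abort(sprintf("No points in: %s", path),
                 class = "contourfit_error_empty_input")
  }
  xyz_tibble(as_xyz_matrix(tb, arg = path))
}

#' Write a contour point cloud
#'
#' Writes points (mm) either as CSV with an `x,y,z` header at full precision
#' or as ASCII PLY (double-precision vertex properties), chosen by the
#' extension of `path`. Both round-trip losslessly through
#' [read_point_cloud()].
#'
#' @param points Data frame/matrix with `x`, `y`, `z` (mm).
#' @param path Destination path (`.csv` or `.ply`).
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(points, path) {
  m <- as_xyz_matrix(points)
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    header <- c(
      "ply", "format ascii 1.0", "comment units mm",
      sprintf("element vertex %d", nrow(m)),
      "property double x", "property double y", "property double z",
      "end_header"
    )
    body <- apply(m, 1, function(p) paste(format(p, digits = 17), collapse = " "))
    writeLines(c(header, body), path)
  } else {
    readr::write_csv(xyz_tibble(m), path)
  }
  invisible(path)
}

# Minimal ASCII-PLY vertex reader: header parsed for the vertex element and
# its property order; only x/y/z are kept.
read_ply_vertices <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ply") {
    rlang::abort(sprintf("Not a PLY file: %s", path),
                 class = "contourfit_error_parse")
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) {
    rlang::abort(sprintf("PLY header not terminated in: %s", path),
                 class = "contourfit_error_parse")
  }
  header <- trimws(lines[seq_len(end)])
  fmt <- grep("^format ", header, value = TRUE)
  if (length(fmt) == 0 || !grepl("ascii", fmt[1])) {
    rlang::abort("Only ASCII PLY is supported.", class = "contourfit_error_parse")
  }
  elements <- grep("^element ", header)
  vertex_line <- grep("^element vertex ", header)
  if (length(vertex_line) == 0) {
    rlang::abort(sprintf("PLY file has no vertex element: %s", path),
                 class = "contourfit_error_parse")
  }
  n_vertex <- as.integer(sub("^element vertex ", "", header[vertex_line[1]]))
  if (n_vertex == 0) {
    rlang::abort(sprintf("No points in: %s", path),
                 class = "contourfit_error_empty_input")
  }
  next_el <- elements[elements > vertex_line[1]]
  prop_end <- if (length(next_el) > 0) next_el[1] - 1 else end - 1
  props <- header[(vertex_line[1] + 1):prop_end]
  props <- props[grepl("^property ", props)]
  prop_names <- vapply(strsplit(props, "\\s+"), function(p) p[length(p)], "")
  idx <- match(c("x", "y", "z"), prop_names)
  if (anyNA(idx)) {
    rlang::abort("PLY vertex element lacks x/y/z properties.",
                 class = "contourfit_error_parse")
  }
  # vertex data follows the header; earlier elements are unsupported
  data_lines <- lines[(end + 1):(end + n_vertex)]
  vals <- strsplit(trimws(data_lines), "\\s+")
  bad <- which(vapply(vals, length, 0L) < max(idx))
  if (length(bad) > 0) {
    rlang::abort(sprintf("Malformed PLY vertex at line %d of %s.",
                         end + bad[1], path),
                 class = "contourfit_error_parse")
  }
  m <- t(vapply(vals, function(v) as.numeric(v[idx]), numeric(3)))
  if (anyNA(m)) {
    rlang::abort(sprintf("Non-numeric PLY vertex data in: %s", path),
                 class = "contourfit_error_parse")
  }
  colnames(m) <- c("x", "y", "z")
  xyz_tibble(m)
}

#' Read anatomical landmarks
#'
#' Reads a landmark file — JSON (object mapping landmark ID to an `[x, y, z]`
#' triple, mm) or CSV (`id, x, y, z` columns, mm) — and validates the IDs
#' against [landmark_vocabulary()].
#'
#' @param path File path (`.json` or `.csv`).
#' @param laterality `"left"` or `"right"`.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  if (!file.exists(path)) abort_contract(sprintf("File not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    lst <- jsonlite::read_json(path, simplifyVector = TRUE)
    landmark_set(lapply(lst, as.numeric), laterality)
  } else {
    tb <- readr::read_csv(path, col_types = readr::cols(
      id = readr::col_character(), .default = readr::col_double()
    ), progress = FALSE)
    landmark_set(tb, laterality)
  }
}

#' Write anatomical landmarks as JSON
#'
#' @param landmarks A [landmark_set()] (or compatible data frame).
#' @param path Destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  lst <- stats::setNames(
    lapply(seq_len(nrow(landmarks)),
           function(i) c(landmarks$x[i], landmarks$y[i], landmarks$z[i])),
    landmarks$id
  )
  jsonlite::write_json(lst, path, digits = NA)
  invisible(path)
}

#' Read a long-format measurement table
#'
#' Reads and validates the long measurement table consumed by
#' [reliability_report()]: one row per cartilage x operator x digitalisation
#' x parameter.
#'
#' @param path CSV path with columns `cartilage_id`, `side`,
#'   `cartilage_type`, `operator_id`, `digitalisation`, `parameter`,
#'   `value`, `unit`.
#' @return A tibble.
#' @export
read_measurement_table <- function(path) {
  tb <- readr::read_csv(path, col_types = readr::cols(
    cartilage_id = readr::col_character(), side = readr::col_character(),
    cartilage_type = readr::col_character(),
    operator_id = readr::col_character(),
    digitalisation = readr::col_integer(),
    parameter = readr::col_character(), value = readr::col_double(),
    unit = readr::col_character()
  ), progress = FALSE)
  probs <- readr::problems(tb)
  if (nrow(probs) > 0) {
    rlang::abort(sprintf("Malformed measurement table at line %d of %s.",
                         probs$row[1] + 1, path),
                 class = "contourfit_error_parse")
  }
  units_by_param <- dplyr::distinct(tb, .data$parameter, .data$unit)
  if (anyDuplicated(units_by_param$parameter)) {
    abort_contract("Inconsistent units within a parameter.")
  }
  tb
}

#' Write a measurement table
#'
#' @param table Long measurement table.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' Write a reliability report
#'
#' Writes the [reliability_report()] tibble as a CSV mirroring the layout of
#' published reliability tables — parameter, unit, mean, SD, 95% CI of the
#' mean, then ICC and SEM (%SEM) per observer condition — with the
#' qualitative classifications as separate columns rather than typography.
#' Millimetre/degree quantities are rounded to 1 decimal and ICCs to 2.
#' A machine-readable JSON twin (full precision) is written alongside when
#' `json_path` is given.
#'
#' @param report A [reliability_report()] tibble.
#' @param path Destination CSV path.
#' @param json_path Optional JSON path.
#' @return `path`, invisibly.
#' @export
write_reliability_report <- function(report, path, json_path = NULL) {
  out <- report |>
    dplyr::transmute(
      cartilage_type = .data$cartilage_type,
      parameter = .data$parameter, unit = .data$unit,
      mean = round(.data$mean, 1), sd = round(.data$sd, 1),
      ci95_lo = round(.data$ci_mean_lo, 1),
      ci95_hi = round(.data$ci_mean_hi, 1),
      icc_intra = round(.data$icc_intra, 2),
      sem_intra = round(.data$sem_intra, 1),
      sem_pct_intra = round(.data$sem_pct_intra, 1),
      icc_class_intra = .data$icc_class_intra,
      sem_class_intra = .data$sem_class_intra,
      icc_inter = round(.data$icc_inter, 2),
      sem_inter = round(.data$sem_inter, 1),
      sem_pct_inter = round(.data$sem_pct_inter, 1),
      icc_class_inter = .data$icc_class_inter,
      sem_class_inter = .data$sem_class_inter
    )
  readr::write_csv(out, path)
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read or write a stylus model as JSON
#'
#' The JSON layout holds `tip_offset` (mm), `probe_radius_mm` and a
#' `markers` object mapping each marker ID to its body-frame pose as
#' `origin` (mm) and unit quaternion `quaternion` (`[w, x, y, z]`).
#'
#' @param path JSON file path.
#' @return [read_stylus_model()] returns a [stylus_model()];
#'   [write_stylus_model()] returns `path` invisibly.
#' @export
read_stylus_model <- function(path) {
  if (!file.exists(path)) abort_contract(sprintf("File not found: %s", path))
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(js$markers) || is.null(js$tip_offset)) {
    rlang::abort("Stylus model JSON needs `markers` and `tip_offset`.",
                 class = "contourfit_error_parse")
  }
  markers <- lapply(js$markers, function(mk) {
    q <- as.numeric(mk$quaternion)
    rigid_frame(as.numeric(mk$origin), quat_to_rotation(q / sqrt(sum(q^2))))
  })
  stylus_model(markers, as.numeric(js$tip_offset),
               probe_radius_mm = js$probe_radius_mm %||% 1)
}

#' @rdname read_stylus_model
#' @param model A [stylus_model()].
#' @export
write_stylus_model <- function(model, path) {
  markers <- lapply(model$markers, function(f) {
    list(origin = f$origin, quaternion = rotation_to_quat(f$axes))
  })
  jsonlite::write_json(
    list(tip_offset = model$tip_offset,
         probe_radius_mm = model$probe_radius_mm, markers = markers),
    path, digits = NA, auto_unbox = FALSE
  )
  invisible(path)
}
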