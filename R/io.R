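#' Write a cine stack as 4D NIfTI
#'
#' Frames are stored as an (x, y, 1, t) volume; the in-plane pixel size and
#' the frame interval go into `pixdim`.
#'
#' @param stack A `cine_stack`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_cine_nifti <- function(stack, path) {
  stopifnot(inherits(stack, "cine_stack"))
  d <- dim(stack$data)
  img <- RNifti::asNifti(array(stack$data, dim = c(d[1], d[2], 1L, d[3])))
  img <- RNifti::`pixdim<-`(img, c(stack$pixel_mm, stack$pixel_mm, 8,
                                   stack$frame_dt_s))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a cine stack from 4D NIfTI
#'
#' @param path NIfTI file with dimensions (x, y, slices, t); only the first
#'   slice is used.
#' @return A `cine_stack`.
#' @export
read_cine_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4) abort("Expected a 4D (x, y, slice, time) NIfTI volume.")
  pd <- RNifti::pixdim(img)
  new_cine_stack(array(img[, , 1, ], dim = d[c(1, 2, 4)]),
                 pixel_mm = pd[1], frame_dt_s = pd[4],
                 meta = list(source = path))
}

#' Write / read pressure traces as CSV with a JSON sidecar
#'
#' The CSV holds `time_s` and one `port_XX` column per channel; sampling
#' rate, port metadata and event markers go into `<path>.json`.
#'
#' @param trace A `pressure_traces` object.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_pressure_csv <- function(trace, path) {
  stopifnot(inherits(trace, "pressure_traces"))
  utils::write.csv(trace$data, path, row.names = FALSE)
  side <- list(fs_hz = trace$fs_hz, ports = trace$ports,
               events = as.list(trace$events))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pressure_csv
#' @export
read_pressure_csv <- function(path) {
  tb <- as_tibble(utils::read.csv(path, check.names = FALSE))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    new_pressure_traces(tb, fs_hz = side$fs_hz,
                        ports = as_tibble(side$ports),
                        events = unlist(side$events))
  } else {
    fs <- 1 / median(diff(tb$time_s))
    new_pressure_traces(tb, fs_hz = fs)
  }
}

#' Write / read a study table as CSV
#'
#' @param tbl Study table tibble.
#' @param path CSV path.
#' @return `path` (write) or a tibble (read).
#' @export
write_study_csv <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_study_csv
#' @export
read_study_csv <- function(path) as_tibble(utils::read.csv(path))

#' Serialise a run configuration to JSON and back
#'
#' Configuration objects round-trip unchanged (up to numeric printing), so a
#' run's provenance record is sufficient to reproduce it.
#'
#' @param cfg A config object or plain list of config objects.
#' @param path JSON path.
#' @return `path` (write) or a named list (read).
#' @export
write_config_json <- function(cfg, path) {
  jsonlite::write_json(serialize_config(cfg), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

serialize_config <- function(x) {
  if (is.list(x) && !is.null(attr(x, "class"))) {
    out <- lapply(unclass(x), serialize_config)
    out$`_class` <- class(x)[1]
    out
  } else if (is.list(x)) {
    lapply(x, serialize_config)
  } else if (is.matrix(x)) {
    list(`_matrix` = TRUE, data = as.vector(x), nrow = nrow(x))
  } else x
}

deserialize_config <- function(x) {
  if (is.list(x) && isTRUE(x$`_matrix`))
    return(matrix(unlist(x$data), nrow = x$nrow))
  if (is.list(x)) {
    cls <- x$`_class`
    x$`_class` <- NULL
    out <- lapply(x, deserialize_config)
    if (!is.null(cls)) class(out) <- cls
    return(out)
  }
  x
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  deserialize_config(jsonlite::read_json(path, simplifyVector = TRUE,
                                         simplifyDataFrame = FALSE,
                                         simplifyMatrix = FALSE))
}

#' Write a displacement series as CSV
#'
#' @param shifts A `displacement_series` tibble.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_displacement_csv <- function(shifts, path) {
  utils::write.csv(as.data.frame(shifts), path, row.names = FALSE)
  invisible(path)
}
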