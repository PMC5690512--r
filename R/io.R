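# Plain-text serialization: contours, key-value (YAML) configs for phantom
# specs and plan parameters, and the per-case directory layout used to ship
# reference libraries:
#
#   case_dir/
#     contours.txt        structure name, role, x,y vertex table (mm)
#     prescription.yaml   dose_gy, fractions, site
#     parameters.yaml     per-structure weight / objective dose / type
#     dvh.csv             per-structure DVH blocks (dvh dialect)
#     fluence.txt         one beamlet intensity per line (optional)
#     spec.yaml           phantom spec, so the influence matrix can be
#                         rebuilt deterministically (optional)

#' Write / read structure contours as plain text
#'
#' One block per structure: \code{structure: <name>}, \code{role: <role>},
#' the column header \code{x_mm,y_mm}, then the closed polygon's vertices,
#' with blocks separated by blank lines.
#'
#' @param ss a \code{structure_set} (write) or the grid to rasterize on
#'   (read).
#' @param path file path.
#' @return \code{read_contours} returns a \code{structure_set}.
#' @export
write_contours <- function(ss, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("grid_shape: %d,%d", ss$grid_shape[1], ss$grid_shape[2]),
               sprintf("voxel_size_mm: %.9g", ss$voxel_size_mm), ""), con)
  for (s in ss$structures) {
    writeLines(c(paste("structure:", s$name), paste("role:", s$role),
                 "x_mm,y_mm",
                 sprintf("%.9g,%.9g", s$contour[, 1], s$contour[, 2]),
                 ""), con)
  }
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  lines <- readLines(path)
  i <- 1L; n <- length(lines)
  grab <- function(key) {
    if (!startsWith(lines[i], paste0(key, ":")))
      stop("contour parse error at line ", i, ": expected '", key, ":'")
    val <- trimws(sub(paste0("^", key, ":\\s*"), "", lines[i]))
    i <<- i + 1L
    val
  }
  gs <- as.integer(strsplit(grab("grid_shape"), ",")[[1]])
  vox <- as.numeric(grab("voxel_size_mm"))
  sl <- list()
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nm <- grab("structure")
    role <- grab("role")
    if (trimws(lines[i]) != "x_mm,y_mm")
      stop("contour parse error at line ", i, ": expected 'x_mm,y_mm'")
    i <- i + 1L
    j <- i
    while (j <= n && nzchar(trimws(lines[j]))) j <- j + 1L
    xy <- utils::read.csv(text = lines[i:(j - 1L)], header = FALSE,
                          col.names = c("x", "y"))
    sl[[length(sl) + 1L]] <- make_structure(nm, role, as.matrix(xy), gs, vox)
    i <- j
  }
  structure_set(gs, vox, sl)
}

#' Write / read plan parameters in the key-value config dialect
#' @param params a \code{plan_params}.
#' @param path file path.
#' @return \code{read_plan_params} returns a \code{plan_params}.
#' @export
write_plan_params <- function(params, path) {
  yaml::write_yaml(lapply(seq_len(nrow(params)), function(k)
    list(structure = params$structure[k], weight = params$weight[k],
         objective_dose_gy = params$objective_dose_gy[k],
         objective_type = params$objective_type[k])), path)
  invisible(path)
}

#' @rdname write_plan_params
#' @export
read_plan_params <- function(path) {
  pl <- yaml::read_yaml(path)
  plan_params(structure = vapply(pl, `[[`, "", "structure"),
              weight = vapply(pl, `[[`, 0, "weight"),
              objective_dose_gy = vapply(pl, `[[`, 0, "objective_dose_gy"),
              objective_type = vapply(pl, `[[`, "", "objective_type"))
}

#' Write / read a phantom spec in the key-value config dialect
#' @param spec a \code{phantom_spec}.
#' @param path file path.
#' @return \code{read_phantom_spec} returns a \code{phantom_spec}.
#' @export
write_phantom_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(phantom_spec, v)
}

#' Serialize / load a reference case directory
#'
#' @param rc a \code{reference_case}.
#' @param dir case directory (created if missing).
#' @param spec optional \code{phantom_spec} stored alongside so the
#'   influence matrix can be regenerated.
#' @return \code{read_case_dir} returns a \code{reference_case}.
#' @export
write_case_dir <- function(rc, dir, spec = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_contours(rc$structures, file.path(dir, "contours.txt"))
  pres <- rc$prescription
  pres$id <- rc$id
  pres$site <- rc$site
  yaml::write_yaml(pres, file.path(dir, "prescription.yaml"))
  write_plan_params(rc$params, file.path(dir, "parameters.yaml"))
  write_dvh_file(rc$dvh, file.path(dir, "dvh.csv"))
  if (!is.null(rc$fluence))
    writeLines(sprintf("%.12g", rc$fluence), file.path(dir, "fluence.txt"))
  if (!is.null(spec)) write_phantom_spec(spec, file.path(dir, "spec.yaml"))
  invisible(dir)
}

#' @rdname write_case_dir
#' @export
read_case_dir <- function(dir) {
  ss <- read_contours(file.path(dir, "contours.txt"))
  pres <- yaml::read_yaml(file.path(dir, "prescription.yaml"))
  params <- read_plan_params(file.path(dir, "parameters.yaml"))
  dvh <- read_dvh_file(file.path(dir, "dvh.csv"))
  flp <- file.path(dir, "fluence.txt")
  fl <- if (file.exists(flp)) as.numeric(readLines(flp)) else NULL
  reference_case(id = pres$id %||% basename(dir),
                 site = pres$site %||% "unknown",
                 structures = ss,
                 prescription = list(dose_gy = pres$dose_gy,
                                     fractions = pres$fractions),
                 params = params, dvh = dvh, fluence = fl)
}

#' Write / read a reference library as one subdirectory per case
#' @param library list of \code{reference_case}s.
#' @param dir library directory.
#' @return \code{read_library_dir} returns a list of
#'   \code{reference_case}s.
#' @export
write_library_dir <- function(library, dir) {
  for (rc in library) write_case_dir(rc, file.path(dir, rc$id))
  invisible(dir)
}

#' @rdname write_library_dir
#' @export
read_library_dir <- function(dir) {
  sub <- list.dirs(dir, recursive = FALSE)
  if (!length(sub)) stop("no case subdirectories in ", dir)
  lapply(sub, read_case_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
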