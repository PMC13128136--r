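# Snapshot and trajectory I/O: gzipped text arrays + JSON sidecar, CSV.

fmt_matrix_lines <- function(m) {
  apply(m, 1, function(row) paste(sprintf("%.17g", row), collapse = ","))
}

write_gz_matrix <- function(m, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(fmt_matrix_lines(m), con)
}

read_gz_matrix <- function(path) {
  lines <- readLines(gzfile(path))
  do.call(rbind, lapply(strsplit(lines, ","), as.numeric))
}

#' Write a field snapshot
#'
#' One gzipped CSV array per field (`phi0` plus each dynamic cell, row-major
#' in the x index) with full double precision, and a `meta.json` sidecar
#' carrying grid metadata (M, h, extent), time stamp, cell names/types and a
#' parameter hash. Round-trips bit-identically through [read_snapshot()].
#'
#' @param state a [pf_state()].
#' @param dir output directory (created if needed).
#' @param cell_names optional names (default `cell_1..N`).
#' @return invisibly, the vector of files written.
#' @export
write_snapshot <- function(state, dir, cell_names = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  N <- dim(state$phi)[3]
  if (is.null(cell_names)) cell_names <- paste0("cell_", seq_len(N))
  files <- file.path(dir, c("phi0.csv.gz", paste0(cell_names, ".csv.gz")))
  write_gz_matrix(state$phi0, files[1])
  for (m in seq_len(N)) write_gz_matrix(state$phi[, , m], files[m + 1])
  meta <- list(
    nx = state$grid$nx, ny = state$grid$ny, h = state$grid$h,
    extent = state$grid$extent, time = state$time,
    index_order = "rows = x index (anterior to posterior), columns = y index",
    cells = data.frame(name = cell_names,
                       type = vapply(state$params, `[[`, "", "type"),
                       Vbar = vapply(state$params, `[[`, 0, "Vbar")),
    param_hash = config_hash(list(
      tables = unclass(state$tables),
      params = lapply(state$params, unclass))))
  meta_path <- file.path(dir, "meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(c(files, meta_path))
}

#' Read a field snapshot written by [write_snapshot()]
#'
#' @param dir snapshot directory.
#' @param tables [interaction_tables()] to attach (not serialized in full).
#' @return a [pf_state()].
#' @export
read_snapshot <- function(dir, tables = interaction_tables()) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  meta$cells <- as.data.frame(meta$cells)
  grid <- build_grid(meta$nx, meta$ny, meta$extent)
  phi0 <- read_gz_matrix(file.path(dir, "phi0.csv.gz"))
  fields <- lapply(meta$cells$name, function(nm)
    read_gz_matrix(file.path(dir, paste0(nm, ".csv.gz"))))
  params <- lapply(seq_len(nrow(meta$cells)), function(i)
    cell_params(meta$cells$type[i], Vbar = meta$cells$Vbar[i]))
  pf_state(grid, phi0, fields, params, tables, time = meta$time)
}

#' Write a trajectory as CSV
#'
#' RFC-4180 CSV ('.' decimal separator), full double precision, columns per
#' the analysis schema. Identical runs reproduce identical bytes.
#'
#' @param traj trajectory data.frame.
#' @param path output file.
#' @export
write_trajectory <- function(traj, path) {
  num <- vapply(traj, is.numeric, TRUE)
  out <- traj
  out[num] <- lapply(traj[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#' @param path file written by [write_trajectory()].
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path)
}
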