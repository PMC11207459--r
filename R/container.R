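## Single-file run container. Groups mirror the sensor streams:
##   /kspace (lines, ktraj, timestamps, channel), /amode, /tof, /iq,
##   /truth (trajectories, masks). Stored as native R serialization with
## a schema header; write-then-read is exact for all arrays.

container_schema <- list(
  kspace = c("lines", "timestamps"),
  amode = c("rf", "fs_hz"),
  tof = c("frames", "validity", "timestamps"),
  iq = c("samples", "fs_hz"),
  truth = character(0)
)

#' Write a run container
#'
#' Persists named groups (`kspace`, `amode`, `tof`, `iq`, `truth`) to a
#' single file. Unknown groups are stored untouched; known groups are
#' checked for their required datasets first.
#'
#' @param path output file (conventionally `.rds`).
#' @param groups named list of groups.
#' @return `path`, invisibly.
#' @export
write_container <- function(path, groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  for (g in intersect(names(groups), names(container_schema))) {
    need <- setdiff(container_schema[[g]], names(groups[[g]]))
    if (length(need))
      stop(sprintf("group '%s' is missing dataset(s): %s", g,
                   paste(need, collapse = ", ")), call. = FALSE)
  }
  obj <- list(format = "mrmotion-run", version = 1L, groups = groups)
  saveRDS(obj, path)
  invisible(path)
}

#' Read a run container
#'
#' @param path file written by [write_container()].
#' @param require character vector of group names that must be present;
#'   a schema error naming the missing path is raised otherwise.
#' @return named list of groups. Unknown groups are kept with a warning.
#' @export
read_container <- function(path, require = NULL) {
  if (!file.exists(path)) stop("no such container: ", path, call. = FALSE)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("schema error: not a readable run container: ", path, call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, "mrmotion-run"))
    stop("schema error: missing /format header in ", path, call. = FALSE)
  groups <- obj$groups
  unknown <- setdiff(names(groups), names(container_schema))
  if (length(unknown))
    warning("ignoring unknown group(s): ", paste(unknown, collapse = ", "))
  for (g in intersect(names(groups), names(container_schema))) {
    need <- setdiff(container_schema[[g]], names(groups[[g]]))
    if (length(need))
      stop(sprintf("schema error: /%s/%s missing in %s", g, need[1], path),
           call. = FALSE)
  }
  if (!is.null(require)) {
    miss <- setdiff(require, names(groups))
    if (length(miss))
      stop("schema error: container lacks group(s): ",
           paste(paste0("/", miss), collapse = ", "), call. = FALSE)
  }
  groups
}
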