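#' Write a simulation ground-truth manifest as JSON
#'
#' @param manifest the `manifest` element of [simulate_recording()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  m <- manifest
  m$design <- unclass(m$design)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Read an ROI configuration from YAML
#'
#' The file maps cluster names to channel-label lists, e.g.
#' `left: [PO3, PO7, P7, PO9]`.
#'
#' @param path YAML file.
#' @return a `roi_set`-classed named list.
#' @export
read_roi_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!length(cfg)) stop("empty ROI configuration")
  cfg <- lapply(cfg, function(v) normalize_channel_labels(as.character(v)))
  structure(cfg, class = "roi_set")
}

#' Write an ROI configuration to YAML
#' @param rois a [roi_set()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_roi_config <- function(rois, path) {
  yaml::write_yaml(lapply(unclass(rois), as.list), path)
  invisible(path)
}
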