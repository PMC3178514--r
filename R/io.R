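#' Write a component set as delimited text
#'
#' Writes `<stem>_maps.tsv` (components x locations) and
#' `<stem>_courses.tsv` (components x time points), plus a JSON sidecar with
#' modality and provenance. Output is bit-stable for a fixed input.
#'
#' @param set a `component_set`.
#' @param stem output path stem.
#' @return The sidecar path, invisibly.
#' @export
write_component_set <- function(set, stem) {
  utils::write.table(set$spatial_maps, paste0(stem, "_maps.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(set$time_courses, paste0(stem, "_courses.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  side <- paste0(stem, ".json")
  jsonlite::write_json(list(modality = set$modality,
                            n_components = nrow(set$spatial_maps),
                            provenance = set$provenance),
                       side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(side)
}

#' Write a causal graph as delimited text
#'
#' One row per ordered pair: from, to, magnitude, F statistic, p-value,
#' significance.
#'
#' @param graph a [gc_edges()] result.
#' @param path output file.
#' @export
write_gc_graph <- function(graph, path) {
  utils::write.table(as.data.frame(tidy(graph)), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a lead field with its geometry sidecar
#'
#' @param leadfield a [compute_leadfield()] result.
#' @param stem output path stem (`<stem>.tsv` + `<stem>.json`).
#' @export
write_leadfield <- function(leadfield, stem) {
  utils::write.table(leadfield$gain, paste0(stem, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(reference = leadfield$reference,
                            sphere_radii = leadfield$sphere_radii,
                            conductivities = leadfield$conductivities,
                            orientation = leadfield$orientation,
                            order = leadfield$order),
                       paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(stem)
}

#' Summarize an analysis or evaluation result as JSON
#'
#' @param x an `mfnc_result` or `mfnc_eval`.
#' @param path output file.
#' @export
write_json_summary <- function(x, path) {
  obj <- if (inherits(x, "mfnc_result")) {
    list(n_eeg_components = nrow(x$eeg_components$spatial_maps),
         n_fmri_components = nrow(x$fmri_components$spatial_maps),
         eeg_order = as.integer(x$eeg_order),
         fmri_order = as.integer(x$fmri_order),
         eeg_edges = as.data.frame(tidy(x$eeg_graph)),
         fmri_edges = as.data.frame(tidy(x$fmri_graph)),
         match = x$match$match,
         eeg_specific = x$match$eeg_specific,
         fmri_specific = x$match$fmri_specific)
  } else if (inherits(x, "mfnc_eval")) {
    list(seed = x$seed, cells = as.data.frame(x$cells))
  } else stop("unsupported object")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
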