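#' Export a feature map as CSV
#'
#' One row per surface point: point id, side, ventricular coordinates, the
#' six EAM features and the activation time.
#'
#' @param fmap a `feature_map`
#' @param surface the matching `eam_surface`
#' @param path output path
#' @return invisibly, the path
#' @export
export_feature_csv <- function(fmap, surface, path) {
  df <- cbind(fmap[, c("point", "side")],
              as.data.frame(surface$uvc),
              fmap[, c(eam_feature_names(), "activation")])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export one point's unipolar signal as CSV
#'
#' @param egm_map an `electrogram_map`
#' @param point surface point index
#' @param path output path
#' @return invisibly, the path
#' @export
export_signal_csv <- function(egm_map, point, path) {
  write.csv(data.frame(time_ms = egm_map$times,
                       potential_mV = egm_map$signals[point, ]),
            path, row.names = FALSE)
  invisible(path)
}

#' Export a model's nodes and labels as VTK
#'
#' Writes the voxel nodes as a VTK point cloud with tissue labels (0
#' normal, 1 border zone, 2 dense core) and, when present, ventricular
#' coordinates as point scalars.
#'
#' @param model a `ventricular_model`
#' @param path output path (.vtk)
#' @return invisibly, the path
#' @export
export_model_vtk <- function(model, path) {
  sc <- list(label = match(model$label, c("normal", "border_zone", "dense_core")) - 1)
  if (!is.null(model$uvc)) {
    sc$ab <- model$uvc[, "ab"]; sc$rot <- model$uvc[, "rot"]
    sc$tm <- model$uvc[, "tm"]
  }
  write_vtk(path, model$coords, scalars = sc)
}

#' Export a mapping surface (optionally with per-point scalars) as VTK
#'
#' @param surface an `eam_surface`
#' @param path output path (.vtk)
#' @param scalars named list of per-point numeric vectors
#' @return invisibly, the path
#' @export
export_surface_vtk <- function(surface, path, scalars = list()) {
  base <- list(side = as.numeric(surface$side == "epi"),
               lid = as.numeric(surface$lid))
  write_vtk(path, surface$points, surface$triangles, c(base, scalars))
}
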