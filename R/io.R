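# Readers and writers for the standard formats around the pipeline:
# NIfTI image panels and masks, CSV biomarker panels and reduced matrices,
# JSON cluster reports, and TSV/GraphML graph exports.

#' Read a panel of co-registered NIfTI images under a common mask
#'
#' @param paths Character vector of NIfTI file paths (one per subject).
#' @param mask NIfTI path or binary 3D array; every image must match its grid.
#' @return \code{image_panel}.
#' @export
read_image_panel <- function(paths, mask) {
  if (is.character(mask)) mask <- as.array(RNifti::readNifti(mask))
  mask <- (mask != 0)
  idx <- which(mask)
  data <- matrix(NA_real_, length(paths), length(idx))
  for (i in seq_along(paths)) {
    img <- as.array(RNifti::readNifti(paths[i]))
    if (!identical(dim(img), dim(mask)))
      stop_netpls(paste0("image grid mismatch in '", paths[i], "'"),
                  "netpls_grid_mismatch")
    data[i, ] <- img[idx]
  }
  image_panel(data, mask)
}

#' Write a brain map as NIfTI aligned to a panel's mask
#'
#' @param map \code{brain_map}.
#' @param panel \code{image_panel} supplying the grid and voxel order.
#' @param path Output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
write_brain_map <- function(map, panel, path) {
  arr <- array(0, dim = dim(panel$mask))
  arr[panel$linear_index] <- map$values
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Read a biomarker panel from CSV
#'
#' Expects a header row and a subject-ID column (first column by default);
#' remaining columns must be numeric, with empty cells / NA as missing.
#'
#' @param path CSV path.
#' @param id_column Name or index of the subject-ID column (default 1).
#' @return \code{biomarker_panel} with subject IDs as row names.
#' @export
read_biomarker_csv <- function(path, id_column = 1L) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(df[[id_column]])
  if (anyDuplicated(ids))
    stop_netpls(paste0("duplicated subject ID(s): ",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                "netpls_invalid_input")
  df <- df[, setdiff(seq_along(df), if (is.numeric(id_column))
    id_column else match(id_column, names(df))), drop = FALSE]
  bad <- names(df)[!vapply(df, is.numeric, logical(1L))]
  if (length(bad))
    stop_netpls(paste0("non-numeric column(s): ", paste(bad, collapse = ", ")),
                "netpls_invalid_input")
  values <- as.matrix(df)
  rownames(values) <- ids
  biomarker_panel(values)
}

#' Write a biomarker panel (or reduced matrix) to CSV
#'
#' Round-trips bit-stably through \code{\link{read_biomarker_csv}} for
#' values written with full precision.
#'
#' @param x \code{biomarker_panel}, \code{reduced_biomarker_matrix}, or matrix.
#' @param path Output CSV path.
#' @param ids Subject IDs (default: row names or 1..n).
#' @return The path, invisibly.
#' @export
write_biomarker_csv <- function(x, path, ids = NULL) {
  values <- if (inherits(x, "biomarker_panel")) x$values
            else if (inherits(x, "reduced_biomarker_matrix")) x$X
            else as.matrix(x)
  ids <- ids %||% rownames(values) %||% as.character(seq_len(nrow(values)))
  df <- data.frame(subject_id = ids, values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a dependency graph
#'
#' @param graph \code{dependency_graph}.
#' @param path Output path; format by extension (.tsv edge list or .graphml).
#' @return The path, invisibly.
#' @export
write_graph <- function(graph, path) {
  if (grepl("\\.graphml$", path)) {
    igraph::write_graph(graph$graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph$graph)
    df <- data.frame(from = el[, 1L], to = el[, 2L],
                     weight = igraph::E(graph$graph)$weight)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write a cluster report as JSON
#'
#' @param clusters \code{overlapping_cluster_set} with representatives.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_cluster_report <- function(clusters, path) {
  overlap <- table(unlist(lapply(clusters$clusters, unique)))
  jsonlite::write_json(
    list(n_clusters = length(clusters$clusters),
         p_representatives = clusters$p,
         clusters = lapply(seq_along(clusters$clusters), function(i)
           list(members = clusters$clusters[[i]],
                representative = clusters$representative[i])),
         overlapping_variables = names(overlap)[overlap > 1L]),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
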