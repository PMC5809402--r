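# End-to-end orchestration: image reduction, biomarker reduction, sparse
# PLS, component selection, and the recovery report, with a single seed
# fanned out to per-stage seeds and a config hash stamped on every artifact.

#' Pipeline configuration
#'
#' Defaults mirror the method's canonical settings: knot spacing 4 voxels,
#' k = 10 components, 5 cross-validation folds, forest-mode graph
#' estimation, X scores as the selection predictors.
#'
#' @param spacing_g0 Knot spacing (voxels).
#' @param graph_mode \code{"forest"} or \code{"threshold"}.
#' @param k Number of sPLS components.
#' @param nfolds Cross-validation folds.
#' @param seed Master seed.
#' @param tune Tune penalties by PRESS (default TRUE); otherwise use
#'   \code{lambda_x}/\code{lambda_y} as given.
#' @param lambda_x,lambda_y Penalties used when \code{tune = FALSE}.
#' @param score_source \code{"T"} (X scores, default) or \code{"U"}.
#' @param ridge Separation fallback for the logistic stage (0 = strict).
#' @param tune_alternations,tune_n_line Search budget for
#'   \code{\link{tune_penalties}}.
#' @param output_dir Optional directory; when set, artifacts are written
#'   (X.csv, Y.csv, clusters.json, graph.tsv, report.json).
#' @return \code{pipeline_config} (validated, with a provenance hash).
#' @export
pipeline_config <- function(spacing_g0 = 4, graph_mode = "forest", k = 10L,
                            nfolds = 5L, seed = 1L, tune = TRUE,
                            lambda_x = 0, lambda_y = 0, score_source = "T",
                            ridge = 1e-4, tune_alternations = 2L,
                            tune_n_line = 5L, output_dir = NULL) {
  if (!score_source %in% c("T", "U"))
    stop_netpls("score_source must be 'T' or 'U'", "netpls_invalid_config")
  if (spacing_g0 < 1) stop_netpls("spacing_g0 must be >= 1", "netpls_invalid_config")
  cfg <- list(spacing_g0 = spacing_g0, graph_mode = graph_mode, k = k,
              nfolds = nfolds, seed = seed, tune = tune,
              lambda_x = lambda_x, lambda_y = lambda_y,
              score_source = score_source, ridge = ridge,
              tune_alternations = tune_alternations,
              tune_n_line = tune_n_line, output_dir = output_dir)
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "output_dir")])
  structure(cfg, class = "pipeline_config")
}

#' Run the full network-based RBF-sPLS pipeline
#'
#' Steps, in order: (1a) impute missing biomarkers, estimate the dependency
#' graph, find overlapping clusters, pick representatives, assemble X;
#' (1b) place knots, build the radial basis, reduce the image panel to Y;
#' (2) tune the L1 penalties by PRESS (optional) and fit the k-component
#' sparse PLS; (3) select diagnosis-relevant components by backward
#' stepwise BIC logistic regression on the component scores and assemble
#' the component report. Every artifact carries the config hash and the
#' master seed.
#'
#' @param images \code{image_panel} (or \code{synthetic_dataset}, which
#'   supplies all three inputs).
#' @param biomarkers \code{biomarker_panel} (ignored when \code{images} is a
#'   dataset).
#' @param labels Binary diagnosis vector (ignored for a dataset).
#' @param config \code{pipeline_config}.
#' @return \code{pipeline_result}: \code{basis}, \code{Y}, \code{graph},
#'   \code{clusters}, \code{X}, \code{model}, \code{tuning} (or NULL),
#'   \code{selection}, \code{report}, \code{config}.
#' @export
run_pipeline <- function(images, biomarkers = NULL, labels = NULL,
                         config = pipeline_config()) {
  if (inherits(images, "synthetic_dataset")) {
    biomarkers <- images$biomarkers
    labels <- images$labels
    images <- images$images
  }
  if (is.null(biomarkers) || is.null(labels))
    stop_netpls("biomarkers and labels are required", "netpls_invalid_config")
  seed <- config$seed

  # stage 1a: biomarker reduction
  panel <- impute_missing(biomarkers, seed = derive_seed(seed, "impute"))
  graph <- estimate_dependency_graph(panel, mode = config$graph_mode)
  clusters <- suppressMessages(cluster_links(graph))
  if (length(clusters$clusters) == 0L)
    stop_netpls("biomarker graph produced no clusters", "netpls_stage_failure")
  clusters <- suppressMessages(select_representatives(clusters, graph, panel))
  Xr <- reduce_biomarkers(panel, clusters)

  # stage 1b: image reduction
  knots <- place_knots(images$mask, config$spacing_g0)
  basis <- suppressMessages(build_basis(images, knots))
  Yr <- reduce_images(images, basis)

  # stage 2: sparse PLS
  tuning <- NULL
  lambda_x <- config$lambda_x; lambda_y <- config$lambda_y
  if (config$tune) {
    tuning <- tune_penalties(Xr$X, Yr$Y, k = config$k, nfolds = config$nfolds,
                             seed = derive_seed(seed, "tune"), labels = labels,
                             n_line = config$tune_n_line,
                             max_alternations = config$tune_alternations)
    lambda_x <- tuning$chosen$lambda_x
    lambda_y <- tuning$chosen$lambda_y
  }
  model <- suppressWarnings(fit_spls(Xr$X, Yr$Y, k = config$k,
                                     lambda_x = lambda_x, lambda_y = lambda_y))

  # stage 3: component selection
  scores <- if (config$score_source == "T") model$T else model$U
  selection <- backward_stepwise_bic(scores, labels,
                                     score_source = config$score_source,
                                     ridge = config$ridge)
  report <- report_components(selection, model, basis, clusters)

  res <- structure(list(basis = basis, Y = Yr, graph = graph,
                        clusters = clusters, X = Xr, model = model,
                        tuning = tuning, selection = selection,
                        report = report, config = config),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) .write_pipeline_artifacts(res, images)
  res
}

.write_pipeline_artifacts <- function(res, images) {
  dir.create(res$config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(res$config$output_dir, f)
  write_biomarker_csv(res$X, out("X.csv"))
  write_biomarker_csv(res$Y$Y, out("Y.csv"))
  write_graph(res$graph, out("graph.tsv"))
  write_cluster_report(res$clusters, out("clusters.json"))
  sel <- res$selection
  jsonlite::write_json(
    list(config_hash = res$config$hash, seed = res$config$seed,
         penalties = res$model$penalties,
         selected_components = sel$selected_indices,
         bic_trace = sel$bic_trace,
         p_values = sel$p_values,
         n_nonzero_voxels = vapply(res$report$components, `[[`, numeric(1L),
                                   "n_nonzero_voxels"),
         note = res$report$note),
    out("report.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (i in seq_along(res$report$components)) {
    cc <- res$report$components[[i]]
    write_brain_map(cc$brain_map, images,
                    out(sprintf("component_%02d_map.nii.gz", cc$component)))
  }
  invisible(NULL)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("network-based RBF-sPLS pipeline result\n")
  cat("  config hash:", x$config$hash, " seed:", x$config$seed, "\n")
  cat("  basis: q =", ncol(x$basis$B), "knots; X: p =", ncol(x$X$X),
      "representatives from", length(x$clusters$clusters), "clusters\n")
  cat("  penalties: lambda_x =", signif(x$model$penalties$lambda_x, 4),
      " lambda_y =", signif(x$model$penalties$lambda_y, 4), "\n")
  cat("  selected components:",
      if (length(x$selection$selected_indices))
        paste(x$selection$selected_indices, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
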