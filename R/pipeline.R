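#' Run the full segmentation pipeline
#'
#' Executes the workflow stages in order — input (file or phantom),
#' pre-processing, binary segmentation, small-component cleanup, distance
#' transform, contour-tree segmentation, post-processing, morphometrics,
#' and evaluation against phantom truth — skipping stages the config
#' disables. Every intermediate volume, a stage-timing log, and a
#' manifest echoing the exact configuration (seeds included) are written
#' to the run directory, so the manifest alone reproduces a run
#' bit-exactly.
#'
#' The configuration is a named list (or path to a YAML/JSON file) with
#' entries:
#' \describe{
#'   \item{input}{`list(path=, spacing=)` — or instead:}
#'   \item{phantom}{`list(kind = "voronoi"|"hex"|"prisms", seed =, ...)`
#'     with the matching generator's arguments; optional
#'     `pore_rate`/`pore_seed` to corrupt the phantom mask. When a
#'     phantom is used, binarization applies to the phantom image unless
#'     `binarize$use_phantom_mask` is set, in which case the (possibly
#'     pore-corrupted) phantom mask is used directly.}
#'   \item{normalize}{`list(sigma =, epsilon =)`, omit to skip.}
#'   \item{binarize}{`list(threshold =, invert =)`.}
#'   \item{clean}{`list(min_voxels =, connectivity =)`, omit to skip.}
#'   \item{distance}{`list(method = "rwdt"|"edt"|"ensemble", connectivity =,
#'     border =, tolerance =, thresholds = / t_min/t_max/t_step,
#'     use_spacing =)`.}
#'   \item{segment}{`list(persistence =, connectivity =, normalize_first =)`.}
#'   \item{postprocess}{`list(merge_pairs = two-column matrix or CSV path,
#'     directed = list(axis =, angle =, overlap =, gap =))`, omit to skip.}
#'   \item{quantify}{`list(min_contact =)` or `FALSE`.}
#'   \item{prisms}{`list(axis =)`, omit to skip.}
#'   \item{evaluate}{`TRUE` to compare against phantom truth.}
#'   \item{output_dir}{run directory (created; default `tempfile()`).}
#' }
#'
#' @param config named list or path to a YAML/JSON config file.
#' @param output_dir overrides `config$output_dir`.
#' @return Invisibly, a list with the run directory, the label volume and
#'   the stage results.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out <- output_dir %||% config$output_dir %||% tempfile("tilewalk_run_")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  config$output_dir <- out
  logf <- file.path(out, "log.txt")
  cat(sprintf("tilewalk pipeline %s\n", format(Sys.time())), file = logf)
  results <- list(run_dir = out)
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    val <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    cat(sprintf("%-12s %8.2fs\n", name, proc.time()[3] - t0),
        file = logf, append = TRUE)
    val
  }

  truth <- NULL
  if (!is.null(config$phantom)) {
    ph <- config$phantom
    bundle <- stage("phantom", {
      kind <- ph$kind %||% "voronoi"
      args <- ph[setdiff(names(ph), c("kind", "pore_rate", "pore_seed"))]
      if (!is.null(args$shape)) args$shape <- as.numeric(args$shape)
      fn <- switch(kind, voronoi = voronoi_tiling_phantom,
                   hex = hexagonal_tiling_phantom,
                   prisms = columnar_prism_phantom,
                   stop("unknown phantom kind '", kind, "'"))
      do.call(fn, args)
    })
    if (!is.null(ph$pore_rate) && ph$pore_rate > 0) {
      bundle$mask <- inject_pore_noise(bundle$mask, ph$pore_rate,
                                       ph$pore_seed %||% (ph$seed %||% 1))
      bundle$image <- intensity_volume(
        render_image(bundle$mask$data, ph$noise_sigma %||% 0),
        bundle$mask$spacing)
    }
    truth <- bundle$truth
    volume <- bundle$image
    results$phantom <- bundle$params
    write_volume(volume, file.path(out, "image.nrrd"))
    write_labels(truth, file.path(out, "truth.tif"))
  } else if (!is.null(config$input)) {
    volume <- stage("read", read_volume(config$input$path,
                                        config$input$spacing %||% NULL))
  } else stop("config must name an input volume or a phantom spec", call. = FALSE)

  if (!is.null(config$normalize)) {
    volume <- stage("normalize", local_normalize(
      volume, config$normalize$sigma, config$normalize$epsilon %||% 1e-6))
    write_volume(volume, file.path(out, "normalized.nrrd"))
  }

  use_phantom_mask <- isTRUE(config$binarize$use_phantom_mask) && !is.null(config$phantom)
  mask <- if (use_phantom_mask) bundle$mask
          else stage("binarize", threshold_mask(
            volume, config$binarize$threshold %||% 125,
            isTRUE(config$binarize$invert)))
  if (!is.null(config$clean)) {
    mask <- stage("clean", remove_small_components(
      mask, config$clean$min_voxels %||% 1, config$clean$connectivity %||% 26))
  }
  write_volume(binary_mask(mask$data, mask$spacing), file.path(out, "mask.tif"))

  dcfg <- config$distance %||% list(method = "rwdt")
  spec <- walk_spec(dcfg$connectivity %||% 26, dcfg$border %||% "reflecting",
                    dcfg$tolerance %||% 1e-8)
  dmap <- stage("distance", switch(
    dcfg$method %||% "rwdt",
    rwdt = random_walk_distance(mask, spec),
    edt = euclidean_distance(mask, isTRUE(dcfg$use_spacing)),
    ensemble = {
      th <- dcfg$thresholds %||% seq(dcfg$t_min, dcfg$t_max, by = dcfg$t_step)
      ensemble_rwdt(volume, th, spec)
    },
    stop("unknown distance method '", dcfg$method, "'")))
  write_volume(intensity_volume(dmap$data, dmap$spacing),
               file.path(out, "distance.nrrd"))

  scfg <- config$segment %||% list()
  params <- segmentation_params(scfg$persistence %||% 0.15,
                                scfg$connectivity %||% 26,
                                scfg$normalize_first %||% TRUE)
  labels <- stage("segment", contour_tree_segment(dmap, params))

  if (!is.null(config$postprocess)) {
    pp <- config$postprocess
    if (!is.null(pp$merge_pairs)) {
      pairs <- pp$merge_pairs
      if (is.character(pairs)) pairs <- as.matrix(utils::read.csv(pairs))
      labels <- stage("merge", apply_merges(labels, pairs))
    }
    if (!is.null(pp$directed)) {
      dd <- pp$directed
      labels <- stage("merge-directed", directed_merge(
        labels, dd$axis %||% "z", dd$angle %||% 30, dd$overlap %||% 0.5,
        dd$gap %||% 3))
    }
  }
  write_labels(labels, file.path(out, "labels.tif"))
  results$labels <- labels

  if (!isFALSE(config$quantify)) {
    rag <- build_rag(labels, config$quantify$min_contact %||% 1)
    stats <- stage("quantify", tile_stats(labels, volume, rag))
    utils::write.csv(stats, file.path(out, "tile_stats.csv"), row.names = FALSE)
    utils::write.csv(rag$edges, file.path(out, "rag_edges.csv"), row.names = FALSE)
    results$stats <- stats
    results$rag <- rag
  }
  if (!is.null(config$prisms)) {
    pr <- stage("prisms", prism_profiles(labels, config$prisms$axis %||% "z"))
    utils::write.csv(pr$profiles, file.path(out, "prism_profiles.csv"),
                     row.names = FALSE)
    results$prisms <- pr
  }
  if (isTRUE(config$evaluate) && !is.null(truth)) {
    ev <- stage("evaluate", evaluate_segmentation(labels, truth))
    jsonlite::write_json(unclass(ev), file.path(out, "evaluation.json"),
                         auto_unbox = TRUE)
    results$evaluation <- ev
  }
  manifest <- config
  manifest$package_version <- as.character(utils::packageVersion("tilewalk"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(results)
}
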