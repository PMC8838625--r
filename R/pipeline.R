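#' Run the void-quantification pipeline
#'
#' Executes an ordered subset of the stages simulate -> segment -> extract
#' -> metrics on one configuration, writing each stage's outputs plus
#' sidecar metadata under `outdir` and returning a manifest of every
#' artifact with its MD5 checksum. Identical config and seed give
#' byte-identical manifests. A single global seed deterministically derives
#' per-stage substreams, so stages can be re-run in isolation on persisted
#' intermediates with the same result.
#'
#' @param config nested list (or path to a YAML file) with elements:
#'   `stages` (character subset of `c("simulate", "segment", "extract",
#'   "metrics")`), `seed`, `outdir`, per-stage blocks `phantom`
#'   (arguments for [phantom_spec()] plus `render` arguments for
#'   [render_grayscale()]), `segment` (`method`, `void_is`, `bandwidth`),
#'   `extract` (`merge_ratio`, `min_pore_radius_um`), and optionally
#'   `inputs` (paths to persisted intermediates from an earlier run:
#'   `grayscale` and/or `mask` as raw_headered volumes, `network` as a
#'   tsv-dialect table directory), so stages can be run in isolation.
#' @return Invisibly, a data frame manifest (`artifact`, `md5`); also
#'   written to `outdir/manifest.tsv`, with the fully resolved config
#'   persisted as `outdir/config_resolved.yaml`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(stages = c("simulate", "segment", "extract", "metrics"),
                   seed = 1L, outdir = "voidnet_run",
                   segment = list(method = "valley", void_is = "dark",
                                  bandwidth = 5),
                   extract = list(merge_ratio = 0.7,
                                  min_pore_radius_um = NULL))
  config <- utils::modifyList(defaults, config)
  stages <- match.arg(config$stages,
                      c("simulate", "segment", "extract", "metrics"),
                      several.ok = TRUE)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  # per-stage substreams derived from the one global seed
  stage_seed <- function(stage)
    (config$seed * 101L +
       match(stage, c("simulate", "segment", "extract", "metrics")) * 7919L) %%
      .Machine$integer.max
  artifacts <- character(0)
  log_line <- function(...) message(sprintf(...))

  truth <- NULL; gray <- NULL; mask <- NULL; net <- NULL
  if (!is.null(config$inputs$grayscale))
    gray <- read_volume(config$inputs$grayscale, format = "raw_headered")
  if (!is.null(config$inputs$mask)) {
    gv <- read_volume(config$inputs$mask, format = "raw_headered")
    mask <- binary_volume(array(gv$data >= 128, dim = gv$dims),
                          gv$voxel_size_um, provenance = gv$provenance)
  }
  if (!is.null(config$inputs$network))
    net <- read_network_tables(config$inputs$network, "tsv")
  for (stage in stages) {
    t0 <- Sys.time()
    res <- tryCatch(switch(stage,
      simulate = {
        ph <- config$phantom
        render_args <- ph$render
        ph$render <- NULL
        ph$seed <- stage_seed("simulate")
        spec <- do.call(phantom_spec, ph)
        truth <- gen_phantom(spec)
        write_volume(truth$binary, file.path(outdir, "truth_mask.raw"),
                     "raw_headered")
        .write_tsv(truth$feature_log, file.path(outdir, "truth_features.tsv"))
        artifacts <- c(artifacts, file.path(outdir, "truth_mask.raw"),
                        file.path(outdir, "truth_mask.raw.hdr"),
                        file.path(outdir, "truth_features.tsv"))
        if (!is.null(render_args)) {
          render_args$truth <- truth
          render_args$seed <- stage_seed("simulate")
          gray <- do.call(render_grayscale, render_args)
          write_volume(gray, file.path(outdir, "grayscale.raw"),
                       "raw_headered")
          artifacts <- c(artifacts, file.path(outdir, "grayscale.raw"),
                          file.path(outdir, "grayscale.raw.hdr"))
        }
        TRUE
      },
      segment = {
        if (is.null(gray)) {
          if (!is.null(truth)) mask <- truth$binary # truth passes through
          if (is.null(mask)) stop("segment stage has no grayscale input")
        } else {
          seg <- if (config$segment$method == "consensus")
            consensus_threshold(gray, config$segment$bandwidth,
                                config$segment$void_is)
          else histogram_valley_threshold(gray, config$segment$bandwidth,
                                          config$segment$void_is)
          mask <- seg$binary
          writeLines(yaml::as.yaml(list(threshold = seg$threshold,
                                        method = seg$method,
                                        peaks = seg$diagnostics$peaks)),
                     file.path(outdir, "segmentation.yaml"))
          artifacts <- c(artifacts, file.path(outdir, "segmentation.yaml"))
        }
        write_volume(mask, file.path(outdir, "mask.raw"), "raw_headered")
        artifacts <- c(artifacts, file.path(outdir, "mask.raw"),
                        file.path(outdir, "mask.raw.hdr"))
        TRUE
      },
      extract = {
        if (is.null(mask)) stop("extract stage has no mask input")
        net <- extract_network(mask,
                                merge_ratio = config$extract$merge_ratio,
                                min_pore_radius_um =
                                  config$extract$min_pore_radius_um)
        write_network_tables(net, file.path(outdir, "network"), "tsv")
        artifacts <- c(artifacts, file.path(outdir, "network", "nodes.tsv"),
                        file.path(outdir, "network", "links.tsv"))
        TRUE
      },
      metrics = {
        if (is.null(net) || is.null(mask))
          stop("metrics stage needs a network and a mask")
        vm <- void_metrics(net, mask)
        .write_tsv(data.frame(v = vm$v, z = vm$z,
                              r43_pore_um = vm$r43_pore_um,
                              r43_throat_um = vm$r43_throat_um,
                              micropore_fraction = vm$micropore_fraction,
                              pore_count = vm$pore_count,
                              throat_count = vm$throat_count),
                   file.path(outdir, "metrics.tsv"))
        artifacts <- c(artifacts, file.path(outdir, "metrics.tsv"))
        TRUE
      }), error = function(e) e)
    if (inherits(res, "error")) {
      .write_manifest(artifacts, outdir, partial = stage)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(res))
    }
    log_line("stage %-8s done in %.2fs", stage,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  writeLines(yaml::as.yaml(config), file.path(outdir,
                                              "config_resolved.yaml"))
  manifest <- .write_manifest(artifacts, outdir)
  invisible(manifest)
}

.write_manifest <- function(artifacts, outdir, partial = NULL) {
  manifest <- data.frame(
    artifact = sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1",
                                    outdir), "/?"), "", artifacts),
    md5 = unname(tools::md5sum(artifacts)))
  if (!is.null(partial))
    manifest$failed_at <- rep(partial, nrow(manifest))
  .write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  manifest
}

#' Export a ball-and-stick scene
#'
#' Writes a renderer-neutral TSV scene description: one record per pore
#' (sphere) and per throat (cylinder between its pore centres), each with a
#' colour scalar `log10(radius_um)` as used in ball-and-stick renderings of
#' pore networks. Records are ordered by id.
#'
#' @param network a `pore_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_ball_and_stick <- function(network, path) {
  stopifnot(inherits(network, "pore_network"))
  p <- network$pores[order(network$pores$id), , drop = FALSE]
  t <- network$throats[order(network$throats$id), , drop = FALSE]
  sph <- data.frame(kind = rep("sphere", nrow(p)), id = p$id,
                    x1_um = p$cx_um, y1_um = p$cy_um, z1_um = p$cz_um,
                    x2_um = NA_real_, y2_um = NA_real_, z2_um = NA_real_,
                    radius_um = p$radius_um,
                    color_log10_radius = log10(p$radius_um))
  if (nrow(t)) {
    ia <- match(t$pore_a, p$id); ib <- match(t$pore_b, p$id)
    cyl <- data.frame(kind = "cylinder", id = t$id,
                      x1_um = p$cx_um[ia], y1_um = p$cy_um[ia],
                      z1_um = p$cz_um[ia],
                      x2_um = p$cx_um[ib], y2_um = p$cy_um[ib],
                      z2_um = p$cz_um[ib],
                      radius_um = t$radius_um,
                      color_log10_radius = log10(t$radius_um))
  } else cyl <- sph[0, ]
  .write_tsv(rbind(sph, cyl), path)
  invisible(path)
}
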