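# End-to-end orchestration with reproducible configuration and a manifest.

#' Run configuration
#'
#' A single nested configuration with the reference defaults for every stage:
#' density thresholds (0.2, 0.05, 0.005), 100 um injection-core erosion,
#' 150 um clustering voxels, and the network cutoffs 0.15 (corticocortical
#' density), 0.2 (nuclear coverage), 0.5 (primary convergence).
#'
#' @param seed integer seed used for scene generation.
#' @param scene a [scene_config()] (its seed is overridden by `seed`).
#' @param density_thresholds dense/moderate/diffuse cutoffs.
#' @param clustering_voxel_um feature-matrix voxel size.
#' @param n_clusters cluster counts at which to cut the voxel dendrogram.
#' @param cc_cutoff,thal_cutoff,convergence_cutoff network cutoffs.
#' @param apply_misalignment simulate and correct a sectioning misalignment.
#' @param alignment_upsample upsampling factor from the data grid to the
#'   resolution at which section alignment operates.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       scene = scene_config(seed = seed),
                       density_thresholds = c(0.2, 0.05, 0.005),
                       clustering_voxel_um = 150,
                       n_clusters = c(2, 3, 4, 15),
                       cc_cutoff = 0.15,
                       thal_cutoff = 0.2,
                       convergence_cutoff = 0.5,
                       apply_misalignment = TRUE,
                       alignment_upsample = 2) {
  scene$seed <- seed
  structure(as.list(environment()), class = "run_config")
}

config_json <- function(config) {
  cfg <- unclass(config)
  cfg$scene <- unclass(cfg$scene)
  cfg$scene$misalignment <- unclass(cfg$scene$misalignment)
  jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the full pipeline
#'
#' Executes simulate, (mis)align, density classification, convergence,
#' confidence mapping, voxel clustering, and network extraction on a
#' synthetic scene, writing all artifacts plus a manifest (config, package
#' version, per-file checksums) to `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return A list of in-memory stage results (invisibly also written to
#'   `out_dir`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  scene <- stage("simulate", {
    sc <- make_scene(config$scene)
    write_scene(sc, file.path(out_dir, "scene"))
    sc
  })

  alignment <- stage("align", {
    if (!config$apply_misalignment) NULL else {
      # alignment operates at section-image resolution, finer than the
      # 100 um voxelized data grid
      f <- config$alignment_upsample
      tmpl <- upsample_mask(scene$striatum, f)
      lm_tmpl <- upsample_mask(scene$landmark, f)
      tru <- upsample_transform(scene$truth$transform, f)
      mis <- apply_misalignment(tmpl, tru)
      mis_lm <- apply_misalignment(lm_tmpl, tru)
      corr <- correct_misalignment(mis, tmpl,
                                   landmark = mis_lm,
                                   landmark_template = lm_tmpl)
      write_volume_nifti(corr$stack, file.path(out_dir, "aligned.nii.gz"))
      jsonlite::write_json(
        list(roll_deg = corr$transform$roll_deg,
             pitch_deg = corr$transform$pitch_deg,
             yaw_deg = corr$transform$yaw_deg,
             scales = c(corr$transform$scale_ap, corr$transform$scale_dv,
                        corr$transform$scale_ml),
             dice = corr$dice),
        file.path(out_dir, "alignment.json"), auto_unbox = TRUE, digits = NA
      )
      corr
    }
  })

  density <- stage("density", {
    maps <- lapply(scene$cortical_fields, classify_density,
                   striatum = scene$striatum,
                   thresholds = config$density_thresholds)
    for (nm in names(maps)) {
      write_volume_nifti(maps[[nm]],
                         file.path(out_dir, paste0("class_", nm, ".nii.gz")))
    }
    maps
  })

  converge <- stage("converge", {
    diffuse_fields <- lapply(density, tier_mask, "diffuse")
    dense_fields <- lapply(density, tier_mask, "dense")
    cc <- convergence_count(diffuse_fields)
    split <- split_high_low(cc, scene$striatum_ipsi)
    pw <- pairwise_convergence(diffuse_fields)
    utils::write.csv(pw, file.path(out_dir, "pairwise_convergence.csv"))
    jsonlite::write_json(
      list(threshold = split$threshold,
           high = as.list(split$high_stats), low = as.list(split$low_stats)),
      file.path(out_dir, "convergence_split.json"),
      auto_unbox = TRUE, digits = NA
    )
    list(count = cc, split = split, pairwise = pw,
         dense_fields = dense_fields, diffuse_fields = diffuse_fields)
  })

  confmaps <- stage("confmap", {
    target <- density[[1]]
    cm <- confidence_map_graded(scene$thalamic_injections, target,
                                scene$thalamus)
    cov <- nuclear_coverage(cm, scene$atlas)
    utils::write.csv(cov, file.path(out_dir, "nuclear_coverage.csv"),
                     row.names = FALSE)
    list(map = cm, coverage = cov)
  })

  clusters <- stage("cluster", {
    fm <- build_feature_matrix(density, scene$striatum_ipsi,
                               voxel_um = config$clustering_voxel_um)
    hc <- cluster_voxels(fm)
    cuts <- lapply(config$n_clusters, function(k)
      cut_dendrogram(hc, k = k))
    names(cuts) <- paste0("k", config$n_clusters)
    write_linkage_csv(hc, file.path(out_dir, "voxel_linkage.csv"))
    list(features = fm, dendrogram = hc, cuts = cuts)
  })

  network <- stage("network", {
    fields_by_tier <- list(
      dense = converge$dense_fields,
      moderate = lapply(density, tier_mask, "moderate"),
      diffuse = converge$diffuse_fields
    )
    conv <- primary_convergent(fields_by_tier,
                               cutoff = config$convergence_cutoff)
    cc <- corticocortical_edges(scene$cortical_density,
                                cutoff = config$cc_cutoff)
    ts_cov <- data.frame(nucleus = confmaps$coverage$nucleus,
                         target = "subdiv1",
                         fraction = confmaps$coverage$average)
    edges <- rbind(
      cc,
      data.frame(source = conv$source[conv$qualifies],
                 target = conv$target[conv$qualifies],
                 type = "corticostriatal_convergent",
                 weight = conv$convergence[conv$qualifies]),
      thalamic_edges(ts_cov, "thalamostriatal", config$thal_cutoff),
      thalamic_edges(scene$thalamocortical_coverage, "thalamocortical",
                     config$thal_cutoff),
      thalamic_edges(scene$corticothalamic_coverage, "corticothalamic",
                     config$thal_cutoff)
    )
    nodes <- data.frame(
      name = c(names(scene$cortical_fields),
               unname(scene$atlas$names), "subdiv1"),
      class = c(rep("cortical", length(scene$cortical_fields)),
                rep("thalamic", length(scene$atlas$names)),
                "striatal_subdivision")
    )
    graph <- circuit_graph(nodes, edges)
    export_graph(graph, file.path(out_dir, "circuit_edges.csv"), "csv")
    export_graph(graph, file.path(out_dir, "circuit.graphml"), "graphml")
    graph
  })

  manifest <- stage("manifest", {
    files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    mf <- list(
      package_version = as.character(utils::packageVersion("striomap")),
      config = jsonlite::fromJSON(config_json(config)),
      config_hash = unname(tools::md5sum(
        local({
          f <- tempfile(); writeLines(config_json(config), f); f
        })
      )),
      checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                          substring(files,
                                                    nchar(out_dir) + 2)))
    )
    jsonlite::write_json(mf, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    mf
  })

  invisible(list(scene = scene, alignment = alignment, density = density,
                 convergence = converge, confidence = confmaps,
                 clusters = clusters, network = network,
                 manifest = manifest))
}
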