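# End-to-end orchestration of the synthetic-embryo analysis: simulate ->
# segment -> detect/fit clusters -> gradient statistics -> colocalization ->
# sensing model, as a configurable, seeded pipeline.

#' Default pipeline configuration
#'
#' Stage toggles, per-stage parameters and seeds for [run_pipeline()]. The
#' defaults use the calibrated presets from [preset_bcd()] at desk-scale
#' problem sizes.
#'
#' @param seed Master seed; per-stage streams are split from it.
#' @param stages Character vector of enabled stages, any of
#'   `"clusters"`, `"persistence"`, `"gradient"`, `"coloc"`, `"sense"`.
#' @param n_nuclei_clusters Nuclei imaged for the cluster stage. Default 4.
#' @param n_nuclei_gradient Truth-level nuclei for the gradient stage.
#'   Default 300.
#' @param n_videos Time-lapse videos for the persistence stage. Default 20.
#' @param n_nuclei_coloc Two-channel nuclei (truth level). Default 120.
#' @param D Diffusion constant for the sensing stage (um^2/s). Default 4.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            stages = c("clusters", "persistence", "gradient",
                                       "coloc", "sense"),
                            n_nuclei_clusters = 4,
                            n_nuclei_gradient = 300,
                            n_videos = 20,
                            n_nuclei_coloc = 120,
                            D = 4) {
  preset <- preset_bcd()
  structure(list(
    seed = seed, stages = stages, preset = preset,
    n_nuclei_clusters = n_nuclei_clusters,
    n_nuclei_gradient = n_nuclei_gradient,
    n_videos = n_videos,
    n_nuclei_coloc = n_nuclei_coloc,
    D = D
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys override [pipeline_config()]
#' defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  overrides <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  known <- intersect(names(overrides), names(cfg))
  cfg[known] <- overrides[known]
  cfg
}

#' Run the synthetic-embryo analysis pipeline
#'
#' Executes the enabled stages in order on synthetic data generated from the
#' configuration's presets, and returns a report bundle of tibbles and fit
#' summaries. When `out_dir` is given, per-stage CSV/JSON artifacts, a
#' provenance log (seed, parameters, package version) and a frozen copy of
#' the resolved configuration are written there.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A `pipeline_report` list with one element per executed stage and
#'   a `provenance` entry.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  preset <- config$preset
  sim <- preset$sim
  acq <- preset$acq
  report <- list()
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  if ("clusters" %in% config$stages) {
    report$clusters <- run_stage("clusters", function() {
      per_nuc <- map(seq_len(config$n_nuclei_clusters), function(i) {
        g <- generate_nucleus_stack(sim, acq, x_over_L = 0.2,
                                    seed = local_seed(config$seed, 100L + i))
        msk <- sphere_mask(dim(g$stack$channels[[1]]),
                           c(g$truth$nuclei$cx_px, g$truth$nuclei$cy_px,
                             g$truth$nuclei$cz_px),
                           g$truth$nuclei$r_xy_px, g$truth$nuclei$r_z_px)
        cl <- quantify_clusters(g$stack, msk)
        cl$nucleus <- i
        cl
      })
      cl <- list_rbind(per_nuc)
      list(
        table = cl,
        summary = tibble(
          n_clusters = nrow(cl),
          mean_d_nm = mean(cl$d_nm),
          mean_amp_ratio = mean(cl$amp_ratio)
        )
      )
    })
  }

  if ("persistence" %in% config$stages) {
    report$persistence <- run_stage("persistence", function() {
      traces <- do.call(cbind, map(seq_len(config$n_videos), function(i) {
        generate_timelapse(sim, acq, n_frames = 60,
                           seed = local_seed(config$seed, 200L + i),
                           n_clusters = 5, render = FALSE)$truth$traces
      }))
      ps <- persistence_stats(presence = traces, frame_time = acq$frame_time)
      tidy(ps)
    })
  }

  if ("gradient" %in% config$stages) {
    report$gradient <- run_stage("gradient", function() {
      out <- list()
      for (q in c("Inuc", "Ic")) {
        pr <- preset$gradient[[q]]
        g <- simulate_nuclear_gradient(
          config$n_nuclei_gradient, c(0.1, 0.65), lambda = pr$lambda,
          cv = pr$cv, amplitude = pr$amplitude,
          seed = local_seed(config$seed, 300L + nchar(q)), quantity = q
        )
        tab <- bin_and_bootstrap(g, q, bin_edges = seq(0.1, 0.65, 0.05),
                                 n_boot = 500,
                                 seed = local_seed(config$seed, 310L))
        fit <- fit_gradient(tab, q)
        pe <- positional_error(tab, fit$lambda, quantity = q)
        out[[q]] <- list(
          table = tab, fit = glance(fit),
          sigma_x_pctL = 100 * pe$mean, sigma_x_sd_pctL = 100 * pe$sd
        )
      }
      out
    })
  }

  if ("coloc" %in% config$stages) {
    report$coloc <- run_stage("coloc", function() {
      tc <- generate_two_channel(sim, acq, "target-strong",
                                 n_nuclei = config$n_nuclei_coloc,
                                 seed = local_seed(config$seed, 400L))
      hs <- tc$hotspots |>
        dplyr::transmute(nucleus = .data$nucleus, x_um = .data$hx_um,
                         y_um = .data$hy_um, z_um = .data$hz_um)
      cp <- coupling_fraction(hs, tc$clusters, r0_um = sim$accumulation_radius_um,
                              seed = local_seed(config$seed, 401L))
      tibble(
        gene_mode = tc$gene_mode,
        coupling_fraction = cp$coupling_fraction,
        median_um = cp$median_um,
        median_se_um = cp$median_se_um,
        planted_fraction = mean(tc$nuclei$coupled_true)
      )
    })
  }

  if ("sense" %in% config$stages) {
    report$sense <- run_stage("sense", function() {
      budget <- molecule_budget(
        molecules_from_flat(8000, 0.2)$n0,
        sim$nucleus_diameter_um, sim$amp_ratio_mean,
        sim$d_mean / 1000, 55
      )
      p <- sensing_params(D = config$D, d_um = sim$d_mean / 1000,
                          c_clust = budget$cluster_concentration,
                          c_nuc = budget$nuclear_density)
      tibble(
        t_cluster_s = t_cluster(p),
        t_site_s = t_site(p),
        ratio = sensing_ratio(p),
        molecules_per_cluster = budget$molecules_per_cluster,
        cluster_fraction = budget$cluster_fraction
      )
    })
  }

  report$provenance <- list(
    seed = config$seed,
    stages = config$stages,
    package_version = as.character(utils::packageVersion("clustersense")),
    timestamp = NA_character_  # deterministic bundles carry no wall clock
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_out <- config
    cfg_out$preset <- NULL
    jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    if (!is.null(report$clusters)) {
      utils::write.csv(report$clusters$table,
                       file.path(out_dir, "clusters.csv"), row.names = FALSE)
    }
    if (!is.null(report$persistence)) {
      utils::write.csv(report$persistence,
                       file.path(out_dir, "persistence.csv"), row.names = FALSE)
    }
    if (!is.null(report$gradient)) {
      for (q in names(report$gradient)) {
        utils::write.csv(report$gradient[[q]]$table,
                         file.path(out_dir, paste0("gradient_", q, ".csv")),
                         row.names = FALSE)
      }
      jsonlite::write_json(
        purrr::map(report$gradient, function(x) {
          list(fit = x$fit, sigma_x_pctL = x$sigma_x_pctL)
        }),
        file.path(out_dir, "gradient_fits.json"),
        auto_unbox = TRUE, digits = NA, force = TRUE
      )
    }
    if (!is.null(report$coloc)) {
      utils::write.csv(report$coloc, file.path(out_dir, "coloc.csv"),
                       row.names = FALSE)
    }
    if (!is.null(report$sense)) {
      utils::write.csv(report$sense, file.path(out_dir, "sensing.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(report$provenance,
                         file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> stages:",
      paste(setdiff(names(x), "provenance"), collapse = ", "), "\n")
  invisible(x)
}
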