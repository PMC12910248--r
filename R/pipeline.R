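#' Configuration for an end-to-end synthetic pipeline run
#'
#' Bundles the seeds, sizes, and marker/statistics parameters of a full
#' synthetic run. Every run writes back its resolved configuration so the
#' results are regenerable from the output directory alone.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; each stage derives its own stream from it.
#' @param stages Stages to run, in order, among `"synth"`, `"markers"`,
#'   `"stats"`, `"mediation"`.
#' @param group_sizes Cohort group sizes for the synthetic cohort.
#' @param n_taxa,n_metabolites Omics table sizes.
#' @param phantom_shape Grid size of the imaging phantoms.
#' @param n_perm PERMANOVA permutations.
#' @param n_boot Mediation bootstrap draws.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       stages = c("synth", "markers", "stats", "mediation"),
                       group_sizes = c(HC = 20, `WMH-NC` = 20, `WMH-CI` = 20),
                       n_taxa = 20, n_metabolites = 30,
                       phantom_shape = c(16, 16, 16),
                       n_perm = 199, n_boot = 200) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(
    list(
      out_dir = out_dir, seed = as.integer(seed), stages = stages,
      group_sizes = group_sizes, n_taxa = n_taxa,
      n_metabolites = n_metabolites, phantom_shape = phantom_shape,
      n_perm = n_perm, n_boot = n_boot
    ),
    class = "run_config"
  )
}

stage_outputs <- function(config) {
  o <- config$out_dir
  list(
    synth = file.path(o, c(
      "cohort.tsv", "taxa.tsv", "metabolites.tsv",
      "diffusivity_dxx.nii", "diffusivity_dyy.nii", "diffusivity_dzz.nii",
      "coupling_series.tsv", "truth.yaml"
    )),
    markers = file.path(o, "markers.tsv"),
    stats = file.path(o, c("stats_groupdiff.tsv", "stats_permanova.tsv")),
    mediation = file.path(o, "mediation.tsv")
  )
}

write_tsv_na <- function(x, path) {
  readr::write_tsv(as.data.frame(x), path, na = "NA")
}

ot_to_tsv <- function(ot, path) {
  write_tsv_na(as_tibble(ot), path)
}

#' Run the synthetic end-to-end pipeline
#'
#' Chains the synthetic-data generators, the glymphatic markers, the omics
#' group statistics, and the serial mediation model into one reproducible
#' run: each requested stage reads only the outputs of earlier stages,
#' writes tab-separated results under the configured directory, and logs
#' the conventions it used. A fixed master seed makes the whole output
#' directory byte-identical across runs.
#'
#' @param config A [run_config()].
#' @param resume If `TRUE`, stages whose outputs already exist are skipped
#'   and only missing (downstream) stages are regenerated.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config.")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- stage_outputs(config)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  done <- function(stage) all(file.exists(outputs[[stage]]))
  wants <- function(stage) stage %in% config$stages

  ## ---- synth ----
  if (wants("synth") && !(resume && done("synth"))) {
    truth <- cohort_truth(config$group_sizes,
      planted_effects = tibble(
        assay = c("taxa", "metabolites"), variable = c(1L, 1L),
        group = names(config$group_sizes)[length(config$group_sizes)],
        offset = c(log(2), log(1.5))
      ),
      seed = derive_seed(config$seed, "synth")
    )
    cohort <- gen_mediation_cohort(truth, n = sum(config$group_sizes))
    cohort$group <- rep(names(config$group_sizes), config$group_sizes)
    write_tsv_na(cohort, file.path(config$out_dir, "cohort.tsv"))
    om <- gen_group_omics(truth, config$n_taxa, config$n_metabolites)
    ot_to_tsv(om$taxa, file.path(config$out_dir, "taxa.tsv"))
    ot_to_tsv(om$metabolites, file.path(config$out_dir, "metabolites.tsv"))

    # painted diffusivity phantom for the ALPS stage
    shp <- config$phantom_shape
    mk <- function(v) volume_grid(array(v, shp))
    write_nifti(mk(1.1e-3), file.path(config$out_dir, "diffusivity_dxx.nii"))
    write_nifti(mk(0.7e-3), file.path(config$out_dir, "diffusivity_dyy.nii"))
    write_nifti(mk(0.7e-3), file.path(config$out_dir, "diffusivity_dzz.nii"))

    ctruth <- coupling_phantom_truth()
    series <- purrr::map_dfr(1:10, function(s) {
      dplyr::mutate(
        gen_coupling_series(ctruth, seed = derive_seed(config$seed, "coupling", s)),
        subject = sprintf("P%02d", s)
      )
    })
    write_tsv_na(series, file.path(config$out_dir, "coupling_series.tsv"))
    yaml::write_yaml(
      list(
        group_sizes = as.list(truth$group_sizes),
        mediation_paths = as.list(truth$mediation_paths),
        noise_sds = as.list(truth$noise_sds),
        seed = truth$seed,
        coupling = list(
          lag_true = ctruth$lag_true, amplitude = ctruth$amplitude,
          tr = ctruth$tr, n_volumes = ctruth$n_volumes
        )
      ),
      file.path(config$out_dir, "truth.yaml")
    )
    note("synth: generated cohort, omics, phantoms (seed %d)", config$seed)
  } else if (wants("synth")) {
    note("synth: outputs present, skipped (resume)")
  }

  ## ---- markers ----
  if (wants("markers") && !(resume && done("markers"))) {
    need <- outputs$synth
    if (!all(file.exists(need))) {
      abort("markers stage: missing upstream synth outputs; run the synth stage first.")
    }
    dxx <- read_nifti(file.path(config$out_dir, "diffusivity_dxx.nii"))
    dyy <- read_nifti(file.path(config$out_dir, "diffusivity_dyy.nii"))
    dzz <- read_nifti(file.path(config$out_dir, "diffusivity_dzz.nii"))
    shp <- dim(dxx$data)
    mid <- round(shp / 2)
    rois <- alps_rois(
      centers = rbind(
        left_scr = c(mid[1] - 4, mid[2], mid[3]),
        left_slf = c(mid[1] - 2, mid[2], mid[3]),
        right_scr = c(mid[1] + 4, mid[2], mid[3]),
        right_slf = c(mid[1] + 2, mid[2], mid[3])
      ),
      diameter_mm = 3, space = "phantom"
    )
    alps <- compute_alps(dxx, dyy, dzz, rois)
    series <- readr::read_tsv(file.path(config$out_dir, "coupling_series.tsv"),
      show_col_types = FALSE
    )
    truth <- yaml::read_yaml(file.path(config$out_dir, "truth.yaml"))
    cg <- gbold_csf_coupling(series, tr = truth$coupling$tr)
    markers <- tibble(
      marker = c("alps_mean", "alps_left", "alps_right", "coupling_lag_s", "coupling_strength"),
      value = c(
        alps$alps_mean, alps$alps_left, alps$alps_right,
        cg$chosen_lag, mean(cg$subjects$strength)
      )
    )
    write_tsv_na(markers, outputs$markers)
    note("markers: ALPS (no asymmetry correction) and gBOLD-CSF coupling")
  } else if (wants("markers")) {
    note("markers: outputs present, skipped (resume)")
  }

  ## ---- stats ----
  if (wants("stats") && !(resume && done("stats"))) {
    if (!all(file.exists(outputs$synth))) {
      abort("stats stage: missing upstream synth outputs; run the synth stage first.")
    }
    taxa <- readr::read_tsv(file.path(config$out_dir, "taxa.tsv"),
      show_col_types = FALSE
    )
    feat <- setdiff(names(taxa), c("sample_id", "role", "group"))
    m <- as.matrix(taxa[feat])
    rownames(m) <- taxa$sample_id
    d <- bray_curtis(m)
    pm <- permanova(d, taxa$group,
      n_perm = config$n_perm,
      seed = derive_seed(config$seed, "permanova")
    )
    write_tsv_na(tidy(pm), file.path(config$out_dir, "stats_permanova.tsv"))
    kw <- purrr::map_dfr(feat, function(f) {
      dplyr::mutate(adjusted_kruskal_wallis(taxa, f, "group"), feature = f)
    })
    write_tsv_na(kw, file.path(config$out_dir, "stats_groupdiff.tsv"))
    note(
      "stats: Bray-Curtis + PERMANOVA (%d perms), Kruskal-Wallis per genus",
      config$n_perm
    )
  } else if (wants("stats")) {
    note("stats: outputs present, skipped (resume)")
  }

  ## ---- mediation ----
  if (wants("mediation") && !(resume && done("mediation"))) {
    if (!file.exists(file.path(config$out_dir, "cohort.tsv"))) {
      abort("mediation stage: missing upstream synth outputs; run the synth stage first.")
    }
    cohort <- readr::read_tsv(file.path(config$out_dir, "cohort.tsv"),
      show_col_types = FALSE
    )
    fit <- serial_mediation(cohort, "x", "m1", "m2", "y",
      covariates = intersect(c("c1", "c2", "c3", "c4"), names(cohort)),
      n_boot = config$n_boot, seed = derive_seed(config$seed, "mediation")
    )
    write_tsv_na(tidy(fit), outputs$mediation)
    note(
      "mediation: percentile bootstrap CIs, %d draws, complete-case",
      config$n_boot
    )
  } else if (wants("mediation")) {
    note("mediation: outputs present, skipped (resume)")
  }

  ## resolved config + log (log is informational, not part of the data)
  yaml::write_yaml(
    list(
      seed = config$seed, stages = config$stages,
      group_sizes = as.list(config$group_sizes),
      n_taxa = config$n_taxa, n_metabolites = config$n_metabolites,
      phantom_shape = config$phantom_shape,
      n_perm = config$n_perm, n_boot = config$n_boot
    ),
    file.path(config$out_dir, "config_resolved.yaml")
  )
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(config$out_dir)
}
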