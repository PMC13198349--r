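# End-to-end orchestration: generate a cohort, run devices and sweeps,
# aggregate, and write result tables.

#' Pipeline run configuration
#'
#' @param n_patients cohort size
#' @param anatomy an [anatomy_config] for the cohort means
#' @param variability cohort variability, see [default_variability()]
#' @param devices list of [device_spec] (default: the contemporary
#'   catalogue)
#' @param sweep_lengths lengths (mm) for the volume-preserving sweep of
#'   every device in `devices`; `NULL` disables the sweep
#' @param engine an [engine_config]
#' @param grid_resolution prevalence-map resolution
#' @param lbbap_margin LBBAP region dilation margin (mm)
#' @param out_dir output directory (`NULL`: nothing written)
#' @param seed master seed; all randomness flows from it
#' @export
run_config <- function(n_patients = 10, anatomy = anatomy_config(),
                       variability = default_variability(),
                       devices = lpm_catalogue(), sweep_lengths = NULL,
                       engine = engine_config(), grid_resolution = 50,
                       lbbap_margin = 5, out_dir = NULL, seed = 1) {
  structure(list(n_patients = n_patients, anatomy = anatomy,
                 variability = variability, devices = devices,
                 sweep_lengths = sweep_lengths, engine = engine,
                 grid_resolution = grid_resolution,
                 lbbap_margin = lbbap_margin, out_dir = out_dir,
                 seed = as.integer(seed)), class = "run_config")
}

#' Run the full collision-risk pipeline
#'
#' Generates (or accepts) the cohort, assesses every device (and sweep
#' design) at every septal node of every patient, and aggregates regional
#' statistics, length trends and prevalence maps.  Deterministic under
#' `config$seed`.  A patient whose assessment fails is logged and skipped;
#' remaining patients still run.
#'
#' @param config a [run_config]
#' @param cohort optional pre-generated list of `patient_anatomy`
#' @return list: `records` (site-level data.frame over all devices),
#'   `labels`, `regional` (regional-stats table, all devices),
#'   `trends` (length-trend table or `NULL`), `maps` (per-device prevalence
#'   maps), `cohort_summary`, `manifest`
#' @export
run_pipeline <- function(config, cohort = NULL) {
  if (length(config$devices) == 0) stop("empty device list")
  if (is.null(cohort)) {
    cohort <- generate_cohort(config$n_patients, config$anatomy,
                              config$variability, config$seed)
  }
  if (length(cohort) == 0) stop("empty cohort")

  devices <- config$devices
  sweep_devices <- list()
  if (!is.null(config$sweep_lengths)) {
    for (d in devices) {
      sw <- build_sweep(d, config$sweep_lengths)
      sweep_devices <- c(sweep_devices, sw$derived)
    }
  }
  all_devices <- c(devices, sweep_devices)

  records <- list()
  labels <- list()
  for (p in seq_along(cohort)) {
    res <- tryCatch({
      an <- cohort[[p]]
      lab <- septal_labels(an, config$lbbap_margin)
      lab$patient <- p
      bvhs <- anatomy_bvhs(an)
      recs <- lapply(all_devices, function(d) {
        run_patient(an, d, config$engine, bvhs = bvhs, patient = p)
      })
      list(lab = lab, recs = do.call(rbind, recs))
    }, error = function(e) {
      warning(sprintf("patient %d failed: %s", p, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    labels[[length(labels) + 1]] <- res$lab
    records[[length(records) + 1]] <- res$recs
  }
  if (length(records) == 0) stop("all patients failed")
  records <- do.call(rbind, records)
  labels <- do.call(rbind, labels)

  regional <- do.call(rbind, lapply(unique(records$device), function(dn) {
    regional_stats(records[records$device == dn, ], labels)
  }))
  regional <- merge(regional,
                    unique(records[, c("device", "length_mm", "diameter_mm")]),
                    by = "device")

  trends <- NULL
  if (!is.null(config$sweep_lengths)) {
    sweep_names <- vapply(sweep_devices, function(d) d$name, character(1))
    sw <- regional[regional$device %in% sweep_names & regional$region_type == "ALL", ]
    if (nrow(sw) > 0) trends <- length_trend(sw)
  }

  maps <- lapply(setNames(nm = vapply(devices, function(d) d$name, character(1))),
                 function(dn) {
                   cohort_prevalence_map(records[records$device == dn, ], labels,
                                         config$grid_resolution)
                 })

  cohort_summary <- data.frame(
    patient = seq_along(cohort),
    edv_ml = vapply(cohort, function(a) max(frame_volumes(a$sequence)), numeric(1)),
    esv_ml = vapply(cohort, function(a) min(frame_volumes(a$sequence)), numeric(1)),
    ef_pct = vapply(cohort, function(a) measured_ef(a$sequence), numeric(1)))

  manifest <- list(seed = config$seed, n_patients = length(cohort),
                   devices = lapply(all_devices, function(d)
                     list(name = d$name, length_mm = d$length,
                          diameter_mm = d$diameter, volume_mm3 = d$volume)),
                   grid_resolution = config$grid_resolution,
                   exclusion_radius = config$engine$exclusion_radius)

  out <- list(records = records, labels = labels, regional = regional,
              trends = trends, maps = maps, cohort_summary = cohort_summary,
              manifest = manifest)
  if (!is.null(config$out_dir)) write_results(out, config$out_dir)
  out
}

write_results <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(out$records, file.path(dir, "site_records.csv"), row.names = FALSE)
  write.csv(out$labels, file.path(dir, "septal_labels.csv"), row.names = FALSE)
  write.csv(out$regional, file.path(dir, "regional_risk.csv"), row.names = FALSE)
  if (!is.null(out$trends)) {
    write.csv(out$trends, file.path(dir, "length_trend.csv"), row.names = FALSE)
  }
  write.csv(out$cohort_summary, file.path(dir, "cohort_summary.csv"),
            row.names = FALSE)
  for (dn in names(out$maps)) {
    write.csv(out$maps[[dn]]$proportion,
              file.path(dir, sprintf("prevalence_grid_%s.csv", dn)),
              row.names = FALSE)
  }
  jsonlite::write_json(out$manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Canned micro-scenes with analytically known collision outcomes
#'
#' Two-frame static fixtures used by the test suite:
#' \describe{
#'   \item{wall_hit}{a 3 x 3-node flat septum with a small RV_WALL cube above
#'     one corner node: with a radius-1, length-16 device exactly that node
#'     collides (the cube floor is at height 15); a length-10 device misses
#'     everywhere.}
#'   \item{tv_graze}{the same septum under a broad TV slab whose underside is
#'     at height 20: TV becomes positive exactly at device lengths >= 20.}
#' }
#'
#' @param seed unused (fixtures are deterministic); kept for interface
#'   symmetry with the generators
#' @return named list of `patient_anatomy` fixtures with an `expected`
#'   attribute describing the known outcome
#' @export
make_fixtures <- function(seed = 1) {
  septum <- flat_septum_mesh()
  cavity <- cube_mesh(60, c(0, 0, 25), "CAVITY")
  landmarks <- list(apex = c(0, 0, 0), tv_centre = c(0, 0, 40),
                    attach_anterior = c(20, 0, 0), attach_posterior = c(0, 20, 0))
  fixture <- function(extra, expected) {
    sc <- labeled_scene(c(list(SEPTUM = septum, CAVITY = cavity), extra), landmarks)
    an <- structure(list(
      sequence = scene_sequence(list(sc, sc), phase = c(0, 0.5)),
      landmarks = landmarks, chordae_points = list(),
      conduction_paths = list(), config = NULL), class = "patient_anatomy")
    attr(an, "expected") <- expected
    an
  }
  list(
    wall_hit = fixture(
      list(RV_WALL = cube_mesh(8, c(7, 7, 19), "RV_WALL"),
           PM = cube_mesh(4, c(-30, -30, 40), "PM"),
           TV = cube_mesh(4, c(30, -30, 40), "TV")),
      list(hit_node = 9L, hit_length = 16, miss_length = 10, radius = 1)),
    tv_graze = fixture(
      list(RV_WALL = cube_mesh(4, c(-30, 30, 40), "RV_WALL"),
           TV = box_mesh(c(40, 40, 4), c(0, 0, 22), "TV")),
      list(threshold_length = 20, radius = 1)))
}

# 3 x 3-node unit septum patch in the z = 0 plane, nodes at {-10, 0, 10}^2,
# node 9 at (10, 10); inward normal +z (toward the cavity fixture)
flat_septum_mesh <- function() {
  g <- expand.grid(x = c(-10, 0, 10), y = c(-10, 0, 10))
  v <- cbind(g$x, g$y, 0)
  idx <- function(i, j) (j - 1L) * 3L + i
  f <- list()
  for (i in 1:2) for (j in 1:2) {
    f[[length(f) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i, j + 1))
    f[[length(f) + 1]] <- c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  triangle_mesh(v, do.call(rbind, f), "SEPTUM")
}
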