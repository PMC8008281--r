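#' Pipeline run configuration
#'
#' Settings for an end-to-end run: simulate (or load) a cohort, derive SES
#' scores and groups, generate and measure labelled volumes, generate and
#' measure folded surfaces, fit the association battery, and write result
#' tables plus a JSON manifest.  In demo mode (no input paths) every input
#' is synthesised, standing in for a non-deposited clinical cohort.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; every stage's randomness derives from
#'   it.
#' @param cohort_csv Optional existing cohort CSV; `NULL` simulates one.
#' @param n_subjects,frac_longitudinal Cohort size when simulating.
#' @param lgi_radius LGI patch radius, mm.
#' @param ses_threshold SES group cut point.
#' @param distress_thresholds Named vector as [distress_thresholds()].
#' @param voxel_dims Voxel edge lengths in mm for simulated volumes
#'   (default `c(1.25, 1.25, 2)`, a typical fetal T2 acquisition).
#' @param grid_dim Simulated volume grid size.
#' @param mesh_subdivisions Icosphere level for simulated surfaces.
#' @param write_images If `TRUE`, write each scan's NIfTI volume and PLY
#'   surface under `out_dir` (off by default: the measured tables are the
#'   product).
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("fetalmorph_run"),
                       seed = 1L,
                       cohort_csv = NULL,
                       n_subjects = 144,
                       frac_longitudinal = 40 / 144,
                       lgi_radius = 10,
                       ses_threshold = 51,
                       distress_thresholds = c(ssai = 40, stai = 40,
                                               pss = 15, epds = 10),
                       voxel_dims = c(1.25, 1.25, 2),
                       grid_dim = c(56, 56, 44),
                       mesh_subdivisions = 2L,
                       write_images = FALSE) {
  if (lgi_radius <= 0 || ses_threshold <= 0 ||
      any(distress_thresholds <= 0))
    stopf("thresholds must be positive")
  if (!is.null(cohort_csv) && !file.exists(cohort_csv))
    stopf("cohort_csv does not exist: %s", cohort_csv)
  structure(as.list(environment()), class = "run_config")
}

#' Exclusion accounting
#'
#' Tallies scans excluded per reason from a raw scan list.  Percentages
#' are always recomputed from the counts against the raw total (half-up
#' rounding to 1 decimal), never stored independently.
#'
#' @param flags Character vector, one flag per raw scan: `"pass"` or an
#'   exclusion reason code (e.g. `"motion"`, `"surface_fail"`).
#' @param scan_ids Optional raw scan identifiers (same length).
#' @return List: `table` (data frame reason / n / pct), `n_raw`,
#'   `n_surviving`.
#' @export
exclusion_report <- function(flags, scan_ids = NULL) {
  allowed <- c("motion", "surface_fail", "pass")
  if (!all(flags %in% allowed))
    stopf("flags must be one of: %s", paste(allowed, collapse = ", "))
  n_raw <- length(flags)
  reasons <- setdiff(unique(flags), "pass")
  tab <- data.frame(
    reason = reasons,
    n = vapply(reasons, function(r) sum(flags == r), integer(1L)),
    stringsAsFactors = FALSE)
  tab$pct <- if (nrow(tab)) round_half_up(100 * tab$n / n_raw, 1) else
    numeric(0)
  list(table = tab, n_raw = n_raw, n_surviving = sum(flags == "pass"),
       excluded_ids = if (!is.null(scan_ids))
         scan_ids[flags != "pass"])
}

# per-scan derived seed, kept below 2^31
scan_seed <- function(master, i, salt = 0L) {
  as.integer((as.numeric(master) * 10007 + i * 97 + salt) %% 2147483587)
}

#' Run the full pipeline
#'
#' Stages: simulate (or load) the cohort; derive SES scores, groups and
#' distress flags; rasterise each scan's tissue volumes into a labelled
#' grid and measure them back by label-volumetry; generate each scan's
#' folded surface (fold amplitude driven by the scan's latent gyrification
#' level) and measure LGI and sulcal depth against its convex hull; fit
#' the linear mixed-effects battery for every SES predictor against
#' measured tissues and folding metrics with Benjamini-Hochberg q-values
#' per family; write results and a reproducibility manifest.  A scan whose
#' imaging stage fails is never silently dropped: it lands in the
#' exclusions table with a reason code and the run continues.
#'
#' @param config A [run_config()].
#' @return List: `cohort`, `morphometry` (per-scan measured table),
#'   `results` (association table), `exclusions`, `manifest`, and the
#'   output file paths.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, paste(format(Sys.time(), "%H:%M:%S"), msg))
    message(msg)
  }

  # --- stage 1: cohort ----------------------------------------------------
  if (is.null(config$cohort_csv)) {
    note("simulate: %d subjects, %.0f longitudinal pairs",
         config$n_subjects,
         round(config$frac_longitudinal * config$n_subjects))
    cohort <- generate_cohort(cohort_config(
      n_subjects = config$n_subjects,
      frac_longitudinal = config$frac_longitudinal,
      seed = config$seed))
  } else {
    note("load cohort: %s", config$cohort_csv)
    cohort <- read.csv(config$cohort_csv, stringsAsFactors = FALSE)
  }
  need <- c("scan_id", "subject_id", "ga_weeks", "sex",
            "edu_m", "occ_m", "edu_f", "occ_f")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stopf("cohort schema violation; missing column(s): %s",
          paste(miss, collapse = ", "))

  # --- stage 2: SES scoring -----------------------------------------------
  cohort <- score_cohort(cohort, config$ses_threshold,
                         config$distress_thresholds)
  note("score: %d scans, %d high-SES, %d visits lack distress measures",
       nrow(cohort), sum(cohort$ses_group == "high"),
       sum(is.na(cohort$distress)))

  # --- stages 3+4: per-scan imaging ---------------------------------------
  tissues <- c("cgm", "wm", "dgm", "cerebellum", "brainstem")
  affine <- diag(c(config$voxel_dims, 1))
  vv <- prod(config$voxel_dims)
  mapping <- list(tissues = as.list(setNames(seq_along(tissues), tissues)))
  lobes <- c("frontal", "parietal", "temporal", "occipital")
  has_latent_vols <- all(tissues %in% names(cohort))
  has_latent_lgi <- "lgi_parietal" %in% names(cohort)

  rows <- vector("list", nrow(cohort))
  flags <- rep("pass", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    rows[[i]] <- tryCatch({
      row <- list(scan_id = cohort$scan_id[i])
      if (has_latent_vols) {
        spec <- lapply(seq_along(tissues), function(t) list(
          label = t,
          count = max(1L, round(cohort[[tissues[t]]][i] * 1000 / vv))))
        lv <- generate_label_volume(spec, dim = config$grid_dim,
                                    affine = affine,
                                    seed = scan_seed(config$seed, i, 1L))
        vt <- tissue_table(lv, lv, mapping)
        names(vt) <- paste0("meas_", names(vt))
        row <- c(row, as.list(vt))
        if (config$write_images)
          write_label_volume(lv, file.path(config$out_dir,
                                           paste0(cohort$scan_id[i],
                                                  "_seg.nii.gz")))
      }
      if (has_latent_lgi) {
        # fold amplitude rises with the scan's latent gyrification level
        amp <- max(0.05, 12 * (cohort$lgi_parietal[i] - 1.10))
        mesh <- generate_folded_surface(folding_params(
          base_radius = 30, amplitude = amp,
          subdivisions = config$mesh_subdivisions,
          seed = scan_seed(config$seed, i, 2L)))
        sm <- surface_morphometry(mesh, lgi_radius = config$lgi_radius)
        for (k in seq_len(nrow(sm$region))) {
          rg <- sm$region$region[k]
          row[[paste0("meas_lgi_", rg)]] <- sm$region$lgi[k]
          row[[paste0("meas_depth_", rg)]] <- sm$region$depth[k]
        }
        if (config$write_images)
          write_ply(mesh, file.path(config$out_dir,
                                    paste0(cohort$scan_id[i], ".ply")))
      }
      as.data.frame(row)
    }, error = function(e) {
      flags[i] <<- "surface_fail"
      note("scan %s excluded: %s", cohort$scan_id[i], conditionMessage(e))
      NULL
    })
  }
  excl <- exclusion_report(flags, cohort$scan_id)
  morph <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  morph <- merge(cohort, morph, by = "scan_id", sort = FALSE)
  note("imaging: %d/%d scans measured", nrow(morph), nrow(cohort))

  # --- stage 5: associations ----------------------------------------------
  predictors <- intersect(c("edu_m", "occ_m", "ses_m",
                            "edu_f", "occ_f", "ses_f", "ses_group"),
                          names(morph))
  fam_tissue <- intersect(paste0("meas_", tissues), names(morph))
  fam_lgi <- intersect(paste0("meas_lgi_", lobes), names(morph))
  fam_depth <- intersect(paste0("meas_depth_", lobes), names(morph))
  extra <- intersect("meas_whole_brain", names(morph))
  results <- list()
  for (pred in predictors) {
    for (fam in list(fam_tissue, fam_lgi, fam_depth)) {
      if (!length(fam)) next
      fits <- lapply(fam, function(o)
        fit_lme(morph, o, pred))
      fr <- do.call(rbind, fits)
      fr$q <- benjamini_hochberg(fr$p)     # family: tissues or lobes
      results[[length(results) + 1L]] <- fr
    }
    for (o in extra) {
      fr <- fit_lme(morph, o, pred)
      fr$q <- fr$p                         # single-outcome family
      results[[length(results) + 1L]] <- fr
    }
  }
  results <- do.call(rbind, results)
  note("assoc: %d model fits", nrow(results))

  # --- stage 6: report ----------------------------------------------------
  paths <- list(
    morphometry = file.path(config$out_dir, "morphometry.csv"),
    results = file.path(config$out_dir, "assoc_results.csv"),
    exclusions = file.path(config$out_dir, "exclusions.csv"),
    manifest = file.path(config$out_dir, "manifest.json"),
    log = file.path(config$out_dir, "run_log.txt"))
  write.csv(morph, paths$morphometry, row.names = FALSE)
  write.csv(results, paths$results, row.names = FALSE)
  write.csv(excl$table, paths$exclusions, row.names = FALSE)
  manifest <- list(
    package = "fetalmorph",
    version = as.character(utils::packageVersion("fetalmorph")),
    seed = config$seed,
    settings = config[c("n_subjects", "frac_longitudinal", "lgi_radius",
                        "ses_threshold", "voxel_dims", "grid_dim",
                        "mesh_subdivisions")],
    distress_thresholds = as.list(config$distress_thresholds),
    n_scans_raw = excl$n_raw,
    n_scans_surviving = excl$n_surviving,
    n_models = nrow(results))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, paths$log)

  list(cohort = cohort, morphometry = morph, results = results,
       exclusions = excl, manifest = manifest, paths = paths)
}
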