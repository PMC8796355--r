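#' Default run configuration
#'
#' All tunables of the pipeline in one nested list: cup geometry, seating
#' parameters, coverage tolerance, morphometric slab thickness, statistics
#' options and the synthetic-cohort parameters.  [read_config()] validates
#' a YAML file against this structure and rejects unknown keys.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    cup = list(outer_diameter_mm = 44, shell_thickness_mm = 4,
               eggshell_thickness_mm = 0.01, subdivision = 3),
    placement = list(abduction_deg = 45, anteversion_deg = 20,
                     step_mm = 0.1, tol_mm = 0.2, max_iter = 500),
    coverage = list(eps_mm = 0.1),
    morphometrics = list(slab_mm = 0.5),
    stats = list(alpha = 0.05, tucr_split = 0.3),
    seed = 1L
  )
}

#' Read and validate a YAML run configuration
#'
#' Keys present in the file override the defaults; unknown keys raise an
#' error naming their path.
#'
#' @param path YAML file path (or `NULL` for pure defaults).
#' @return Validated config list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_checked <- function(base, upd, where = "") {
    for (k in names(upd)) {
      key <- paste0(where, k)
      if (!k %in% names(base)) {
        stop("unknown config key: ", key, call. = FALSE)
      }
      if (is.list(base[[k]])) {
        if (!is.list(upd[[k]])) stop("config key ", key, " must be a map",
                                     call. = FALSE)
        base[[k]] <- merge_checked(base[[k]], upd[[k]], paste0(key, "/"))
      } else {
        base[[k]] <- upd[[k]]
      }
    }
    base
  }
  merge_checked(cfg, user)
}

# Small deterministic content hash (polynomial rolling hash over the
# deparsed config) used to stamp outputs.
config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  sprintf("%08x", h)
}

# Analyse one hip (already-loaded bone + landmarks).  Internal worker.
analyze_hip <- function(bone, landmarks, cfg) {
  frame <- build_pelvic_frame(landmarks)
  spec_std <- cup_spec(cfg$cup$outer_diameter_mm, cfg$cup$shell_thickness_mm,
                       cfg$cup$subdivision)
  pose <- place_cup(bone, landmarks, frame, spec_std,
                    abduction_deg = cfg$placement$abduction_deg,
                    anteversion_deg = cfg$placement$anteversion_deg,
                    step_mm = cfg$placement$step_mm,
                    tol_mm = cfg$placement$tol_mm,
                    max_iter = cfg$placement$max_iter)
  egg <- cup_spec(cfg$cup$outer_diameter_mm, cfg$cup$eggshell_thickness_mm,
                  cfg$cup$subdivision)
  cup_surface <- build_cup_mesh(egg, pose, variant = "outer_shell_only")
  cov <- classify_coverage(bone, cup_surface, eps = cfg$coverage$eps_mm)
  planes <- quadrant_planes(landmarks, frame, pose$center)
  ucrs <- segmental_ucrs(cov, planes)
  h <- acetabular_height(landmarks, frame)
  r <- ap_diameter(bone, landmarks, frame, h,
                   slab_mm = cfg$morphometrics$slab_mm)
  list(pose = pose, coverage = cov, ucrs = ucrs,
       height_mm = h, ap_diameter_mm = r,
       volume_proxy_mm3 = volume_proxy(h, r))
}

hip_record <- function(hip_id, res) {
  data.frame(hip_id = hip_id,
             tucr = res$ucrs$tucr,
             asucr = res$ucrs$asucr, aiucr = res$ucrs$aiucr,
             psucr = res$ucrs$psucr, piucr = res$ucrs$piucr,
             total_area_mm2 = res$ucrs$total_area_mm2,
             uncovered_area_mm2 = sum(res$ucrs$uncovered_area_mm2),
             height_mm = res$height_mm,
             ap_diameter_mm = res$ap_diameter_mm,
             volume_proxy_mm3 = res$volume_proxy_mm3,
             center_x = res$pose$center[1],
             center_y = res$pose$center[2],
             center_z = res$pose$center[3],
             medialization_mm = res$pose$medialization_mm,
             residual_anterior_mm = unname(res$pose$residuals["anterior"]),
             residual_inferior_mm = unname(res$pose$residuals["inferior"]),
             status = "ok", error = "")
}

failed_record <- function(hip_id, msg) {
  out <- data.frame(hip_id = hip_id, tucr = NA_real_, asucr = NA_real_,
                    aiucr = NA_real_, psucr = NA_real_, piucr = NA_real_,
                    total_area_mm2 = NA_real_, uncovered_area_mm2 = NA_real_,
                    height_mm = NA_real_, ap_diameter_mm = NA_real_,
                    volume_proxy_mm3 = NA_real_, center_x = NA_real_,
                    center_y = NA_real_, center_z = NA_real_,
                    medialization_mm = NA_real_,
                    residual_anterior_mm = NA_real_,
                    residual_inferior_mm = NA_real_,
                    status = "failed", error = msg)
  out
}

#' Run the full measurement pipeline over a set of hips
#'
#' For every hip: pelvic frame, cup seating, eggshell coverage
#' classification, quadrant partition, morphometrics; then the cohort
#' statistics stage over the successful hips.  Per-hip failures are
#' recorded and do not abort the run.
#'
#' @param hips A list whose elements are either `cc_synthhip` objects (from
#'   [generate_hip()]), lists with `bone` + `landmarks`, or lists with
#'   file paths `bone_stl` + `landmarks_json`.
#' @param config A config list (see [default_config()]).
#' @param output_dir Optional directory: per-hip CSV and summary CSV are
#'   written there.
#' @return List of class `cc_run`: `records` (per-hip data frame),
#'   `summary` (a [cohort_summary()] when >= 3 hips succeeded), `details`
#'   (per-hip result objects), `meta` (version, config hash), `n_failed`.
#' @export
run_pipeline <- function(hips, config = default_config(),
                         output_dir = NULL) {
  if (length(hips) < 1) stop("need at least one hip", call. = FALSE)
  details <- vector("list", length(hips))
  rows <- vector("list", length(hips))
  for (i in seq_along(hips)) {
    h <- hips[[i]]
    hip_id <- if (!is.null(h$hip_id)) h$hip_id else sprintf("hip_%03d", i)
    rows[[i]] <- tryCatch({
      if (!is.null(h$bone_stl)) {
        bone <- read_stl(h$bone_stl)
        landmarks <- read_landmarks_json(h$landmarks_json)
      } else {
        bone <- h$bone
        landmarks <- h$landmarks
      }
      res <- analyze_hip(bone, landmarks, config)
      details[[i]] <- res
      hip_record(hip_id, res)
    }, error = function(e) failed_record(hip_id, conditionMessage(e)))
  }
  records <- do.call(rbind, rows)
  ok <- records$status == "ok"
  summary <- if (sum(ok) >= 3) {
    cohort_summary(records[ok, , drop = FALSE],
                   group_split_tucr = config$stats$tucr_split,
                   alpha = config$stats$alpha)
  } else NULL
  meta <- list(package_version = as.character(packageVersion("cupcoverage")),
               config_hash = config_hash(config),
               n_hips = length(hips), n_failed = sum(!ok))
  out <- structure(list(records = records, summary = summary,
                        details = details, meta = meta,
                        n_failed = sum(!ok)),
                   class = "cc_run")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    rec <- records
    rec$package_version <- meta$package_version
    rec$config_hash <- meta$config_hash
    write.csv(rec, file.path(output_dir, "per_hip.csv"), row.names = FALSE)
    if (!is.null(summary)) {
      vs <- summary$variables
      vs$package_version <- meta$package_version
      vs$config_hash <- meta$config_hash
      write.csv(vs, file.path(output_dir, "summary_variables.csv"),
                row.names = FALSE)
      cs <- summary$correlations
      cs$package_version <- meta$package_version
      cs$config_hash <- meta$config_hash
      write.csv(cs, file.path(output_dir, "summary_correlations.csv"),
                row.names = FALSE)
    }
  }
  out
}

#' Generate a synthetic cohort, optionally write its files, and analyse it
#'
#' Wraps [generate_cohort()] and [run_pipeline()].  When `output_dir` is
#' given, each hip's bone STL, landmarks JSON and ground-truth CSV are
#' written together with a YAML manifest listing files and seeds.
#'
#' @param cohort A [cohort_params()] object.
#' @param config Pipeline config.
#' @param output_dir Optional output directory.
#' @return The [run_pipeline()] result, with `hips` (the generated cohort)
#'   and `ground_truth` (data frame) attached.
#' @export
simulate_cohort <- function(cohort = cohort_params(),
                            config = default_config(),
                            output_dir = NULL) {
  hips <- generate_cohort(cohort)
  gt <- do.call(rbind, lapply(seq_along(hips), function(i) {
    g <- hips[[i]]$ground_truth
    data.frame(hip_id = sprintf("hip_%03d", i),
               gt_tucr = g$tucr, gt_asucr = g$asucr, gt_aiucr = g$aiucr,
               gt_psucr = g$psucr, gt_piucr = g$piucr,
               gt_height_mm = g$height_mm,
               gt_ap_diameter_mm = g$ap_diameter_mm,
               seed = hips[[i]]$params$seed)
  }))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(n_hips = length(hips),
                     master_seed = cohort$master_seed, hips = list())
    for (i in seq_along(hips)) {
      id <- sprintf("hip_%03d", i)
      stl <- file.path(output_dir, paste0(id, ".stl"))
      js <- file.path(output_dir, paste0(id, "_landmarks.json"))
      write_stl(hips[[i]]$bone, stl)
      write_landmarks_json(hips[[i]]$landmarks, js)
      manifest$hips[[i]] <- list(hip_id = id, bone_stl = basename(stl),
                                 landmarks_json = basename(js),
                                 seed = hips[[i]]$params$seed)
    }
    write.csv(gt, file.path(output_dir, "ground_truth.csv"),
              row.names = FALSE)
    yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
  }
  run <- run_pipeline(hips, config = config, output_dir = output_dir)
  run$hips <- hips
  run$ground_truth <- gt
  run
}
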