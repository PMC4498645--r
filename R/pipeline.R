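#' Build a study configuration
#'
#' Collects everything a reproducible run needs: the seed, the group
#' definitions, geometry and segmentation settings, the exclusion-rule
#' settings, and the reference group for relative-area reporting.
#'
#' @param groups List of [group_params()] objects (at least one).
#' @param eyes_per_group Eyes simulated per group.
#' @param seed Integer study seed; drives truth sampling and image noise.
#' @param geometry An [layout_burn_sites()] geometry shared by all eyes.
#' @param segmentation A [segmentation_params()] list.
#' @param render A [render_params()] list.
#' @param outlier_factor Outlier multiplier (> 1).
#' @param outlier_scope `"eye"` or `"condition"`.
#' @param ttest `"welch"` or `"pooled"` two-group test variant.
#' @param reference Label of the reference group; defaults to the first.
#' @param ffa Render and score fundus angiography pairs?
#' @param write_images Write the rendered TIFFs to the run directory?
#'   (Disable to save I/O when only the tables matter.)
#' @return A list of class `study_config`.
#' @export
study_config <- function(groups, eyes_per_group = 10L, seed = 1L,
                         geometry = layout_burn_sites(),
                         segmentation = segmentation_params(
                           pixel_scale = geometry$pixel_scale),
                         render = render_params(),
                         outlier_factor = 5, outlier_scope = "eye",
                         ttest = c("welch", "pooled"),
                         reference = NULL, ffa = TRUE,
                         write_images = TRUE) {
  ttest <- match.arg(ttest)
  errs <- character(0)
  if (!length(groups) || !all(vapply(groups, inherits, logical(1),
                                     "group_params"))) {
    errs <- c(errs, "groups must be a non-empty list of group_params objects")
  } else {
    labels <- vapply(groups, `[[`, character(1), "label")
    if (anyDuplicated(labels)) errs <- c(errs, "group labels must be unique")
    if (is.null(reference)) reference <- labels[1]
    if (!reference %in% labels) {
      errs <- c(errs, paste0("reference group '", reference, "' is not defined"))
    }
  }
  if (outlier_factor <= 1) errs <- c(errs, "outlier_factor must be > 1")
  if (!outlier_scope %in% c("eye", "condition")) {
    errs <- c(errs, "outlier_scope must be 'eye' or 'condition'")
  }
  if (eyes_per_group < 1) errs <- c(errs, "eyes_per_group must be >= 1")
  if (length(errs)) {
    abort_input("invalid study configuration:\n  - ",
                paste(errs, collapse = "\n  - "))
  }
  structure(list(groups = groups, eyes_per_group = as.integer(eyes_per_group),
                 seed = as.integer(seed), geometry = geometry,
                 segmentation = segmentation, render = render,
                 outlier_factor = outlier_factor,
                 outlier_scope = outlier_scope, ttest = ttest,
                 reference = reference, ffa = isTRUE(ffa),
                 write_images = isTRUE(write_images)),
            class = "study_config")
}

#' Validate a YAML study configuration file
#'
#' Parses the file, reports all validation problems together, and returns
#' a complete [study_config()] with defaults filled in.
#'
#' @param path Path to a YAML file with optional top-level keys `seed`,
#'   `eyes_per_group`, `outlier_factor`, `outlier_scope`, `ttest`,
#'   `reference`, `ffa`, `write_images`, mapping blocks `geometry`,
#'   `segmentation`, `render`, and a required `groups` list whose entries
#'   hold [group_params()] fields.
#' @return A validated `study_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) abort_input("config file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) abort_input("cannot parse config: ",
                                                  conditionMessage(e)))
  errs <- character(0)
  groups <- list()
  if (is.null(raw$groups) || !length(raw$groups)) {
    errs <- c(errs, "no groups defined")
  } else {
    for (i in seq_along(raw$groups)) {
      g <- raw$groups[[i]]
      res <- tryCatch(do.call(group_params, g), error = function(e) e)
      if (inherits(res, "error")) {
        errs <- c(errs, paste0("group ", i, ": ", conditionMessage(res)))
      } else {
        groups[[length(groups) + 1L]] <- res
      }
    }
  }
  geometry <- tryCatch(do.call(layout_burn_sites, as.list(raw$geometry)),
                       error = function(e) {
                         errs <<- c(errs, paste0("geometry: ",
                                                 conditionMessage(e)))
                         NULL
                       })
  seg_args <- as.list(raw$segmentation)
  if (is.null(seg_args$pixel_scale) && !is.null(geometry)) {
    seg_args$pixel_scale <- geometry$pixel_scale
  }
  segmentation <- tryCatch(do.call(segmentation_params, seg_args),
                           error = function(e) {
                             errs <<- c(errs, paste0("segmentation: ",
                                                     conditionMessage(e)))
                             NULL
                           })
  render <- tryCatch(do.call(render_params, as.list(raw$render)),
                     error = function(e) {
                       errs <<- c(errs, paste0("render: ",
                                               conditionMessage(e)))
                       NULL
                     })
  if (length(errs)) {
    abort_input("invalid study configuration:\n  - ",
                paste(errs, collapse = "\n  - "))
  }
  cfg <- study_config(
    groups = groups,
    eyes_per_group = raw$eyes_per_group %||% 10L,
    seed = raw$seed %||% 1L,
    geometry = geometry, segmentation = segmentation, render = render,
    outlier_factor = raw$outlier_factor %||% 5,
    outlier_scope = raw$outlier_scope %||% "eye",
    ttest = raw$ttest %||% "welch",
    reference = raw$reference,
    ffa = raw$ffa %||% TRUE,
    write_images = raw$write_images %||% TRUE
  )
  attr(cfg, "config_md5") <- unname(tools::md5sum(path))
  cfg
}

# Reconstruct the per-shot outcome table for one eye from the segmentation
# and detection results: every burn site becomes one row whether or not a
# lesion developed there.
shots_from_measurements <- function(measurements, bleeds, damage, eye_id) {
  claims <- attr(measurements, "claims")
  rows <- lapply(0:3, function(s) {
    comp <- if (!is.null(claims) && ncol(claims) &&
                nrow(measurements)) which(claims[s + 1L, ]) else integer(0)
    comp <- comp[comp %in% measurements$lesion_id]
    axis <- if (nrow(bleeds)) max(c(0, bleeds$major_axis_um[bleeds$site == s]))
            else 0
    if (!length(comp)) {
      data.frame(eye_id = eye_id, site = s, lesion_id = NA_integer_,
                 area_um2 = 0, eq_diameter_um = 0, grade = 0L,
                 no_rupture = TRUE, choroidal_damage = damage[s + 1L],
                 fused = FALSE, bleed_major_axis_um = axis)
    } else {
      m <- measurements[measurements$lesion_id == comp[1L], ]
      data.frame(eye_id = eye_id, site = s, lesion_id = m$lesion_id,
                 area_um2 = m$area_um2, eq_diameter_um = m$eq_diameter_um,
                 grade = grade_hemorrhage(m$eq_diameter_um, axis),
                 no_rupture = FALSE, choroidal_damage = damage[s + 1L],
                 fused = m$fused, bleed_major_axis_um = axis)
    }
  })
  do.call(rbind, rows)
}

#' Run the full synthetic study pipeline
#'
#' Executes generate, segment, grade/exclude, leakage and stats stages for
#' every group and eye in the configuration, writing all intermediate
#' artifacts and a final report under `out_dir`. Reruns with the same
#' configuration and seed reproduce identical outputs; a `manifest.json`
#' records the seed, configuration hash and stage bookkeeping.
#'
#' @param config A [study_config()] (or a YAML path, passed through
#'   [validate_config()]).
#' @param out_dir Run directory; created if missing.
#' @param quiet Suppress per-stage progress messages?
#' @return Invisibly, a list with `truths`, `measurements`, `shots`
#'   (graded per-shot table), `tally`, `summaries`, `comparisons`,
#'   `leakage`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(out_dir, "images")
  if (config$write_images) dir.create(img_dir, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[lasercnv] ", ...)

  all_truths <- list(); all_meas <- list(); all_shots <- list()
  all_leak <- list()
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", label, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  global_eye <- 0L
  for (gi in seq_along(config$groups)) {
    group <- config$groups[[gi]]
    say("group ", group$label, ": generating ", config$eyes_per_group, " eyes")
    group_seed <- eye_seed(config$seed, gi * 100003L) # distinct substream per group
    truths <- stage("generate",
                    sample_lesion_truths(group, config$eyes_per_group,
                                         seed = group_seed))
    truths$group <- group$label
    all_truths[[group$label]] <- truths

    group_shots <- list()
    for (eye in unique(truths$eye_id)) {
      global_eye <- global_eye + 1L
      te <- truths[truths$eye_id == eye, , drop = FALSE]
      set.seed(eye_seed(config$seed + 104729L, global_eye)) # render substream
      fm <- stage("render", render_flatmount(te, config$geometry,
                                             config$render))
      if (config$write_images) {
        write_gray(fm$fluor, file.path(img_dir, paste0(eye, "_fluor.tif")),
                   bits = config$render$bits)
        write_gray(fm$bright, file.path(img_dir, paste0(eye, "_bright.tif")),
                   bits = config$render$bits)
      }

      seg <- stage("segment", segment_lesions(fm$fluor, config$segmentation))
      meas <- stage("segment", assign_to_sites(seg$measurements, seg$labels,
                                               config$geometry))
      bleeds <- stage("segment", detect_bleeding(fm$bright,
                                                 config$segmentation,
                                                 config$geometry))
      damage <- stage("segment", detect_choroidal_damage(fm$bright, fm$fluor,
                                                         config$segmentation,
                                                         config$geometry))
      shots <- stage("qc", shots_from_measurements(meas, bleeds, damage, eye))
      shots$group <- group$label
      meas$eye_id <- eye
      meas$group <- group$label
      all_meas[[eye]] <- as.data.frame(meas)
      group_shots[[eye]] <- shots

      if (config$ffa && max(seg$labels) > 0) {
        ffa <- stage("leakage", render_ffa_pair(te, config$geometry,
                                                config$render))
        if (config$write_images) {
          write_gray(ffa$ffa_5min, file.path(img_dir, paste0(eye, "_ffa5.tif")),
                     bits = config$render$bits)
          write_gray(ffa$ffa_10min, file.path(img_dir, paste0(eye, "_ffa10.tif")),
                     bits = config$render$bits)
        }
        lk <- stage("leakage", measure_leakage(ffa$ffa_5min, ffa$ffa_10min,
                                               seg$labels))
        lk <- cbind(eye_id = eye, lk, group = group$label)
        all_leak[[eye]] <- lk
      }
    }

    # exclusion pass: with condition scope the outlier mean pools the
    # structurally eligible lesions of the whole group
    pool <- NULL
    if (config$outlier_scope == "condition") {
      raw <- do.call(rbind, group_shots)
      g2_eyes <- unique(raw$eye_id[raw$grade == 2L & !raw$no_rupture])
      elig <- !raw$no_rupture & !raw$choroidal_damage & !raw$fused &
        raw$grade == 0L & !(raw$eye_id %in% g2_eyes)
      pool <- raw$area_um2[elig]
    }
    for (eye in names(group_shots)) {
      group_shots[[eye]] <- stage("qc", apply_exclusions(
        group_shots[[eye]], config$outlier_factor, config$outlier_scope,
        condition_areas = pool))
      all_shots[[eye]] <- group_shots[[eye]]
    }
  }

  truths <- do.call(rbind, all_truths); rownames(truths) <- NULL
  measurements <- do.call(rbind, all_meas); rownames(measurements) <- NULL
  shots <- do.call(rbind, all_shots); rownames(shots) <- NULL
  leakage <- if (length(all_leak)) do.call(rbind, all_leak) else NULL
  if (!is.null(leakage)) rownames(leakage) <- NULL

  say("tallying outcomes and summarizing groups")
  tally <- stage("stats", tally_lesion_types(shots))
  included <- shots[shots$included, , drop = FALSE]
  labels <- vapply(config$groups, `[[`, character(1), "label")
  summaries <- do.call(rbind, lapply(labels, function(l) {
    summarize_group(included$area_um2[included$group == l], l)
  }))
  comparisons <- NULL
  if (length(labels) == 2L) {
    comparisons <- stage("stats", compare_two(
      included$area_um2[included$group == labels[1]],
      included$area_um2[included$group == labels[2]],
      labels = labels, var_equal = config$ttest == "pooled"))
  } else if (length(labels) >= 3L) {
    comparisons <- stage("stats", compare_many(
      split(included$area_um2, included$group)[labels]))
  }

  say("writing artifacts to ", out_dir)
  write_truth(truths, file.path(out_dir, "truth.csv"), config$geometry)
  utils::write.csv(measurements, file.path(out_dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(shots, file.path(out_dir, "graded_lesions.csv"),
                   row.names = FALSE)
  build_report(tally, summaries, comparisons, leakage, out_dir,
               reference = config$reference)

  manifest <- list(
    seed = config$seed,
    config_md5 = attr(config, "config_md5") %||% NA,
    package_version = as.character(utils::packageVersion("lasercnv")),
    n_groups = length(config$groups), n_eyes = global_eye,
    n_shots = nrow(shots), n_lesions_measured = nrow(measurements),
    n_included = sum(shots$included)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(truths = truths, measurements = measurements,
                 shots = shots, tally = tally, summaries = summaries,
                 comparisons = comparisons, leakage = leakage,
                 manifest = manifest))
}
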