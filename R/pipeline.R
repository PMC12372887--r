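#' Validate a pipeline run configuration
#'
#' Reads a YAML configuration and checks every stage before any computation:
#' referenced files must exist, seeds must be explicit for stochastic
#' stages, and thresholds must be orderable. Problems are aggregated into a
#' single error rather than failing on the first.
#'
#' A configuration has an optional `output_dir` and any of the stage blocks
#' `panel` (file, compound, optional compound_b and cutoffs), `conservation`
#' (msa_inhibited, msa_noninhibited, reference_id, first_residue_number,
#' seed, optional n_bootstrap and min_delta), `geometry` (structure, optional
#' chain and anchor overrides), and `fits` (list of file + model entries).
#'
#' @param path Path to a YAML file.
#' @return The validated configuration (class `run_config`).
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  errs <- character(0)
  need_file <- function(p, what) {
    if (is.null(p)) errs <<- c(errs, paste0(what, " is not set"))
    else if (!file.exists(p)) errs <<- c(errs, paste0(what, " not found: ", p))
  }
  if (!is.null(cfg$panel)) {
    need_file(cfg$panel$file, "panel.file")
    if (is.null(cfg$panel$compound)) {
      errs <- c(errs, "panel.compound is not set")
    }
    ic <- cfg$panel$inhibited_cutoff %||% 50
    nc <- cfg$panel$noninhibited_cutoff %||% 99
    if (!(ic < nc)) {
      errs <- c(errs, "panel cutoffs must satisfy inhibited < noninhibited")
    }
  }
  if (!is.null(cfg$conservation)) {
    need_file(cfg$conservation$msa_inhibited, "conservation.msa_inhibited")
    need_file(cfg$conservation$msa_noninhibited,
              "conservation.msa_noninhibited")
    if (is.null(cfg$conservation$reference_id)) {
      errs <- c(errs, "conservation.reference_id is not set")
    }
    if (is.null(cfg$conservation$first_residue_number)) {
      errs <- c(errs, "conservation.first_residue_number is not set")
    }
    if (is.null(cfg$conservation$seed)) {
      errs <- c(errs, "conservation.seed is not set (stochastic stage)")
    }
  }
  if (!is.null(cfg$geometry)) {
    need_file(cfg$geometry$structure, "geometry.structure")
  }
  for (i in seq_along(cfg$fits)) {
    need_file(cfg$fits[[i]]$file, paste0("fits[", i, "].file"))
    m <- cfg$fits[[i]]$model
    if (is.null(m) || !m %in% c("total-binding", "dose-response")) {
      errs <- c(errs, paste0("fits[", i,
                             "].model must be total-binding or dose-response"))
    }
  }
  if (length(errs) > 0) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  cfg$output_dir <- cfg$output_dir %||% "."
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Orchestrates the configured stages: panel classification (and overlap if
#' a second compound is given), conservation profiling of the two group
#' alignments plus the differential screen, structure geometry and
#' conformational classification, and curve fits. Stages are independent: a
#' failing stage is recorded in the report and the others still run.
#' Deterministic given the configuration (all seeds explicit); the report
#' embeds the thresholds, seeds, and method tags used.
#'
#' @param config A validated [validate_config()] result (or a path to a
#'   YAML file, which will be validated first).
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return The consolidated report (list, class `run_report`); also written
#'   as `report.json` plus per-stage TSVs under the configured
#'   `output_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, msg) {
    if (!quiet) message("[", stage, "] ", msg)
  }
  report <- list(package_version =
                   as.character(utils::packageVersion("kinconform")),
                 stages = list(), errors = list())
  run_stage <- function(name, fun) {
    out <- tryCatch(fun(), error = function(e) {
      say(name, paste("FAILED:", conditionMessage(e)))
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(out)) report$stages[[name]] <<- out
  }

  if (!is.null(config$panel)) run_stage("panel", function() {
    p <- config$panel
    say("panel", paste("reading", p$file))
    tab <- read_panel_table(p$file,
                            kinase_col = p$kinase_col %||% "kinase_id",
                            compound_col = p$compound_col %||% "compound_id",
                            activity_col = p$activity_col %||%
                              "remaining_activity",
                            sep = p$sep %||% ",")
    g <- classify_groups(tab, p$compound,
                         inhibited_cutoff = p$inhibited_cutoff %||% 50,
                         noninhibited_cutoff = p$noninhibited_cutoff %||% 99)
    groups_to_json(g, file.path(config$output_dir, "panel_groups.json"))
    out <- list(groups = unclass(g))
    if (!is.null(p$compound_b)) {
      gb <- classify_groups(tab, p$compound_b,
                            inhibited_cutoff = p$inhibited_cutoff %||% 50,
                            noninhibited_cutoff = p$noninhibited_cutoff
                              %||% 99)
      ov <- overlap_groups(g, gb)
      out$overlap <- ov
    }
    out
  })

  if (!is.null(config$conservation)) run_stage("conservation", function() {
    cc <- config$conservation
    say("conservation", "profiling the two group alignments")
    prof <- function(f, tag) {
      conservation_profile(read_msa(f), cc$reference_id,
                           cc$first_residue_number, seed = cc$seed,
                           n_bootstrap = cc$n_bootstrap %||% 200,
                           msa_id = tag)
    }
    p_in <- prof(cc$msa_inhibited, "inhibited")
    p_non <- prof(cc$msa_noninhibited, "noninhibited")
    write_profile(p_in, file.path(config$output_dir,
                                  "profile_inhibited.tsv"))
    write_profile(p_non, file.path(config$output_dir,
                                   "profile_noninhibited.tsv"))
    d <- grade_delta(p_in, p_non, min_delta = cc$min_delta %||% 3,
                     omit_low_confidence = !isTRUE(cc$keep_low_confidence))
    d <- assign_regions(d)
    write_deltas(d, file.path(config$output_dir, "differential.tsv"))
    list(method_tag = attr(p_in, "method_tag"), seed = cc$seed,
         n_differential = nrow(d), differential = d)
  })

  if (!is.null(config$geometry)) run_stage("geometry", function() {
    gg <- config$geometry
    say("geometry", paste("reading", gg$structure))
    model <- read_structure(gg$structure)
    anchors <- do.call(kinase_anchors, gg$anchors %||% list())
    if (!is.null(gg$chain)) anchors$chain_id <- gg$chain
    call <- classify_conformation(model, anchors)
    js <- jsonlite::toJSON(list(
      structure_id = call$geometry$structure_id,
      spatial_label = call$spatial_label, alphaC_label = call$alphaC_label,
      dihedral_cluster = call$dihedral_cluster,
      d1 = call$d1, d2 = call$d2,
      lys_glu_distance = call$lys_glu_distance,
      thresholds_used = call$thresholds_used),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(js, file.path(config$output_dir, "conformation.json"))
    call
  })

  for (i in seq_along(config$fits)) {
    local({
      k <- i
      run_stage(paste0("fit", k), function() {
        ff <- config$fits[[k]]
        say(paste0("fit", k), paste(ff$model, "fit of", ff$file))
        curve <- read_curve(ff$file)
        fit <- if (ff$model == "total-binding") fit_total_binding(curve)
               else fit_dose_response(curve)
        fit_to_json(fit, file.path(config$output_dir,
                                   paste0("fit", k, ".json")))
        list(model = fit$model, estimate = as.list(fit$estimate),
             std_error = as.list(fit$std_error), rss = fit$rss,
             converged = fit$converged)
      })
    })
  }

  js <- jsonlite::toJSON(serialize_report(report), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  writeLines(js, file.path(config$output_dir, "report.json"))
  class(report) <- "run_report"
  if (length(report$errors) > 0) {
    warning("stage(s) failed: ", paste(names(report$errors),
                                       collapse = ", "))
  }
  report
}

# strip heavy embedded objects before serializing
serialize_report <- function(report) {
  st <- report$stages
  if (!is.null(st$geometry)) {
    g <- st$geometry
    st$geometry <- list(spatial_label = g$spatial_label,
                        alphaC_label = g$alphaC_label,
                        dihedral_cluster = g$dihedral_cluster,
                        d1 = g$d1, d2 = g$d2,
                        lys_glu_distance = g$lys_glu_distance,
                        thresholds_used = g$thresholds_used)
  }
  list(package_version = report$package_version, stages = st,
       errors = report$errors)
}
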