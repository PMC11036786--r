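#' Assemble a pipeline configuration
#'
#' Collects paths, thresholds and seeds for \code{\link{run_pipeline}}.
#' Every tunable is echoed into the run's provenance file; nothing is
#' defaulted silently at run time.
#'
#' @param volume_dir directory containing one NIfTI per subject, named
#'   \code{<id>.nii} or \code{<id>.nii.gz} for the ids in the covariate
#'   table. Alternatively \code{volumes} may give explicit paths.
#' @param atlas_path,atlas_table_path atlas NIfTI and region TSV
#'   (table optional).
#' @param covariates_path subject covariate table.
#' @param output_dir directory for all outputs (created if absent).
#' @param volumes optional named character vector of per-subject paths
#'   (names = subject ids), overriding \code{volume_dir}.
#' @param mask_threshold grey-matter mask rule: density strictly above
#'   this value (default 0).
#' @param regional_alpha right-tailed alpha for flagging dissimilar
#'   regions (default 0.05).
#' @param screen_p inter-regional screen threshold (default 1e-12; scale
#'   to cohort size).
#' @param bonferroni_alpha base alpha for the randomness comparison
#'   (default 0.05, corrected over regions).
#' @param prescreen_p regression prescreen threshold (default 0.1).
#' @param n_surrogates surrogates per region for nonrandomness
#'   (default 10).
#' @param min_subjects smallest admissible case group for the regression
#'   stage (default 10).
#' @param seed master seed for all stochastic stages.
#' @param axis_convention axis semantics of the input grids.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(volume_dir = NULL, atlas_path,
                            atlas_table_path = NULL, covariates_path,
                            output_dir, volumes = NULL,
                            mask_threshold = 0,
                            regional_alpha = 0.05,
                            screen_p = 1e-12,
                            bonferroni_alpha = 0.05,
                            prescreen_p = 0.1,
                            n_surrogates = 10L,
                            min_subjects = 10L,
                            seed = 1L,
                            axis_convention = DEFAULT_AXES) {
  thr <- c(regional_alpha = regional_alpha, screen_p = screen_p,
           bonferroni_alpha = bonferroni_alpha, prescreen_p = prescreen_p)
  if (any(thr <= 0 | thr >= 1))
    stop("all thresholds must lie in (0, 1)", call. = FALSE)
  structure(list(volume_dir = volume_dir, volumes = volumes,
                 atlas_path = atlas_path,
                 atlas_table_path = atlas_table_path,
                 covariates_path = covariates_path,
                 output_dir = output_dir,
                 mask_threshold = mask_threshold,
                 regional_alpha = regional_alpha,
                 screen_p = screen_p,
                 bonferroni_alpha = bonferroni_alpha,
                 prescreen_p = prescreen_p,
                 n_surrogates = as.integer(n_surrogates),
                 min_subjects = as.integer(min_subjects),
                 seed = as.integer(seed),
                 axis_convention = axis_convention),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path config file; keys as in \code{\link{pipeline_config}}.
#' @return A \code{pipeline_config}.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop(sprintf("%s: unknown config keys: %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (!is.null(raw$axis_convention)) {
    ac <- unlist(raw$axis_convention)
    if (is.null(names(ac)) && length(ac) == 3L)
      names(ac) <- c("x", "y", "z")
    raw$axis_convention <- ac
  }
  if (!is.null(raw$volumes)) raw$volumes <- unlist(raw$volumes)
  do.call(pipeline_config, raw)
}

resolve_volume_paths <- function(config, ids) {
  if (!is.null(config$volumes)) {
    paths <- config$volumes[ids]
    if (anyNA(paths))
      stop(sprintf("no volume path for subjects: %s",
                   paste(ids[is.na(paths)], collapse = ", ")),
           call. = FALSE)
    return(paths)
  }
  paths <- vapply(ids, function(id) {
    cand <- file.path(config$volume_dir,
                      c(paste0(id, ".nii.gz"), paste0(id, ".nii")))
    hit <- cand[file.exists(cand)]
    if (length(hit) == 0L)
      stop(sprintf("volume for subject %s not found under %s",
                   id, config$volume_dir), call. = FALSE)
    hit[1L]
  }, character(1L))
  paths
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Encodes every subject's pattern map, builds per-subject inter-regional
#' similarity matrices, computes per-region nonrandomness profiles, runs
#' the group statistics (regional dissimilarity flags, inter-regional
#' screen, Bonferroni-corrected randomness comparison) and the cognition
#' regression on the case group, writing all tables, maps and a
#' provenance record under \code{config$output_dir}. Rerunning with the
#' same config reproduces every table exactly.
#'
#' @param config a \code{pipeline_config}, or the path of a YAML/JSON
#'   config file.
#' @param stages subset of stages to run (later stages require earlier
#'   ones in the same call).
#' @param verbose print per-stage progress (default TRUE).
#' @return An \code{ibs_pipeline} object (invisibly): the key results and
#'   output paths.
#' @export
run_pipeline <- function(config,
                         stages = c("encode", "similarity", "randomness",
                                    "compare", "regress"),
                         verbose = TRUE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  subjects <- tryCatch(read_covariates(config$covariates_path),
                       error = function(e)
                         stop(sprintf("[stage input] %s",
                                      conditionMessage(e)), call. = FALSE))
  atlas <- tryCatch(read_atlas(config$atlas_path,
                               config$atlas_table_path),
                    error = function(e)
                      stop(sprintf("[stage input] %s",
                                   conditionMessage(e)), call. = FALSE))
  ids <- subjects$id
  paths <- resolve_volume_paths(config, ids)
  res <- list(config = config, subjects = subjects, atlas = atlas)

  stage <- function(name, id, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s, subject %s] %s", name, id,
                   conditionMessage(e)), call. = FALSE))
  }

  # encode
  maps <- NULL
  if (any(c("encode", "similarity", "randomness", "compare",
            "regress") %in% stages)) {
    t0 <- Sys.time()
    map_dir <- file.path(out_dir, "pattern_maps")
    dir.create(map_dir, showWarnings = FALSE)
    vols <- list()
    maps <- list()
    for (i in seq_along(ids)) {
      id <- ids[i]
      v <- stage("encode", id, suppressMessages(
        read_volume(paths[i], axis_convention = config$axis_convention)))
      stage("encode", id, check_atlas_shape(atlas, dim(v)))
      m <- stage("encode", id,
                 compute_pattern_map(v,
                                     mask_threshold = config$mask_threshold))
      vols[[id]] <- v
      maps[[id]] <- m
      if ("encode" %in% stages)
        write_pattern_map(m, file.path(map_dir,
                                       paste0(id, "_pattern.nii.gz")),
                          axis_convention = config$axis_convention,
                          mask_rule = sprintf("density > %g",
                                              config$mask_threshold))
    }
    say("encode: %d subjects, %d retained voxels (first subject), %.1fs",
        length(ids), sum(!is.na(maps[[1L]])),
        as.numeric(Sys.time() - t0, units = "secs"))
  }

  is_case <- subjects$group == "case"
  sims <- NULL
  if (any(c("similarity", "compare") %in% stages)) {
    t0 <- Sys.time()
    sim_dir <- file.path(out_dir, "similarity")
    dir.create(sim_dir, showWarnings = FALSE)
    sims <- list()
    long_all <- list()
    for (id in ids) {
      sm <- stage("similarity", id,
                  interregional_matrix(maps[[id]], atlas,
                                       subject_id = id))
      sims[[id]] <- sm
      write_tsv(data.frame(region = rownames(sm),
                           round(unclass(sm), 10), check.names = FALSE),
                file.path(sim_dir, paste0(id, "_similarity.tsv")))
      lg <- similarity_long(sm)
      lg$subject <- id
      long_all[[id]] <- lg
    }
    write_tsv(do.call(rbind, long_all)[, c("subject", "region_i",
                                           "region_j", "distance")],
              file.path(out_dir, "similarity_long.tsv"))
    say("similarity: %d subjects x %d pairs, %.1fs", length(ids),
        sum(upper.tri(sims[[1L]])),
        as.numeric(Sys.time() - t0, units = "secs"))
  }

  profiles <- NULL
  if (any(c("randomness", "compare", "regress") %in% stages)) {
    t0 <- Sys.time()
    profiles <- list()
    for (id in ids) {
      profiles[[id]] <- stage("randomness", id,
        nonrandomness_profile(vols[[id]],
                              mask = unclass(vols[[id]]) > config$mask_threshold,
                              atlas = atlas,
                              n_surrogates = config$n_surrogates,
                              seed = config$seed, subject_id = id))
    }
    write_tsv(do.call(rbind, lapply(profiles, as.data.frame)),
              file.path(out_dir, "nonrandomness.tsv"))
    say("randomness: %d subjects x %d regions, %.1fs", length(ids),
        length(atlas$regions),
        as.numeric(Sys.time() - t0, units = "secs"))
  }

  if ("compare" %in% stages) {
    t0 <- Sys.time()
    stat_dir <- file.path(out_dir, "stats")
    dir.create(stat_dir, showWarnings = FALSE)
    regional_D <- group_dissimilarity_profile(maps[!is_case],
                                              maps[is_case], atlas)
    res$regional_dissimilarity <- regional_D
    res$regional_flags <- flag_dissimilar_regions(regional_D,
                                                  alpha = config$regional_alpha)
    write_tsv(as.data.frame(res$regional_flags),
              file.path(stat_dir, "regional_dissimilarity.tsv"))
    res$interregional_screen <- screen_interregional(sims[!is_case],
                                                     sims[is_case],
                                                     threshold_p = config$screen_p)
    write_tsv(as.data.frame(res$interregional_screen),
              file.path(stat_dir, "interregional_screen.tsv"))
    res$randomness_comparison <- compare_randomness(profiles[!is_case],
                                                    profiles[is_case],
                                                    alpha = config$bonferroni_alpha)
    write_tsv(as.data.frame(res$randomness_comparison),
              file.path(stat_dir, "randomness_comparison.tsv"))
    say("compare: %d regions flagged, %d pairs passing, %d randomness hits, %.1fs",
        sum(res$regional_flags$pass), sum(res$interregional_screen$pass),
        sum(res$randomness_comparison$pass),
        as.numeric(Sys.time() - t0, units = "secs"))
  }

  if ("regress" %in% stages) {
    t0 <- Sys.time()
    reg_dir <- file.path(out_dir, "regression")
    dir.create(reg_dir, showWarnings = FALSE)
    case_ids <- ids[is_case]
    idx <- t(vapply(case_ids, function(id) profiles[[id]]$index,
                    numeric(length(atlas$regions))))
    colnames(idx) <- as.character(atlas$regions)
    fit <- cognition_regression(idx,
                                subjects[is_case, , drop = FALSE],
                                prescreen_p = config$prescreen_p,
                                min_subjects = config$min_subjects)
    res$regression <- fit
    write_tsv(fit$coefficients,
              file.path(reg_dir, "regression_coefficients.tsv"))
    jsonlite::write_json(list(selected = fit$selected,
                              prescreen = fit$prescreen,
                              coefficients = fit$coefficients,
                              thresholds = fit$thresholds,
                              n = fit$n),
                         file.path(reg_dir, "regression_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("regress: %d prescreened, %d selected, %.1fs",
        sum(fit$prescreen$kept), length(fit$selected),
        as.numeric(Sys.time() - t0, units = "secs"))
  }

  provenance <- list(
    package = "ibsmorph",
    package_version = as.character(utils::packageVersion("ibsmorph")),
    config = config[setdiff(names(config), "volumes")],
    volumes = as.list(paths),
    stages = stages,
    n_subjects = length(ids),
    n_regions = length(atlas$regions))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  res$output_dir <- out_dir
  class(res) <- "ibs_pipeline"
  invisible(res)
}

#' @export
print.ibs_pipeline <- function(x, ...) {
  cat("<ibs_pipeline> ", length(x$subjects$id), " subjects, ",
      length(x$atlas$regions), " regions\n", sep = "")
  cat("  outputs: ", x$output_dir, "\n", sep = "")
  if (!is.null(x$regional_flags))
    cat("  dissimilar regions flagged: ",
        sum(x$regional_flags$pass), "\n", sep = "")
  if (!is.null(x$regression))
    cat("  regression selected: ",
        if (length(x$regression$selected) == 0L) "(none)"
        else paste(x$regression$selected, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk in pipeline input layout
#'
#' Materialises \code{\link{generate_cohort}} output as the files
#' \code{\link{run_pipeline}} consumes: one NIfTI per subject under
#' \code{dir/volumes}, the atlas and region table, and the covariate TSV.
#'
#' @param cohort result of \code{\link{generate_cohort}}.
#' @param dir output directory.
#' @return A ready \code{\link{pipeline_config}} pointing at the files
#'   (output_dir set to \code{dir/results}).
#' @export
write_cohort <- function(cohort, dir) {
  vol_dir <- file.path(dir, "volumes")
  dir.create(vol_dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$volumes))
    write_volume(cohort$volumes[[id]],
                 file.path(vol_dir, paste0(id, ".nii.gz")))
  atlas_path <- file.path(dir, "atlas.nii.gz")
  table_path <- file.path(dir, "regions.tsv")
  write_atlas(cohort$atlas, atlas_path, table_path)
  cov_path <- file.path(dir, "covariates.tsv")
  write_tsv(cohort$subjects, cov_path)
  pipeline_config(volume_dir = vol_dir, atlas_path = atlas_path,
                  atlas_table_path = table_path,
                  covariates_path = cov_path,
                  output_dir = file.path(dir, "results"),
                  seed = cohort$spec$seed,
                  n_surrogates = cohort$spec$n_surrogates)
}
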