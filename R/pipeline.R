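#' Pipeline configuration
#'
#' Bundles the per-stage parameters and named seeds of a full synthetic
#' run: simulate -> parameterize -> register -> features -> stats ->
#' classify. Every source of randomness is funnelled through a named seed
#' recorded in the run manifest.
#'
#' @param out_dir output directory for stage artifacts and the manifest.
#' @param cohort a [simulation_config()].
#' @param stages character vector of stages to execute (subset of the six,
#'   order fixed internally).
#' @param template `"designated_subject"` (first reference-group subject,
#'   the default) or `"external_mesh"`.
#' @param template_mesh path to a mesh file when
#'   `template = "external_mesh"`.
#' @param use_analytic_grids if `TRUE` (default) the parameterize stage
#'   reuses the generator's closed-form subject grids; if `FALSE` each
#'   subject mesh is re-parameterized with [conformal_parameterize()].
#' @param registration a [registration_params()].
#' @param stats list: `channels` (subset of RD/TBM/mTBM/MMS), `n_perm`,
#'   `alpha`.
#' @param classify list of [cross_validate()] settings
#'   (`n_patches`, `side`, `k`, `gamma`, `epochs`, `n_rounds`, `max_depth`,
#'   `k_folds`, `pooling`, `max_train_patches`, `encode_tol`) or `NULL` to
#'   skip configuring.
#' @param seeds named list of integer seeds (`simulate`, `patches`, `scc`,
#'   `folds`, `permutation`).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            cohort = simulation_config(),
                            stages = c("simulate", "parameterize", "register",
                                       "features", "stats", "classify"),
                            template = c("designated_subject", "external_mesh"),
                            template_mesh = NULL,
                            use_analytic_grids = TRUE,
                            registration = registration_params(levels = 2L,
                                                               max_iter = 60L),
                            stats = list(channels = c("RD", "MMS"),
                                         n_perm = 500L, alpha = 0.05),
                            classify = list(n_patches = 60L, side = 10L,
                                            k = 32L, gamma = 0.15,
                                            epochs = 1L, n_rounds = 30L,
                                            max_depth = 2L, k_folds = 10L,
                                            pooling = "patch_matrix",
                                            max_train_patches = 1500L,
                                            encode_tol = 1e-5),
                            seeds = list(simulate = 1L, patches = 2L,
                                         scc = 3L, folds = 4L,
                                         permutation = 5L)) {
  template <- match.arg(template)
  all_stages <- c("simulate", "parameterize", "register", "features",
                  "stats", "classify")
  bad <- setdiff(stages, all_stages)
  if (length(bad))
    stop_subshape("bad_config", sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  if (template == "external_mesh" &&
      (is.null(template_mesh) || !file.exists(template_mesh)))
    stop_subshape("bad_config", "template_mesh must exist for external_mesh policy")
  structure(list(out_dir = out_dir, cohort = cohort,
                 stages = all_stages[all_stages %in% stages],
                 template = template, template_mesh = template_mesh,
                 use_analytic_grids = use_analytic_grids,
                 registration = registration, stats = stats,
                 classify = classify, seeds = seeds),
            class = "pipeline_config")
}

object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

stage_deps <- c(simulate = "", parameterize = "simulate",
                register = "parameterize", features = "register",
                stats = "features", classify = "features")

#' Run the full pipeline
#'
#' Executes the enabled stages in order, each consuming the previous
#' stage's serialized output under `config$out_dir` and recording its file
#' hash, seed and wall time in the run manifest (`manifest.json`). A rerun
#' with the identical configuration reuses stage outputs whose hashes
#' match (stage-level resume); a config change is detected by hash and
#' refuses to reuse stale artifacts unless `force = TRUE`.
#'
#' @param config a [pipeline_config()].
#' @param force rerun all stages, overwriting existing artifacts.
#' @param quiet suppress progress messages.
#' @return the run manifest (list), invisibly classed `pipeline_manifest`.
#' @export
run_pipeline <- function(config, force = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  cfg_hash <- object_hash(config[setdiff(names(config), "out_dir")])
  old_manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else NULL
  if (!is.null(old_manifest) && !force &&
      !identical(old_manifest$config_hash, cfg_hash)) {
    stop_subshape("stale_run",
      "existing run was produced by a different configuration; use force = TRUE to overwrite")
  }

  # dependency check
  for (st in config$stages) {
    dep <- stage_deps[[st]]
    if (nzchar(dep) && !dep %in% config$stages) {
      dep_file <- file.path(config$out_dir, paste0(dep, ".rds"))
      if (!file.exists(dep_file))
        stop_subshape("missing_dependency",
          sprintf("stage '%s' requires the '%s' artifact (%s), which is neither scheduled nor on disk",
                  st, dep, dep_file))
    }
  }

  manifest <- list(config_hash = cfg_hash,
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("subshape")),
                   stages = list())
  state <- new.env(parent = emptyenv())

  load_artifact <- function(stage) {
    if (!is.null(state[[stage]])) return(state[[stage]])
    f <- file.path(config$out_dir, paste0(stage, ".rds"))
    if (!file.exists(f))
      stop_subshape("missing_dependency",
        sprintf("required artifact missing: %s", f))
    state[[stage]] <- readRDS(f)
    state[[stage]]
  }

  run_stage <- function(stage, fun, seed = NA_integer_) {
    f <- file.path(config$out_dir, paste0(stage, ".rds"))
    t0 <- Sys.time()
    prev <- if (!is.null(old_manifest)) old_manifest$stages[[stage]] else NULL
    if (!force && !is.null(prev) && file.exists(f) &&
        identical(unname(tools::md5sum(f)), prev$md5)) {
      if (!quiet) message(sprintf("[%s] reused (%s)", stage, prev$md5))
      state[[stage]] <- readRDS(f)
    } else {
      if (!quiet) message(sprintf("[%s] running ...", stage))
      state[[stage]] <- fun()
      saveRDS(state[[stage]], f, version = 2)
    }
    manifest$stages[[stage]] <<- list(
      file = basename(f), md5 = unname(tools::md5sum(f)),
      seed = seed, seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
  }

  for (stage in config$stages) {
    switch(stage,
      simulate = run_stage("simulate", function() {
        simulate_cohort(config$cohort, meshes = !config$use_analytic_grids)
      }, seed = config$cohort$seed),
      parameterize = run_stage("parameterize", function() {
        cohort <- load_artifact("simulate")
        if (config$use_analytic_grids) {
          list(grids = cohort$grids, source = "analytic")
        } else {
          list(grids = lapply(cohort$meshes, conformal_parameterize,
                              dims = config$cohort$grid_dims),
               source = "conformal_parameterize")
        }
      }),
      register = run_stage("register", function() {
        cohort <- load_artifact("simulate")
        grids <- load_artifact("parameterize")$grids
        tpl_rep <- if (config$template == "designated_subject") {
          conformal_representation(grids[[which(cohort$labels == levels(cohort$labels)[1])[1]]])
        } else {
          conformal_representation(conformal_parameterize(
            read_mesh(config$template_mesh), dims = config$cohort$grid_dims))
        }
        defs <- lapply(grids, function(g) {
          fluid_register(conformal_representation(g), tpl_rep,
                         config$registration)
        })
        list(deformations = defs, template = config$template)
      }),
      features = run_stage("features", function() {
        grids <- load_artifact("parameterize")$grids
        defs <- load_artifact("register")$deformations
        mapply(vertex_features, grids, defs, SIMPLIFY = FALSE)
      }),
      stats = run_stage("stats", function() {
        cohort <- load_artifact("simulate")
        feats <- load_artifact("features")
        out <- list()
        for (chn in config$stats$channels) {
          arr <- stack_features(feats, chn)
          smap <- permutation_test(arr, cohort$labels,
                                   n_perm = config$stats$n_perm,
                                   alpha = config$stats$alpha,
                                   seed = config$seeds$permutation)
          entry <- list(structure = config$cohort$structure_kind,
                        measure = chn,
                        comparison = paste(levels(cohort$labels)[1:2], collapse = "-"),
                        map = smap)
          if (chn %in% c("RD", "TBM")) {
            entry$direction <- direction_map(arr, cohort$labels, smap)
          }
          out[[chn]] <- entry
        }
        out
      }, seed = config$seeds$permutation),
      classify = run_stage("classify", function() {
        cohort <- load_artifact("simulate")
        feats <- load_artifact("features")
        mmsl <- lapply(feats, `[[`, "MMS")
        cc <- config$classify
        layout <- generate_patches(config$cohort$grid_dims,
                                   n_patches = cc$n_patches, side = cc$side,
                                   seed = config$seeds$patches)
        cross_validate(mmsl, cohort$labels, layout, k = cc$k,
                       gamma = cc$gamma, epochs = cc$epochs,
                       n_rounds = cc$n_rounds, max_depth = cc$max_depth,
                       k_folds = cc$k_folds, seed = config$seeds$folds,
                       pooling = cc$pooling %||% "patch_matrix",
                       max_train_patches = cc$max_train_patches %||% Inf,
                       encode_tol = cc$encode_tol %||% 1e-6)
      }, seed = config$seeds$folds))
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(structure(manifest, class = "pipeline_manifest"))
}

#' Comparison summary report
#'
#' Builds the global-p and classification summary tables of one or more
#' comparisons: per structure x measure x comparison the corrected global
#' p (entries below the significance level flagged), and per structure x
#' task the five cross-validation metrics. Written as JSON plus a markdown
#' table when `path` is given; the classification section is omitted when
#' no CV reports are supplied.
#'
#' @param stat_maps list of entries `list(structure, measure, comparison,
#'   map)` where `map` is a [permutation_test()] result (the `stats` stage
#'   artifact of [run_pipeline()] has this shape).
#' @param cv_reports optional named list of [cross_validate()] results
#'   (names used as task labels).
#' @param path optional output stem; writes `<path>.json` and `<path>.md`.
#' @param alpha significance flag threshold.
#' @return list with data.frames `global_p` and (possibly) `classification`.
#' @export
make_comparison_report <- function(stat_maps, cv_reports = NULL, path = NULL,
                                   alpha = 0.05) {
  if (!length(stat_maps))
    stop_subshape("bad_argument", "need at least one stat map")
  gp <- do.call(rbind, lapply(stat_maps, function(e) {
    data.frame(structure = e$structure, measure = e$measure,
               comparison = e$comparison, p_global = e$map$p_global,
               significant = e$map$p_global < alpha)
  }))
  rownames(gp) <- NULL
  out <- list(global_p = gp)
  if (length(cv_reports)) {
    cls <- do.call(rbind, lapply(seq_along(cv_reports), function(i) {
      m <- cv_reports[[i]]$mean_metrics
      data.frame(task = names(cv_reports)[i] %||% sprintf("task%d", i),
                 ACC = m["ACC"], SEN = m["SEN"], SPE = m["SPE"],
                 PPV = m["PPV"], NPV = m["NPV"], row.names = NULL)
    }))
    out$classification <- cls
  }
  if (!is.null(path)) {
    jsonlite::write_json(out, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    md <- c("# Comparison report", "", "## Global corrected p values", "",
            "| structure | measure | comparison | global p |",
            "|---|---|---|---|",
            apply(gp, 1, function(r) {
              pcell <- if (as.logical(r[["significant"]]))
                sprintf("**%s**", r[["p_global"]]) else r[["p_global"]]
              sprintf("| %s | %s | %s | %s |", r[["structure"]],
                      r[["measure"]], r[["comparison"]], pcell)
            }))
    if (!is.null(out$classification)) {
      md <- c(md, "", "## Classification performance", "",
              "| task | ACC | SEN | SPE | PPV | NPV |",
              "|---|---|---|---|---|---|",
              apply(out$classification, 1, function(r) {
                sprintf("| %s | %.4f | %.4f | %.4f | %.4f | %.4f |",
                        r[["task"]], as.numeric(r[["ACC"]]), as.numeric(r[["SEN"]]),
                        as.numeric(r[["SPE"]]), as.numeric(r[["PPV"]]),
                        as.numeric(r[["NPV"]]))
              }))
    }
    writeLines(md, paste0(path, ".md"))
  }
  out
}
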