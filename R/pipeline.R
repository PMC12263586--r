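#' Validate a pipeline run configuration
#'
#' Checks the schema before any stage runs: required top-level fields,
#' known stage names, and per-stage required fields (either given in the
#' config or produced by an earlier stage of the same run).
#'
#' @param config A configuration list, or the path to a YAML file.
#' @return The validated configuration list (invisibly normalized);
#'   violations raise a config error naming the offending field.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) {
    # keep bare "y"/"n" as strings so a `n:` (sample size) key survives
    # YAML 1.1 boolean resolution; true/false/yes/no stay logical
    config <- yaml::read_yaml(config, handlers = list(
      "bool#yes" = function(x) if (tolower(x) == "y") x else TRUE,
      "bool#no" = function(x) if (tolower(x) == "n") x else FALSE
    ))
  }
  for (f in c("run_id", "stages", "output_root")) {
    if (is.null(config[[f]])) {
      eq_abort(sprintf("config field `%s` is required.", f), "eq_config_error")
    }
  }
  config$master_seed <- config$master_seed %||% 1L
  known <- c("simulate", "quantify", "affinity", "stats")
  bad <- setdiff(config$stages, known)
  if (length(bad) > 0) {
    eq_abort(sprintf("unknown stage `%s`.", bad[1]), "eq_config_error")
  }
  if ("simulate" %in% config$stages && is.null(config$simulate$groups)) {
    eq_abort("config field `simulate.groups` is required.", "eq_config_error")
  }
  if ("quantify" %in% config$stages && !"simulate" %in% config$stages &&
      is.null(config$quantify$images_dir)) {
    eq_abort("config field `quantify.images_dir` is required when the simulate stage is not run.",
             "eq_config_error")
  }
  if ("stats" %in% config$stages && !"quantify" %in% config$stages &&
      is.null(config$stats$table)) {
    eq_abort("config field `stats.table` is required when the quantify stage is not run.",
             "eq_config_error")
  }
  if ("affinity" %in% config$stages) {
    for (f in c("fasta", "sites", "pbm_dir")) {
      if (is.null(config$affinity[[f]])) {
        eq_abort(sprintf("config field `affinity.%s` is required.", f),
                 "eq_config_error")
      }
    }
  }
  invisible(config)
}

md5_of <- function(paths) {
  unname(tools::md5sum(paths))
}

#' Run the simulate / quantify / affinity / stats pipeline
#'
#' Executes the requested stages in order under
#' `<output_root>/<run_id>/<stage>/` and writes an append-only
#' `manifest.json` at the run root recording the configuration digest, the
#' seeds, the package version and the MD5 checksum of every output file.
#' Rerunning an identical configuration reproduces identical output
#' checksums: every random choice derives from `master_seed`.
#'
#' @param config Configuration list or YAML path; see
#'   [validate_run_config()]. Stage blocks: `simulate` (groups with
#'   `label`, `n` and [sim_config()] fields), `quantify` (`mask`,
#'   optionally `images_dir`), `affinity` (`fasta`, `sites`, `pbm_dir`,
#'   `window_policy`), `stats` (`scheme`, optionally `table`, `figure`).
#' @return Invisibly, the run manifest (list).
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  run_dir <- file.path(config$output_root, config$run_id)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  stage_status <- list()
  activity <- NULL
  images_dir <- config$quantify$images_dir

  run_stage <- function(stage, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      stage_status[[stage]] <<- paste("failed:", conditionMessage(res))
      eq_abort(sprintf("stage `%s` failed: %s", stage, conditionMessage(res)),
               "eq_stage_error")
    }
    stage_status[[stage]] <<- "ok"
    res
  }

  if ("simulate" %in% config$stages) {
    run_stage("simulate", function() {
      sim_dir <- file.path(run_dir, "simulate")
      specs <- bind_rows(lapply(config$simulate$groups, function(g) {
        cfg_fields <- g[setdiff(names(g), c("label", "n"))]
        tibble(label = g$label, n = g$n, config = list(cfg_fields))
      }))
      cohort <- simulate_cohort(specs, seed = config$master_seed)
      walk(cohort$bundle, write_bundle, dir = sim_dir)
      purrr::walk2(cohort$truth, cohort$embryo_id, write_truth, dir = sim_dir)
      outputs <<- c(outputs, list.files(sim_dir, full.names = TRUE))
      images_dir <<- sim_dir
      invisible(NULL)
    })
  }

  if ("quantify" %in% config$stages) {
    run_stage("quantify", function() {
      q_dir <- file.path(run_dir, "quantify")
      dir.create(q_dir, showWarnings = FALSE)
      cohort <- read_cohort(images_dir)
      # truth tiffs also live in simulate dirs; read_cohort only picks
      # bundles with sidecar annotations, so exclude *_truth files
      mask <- config$quantify$mask %||% "posterior"
      activity <<- quantify_cohort(cohort, mask_choice = mask)
      csv <- file.path(q_dir, "activity.csv")
      write_activity_csv(activity, csv)
      outputs <<- c(outputs, csv)
      invisible(NULL)
    })
  }

  if ("affinity" %in% config$stages) {
    run_stage("affinity", function() {
      a_dir <- file.path(run_dir, "affinity")
      dir.create(a_dir, showWarnings = FALSE)
      seq <- read_query_fasta(config$affinity$fasta)
      sites <- read_sites(config$affinity$sites)
      pbm_files <- sort(list.files(config$affinity$pbm_dir,
                                   pattern = "\\.tsv$", full.names = TRUE))
      tables <- map(pbm_files, load_pbm_table)
      names(tables) <- map_chr(tables, function(t) attr(t, "factor_name"))
      am <- build_affinity_matrix(tables, seq, sites,
                                  window_policy = config$affinity$window_policy %||% "overlap6")
      mat_path <- file.path(a_dir, "affinity_matrix.tsv")
      readr::write_tsv(as_tibble(as.matrix(am), rownames = "factor"),
                       mat_path, progress = FALSE)
      prov_path <- file.path(a_dir, "provenance.json")
      jsonlite::write_json(tidy(am), prov_path, dataframe = "rows",
                           auto_unbox = TRUE, digits = NA, na = "null")
      outputs <<- c(outputs, mat_path, prov_path)
      if (isTRUE(config$affinity$figure)) {
        fig <- file.path(a_dir, "affinity_heatmap.png")
        render_heatmap(am, fig)
        outputs <<- c(outputs, fig)
      }
      invisible(NULL)
    })
  }

  if ("stats" %in% config$stages) {
    run_stage("stats", function() {
      s_dir <- file.path(run_dir, "stats")
      dir.create(s_dir, showWarnings = FALSE)
      tab <- if (!is.null(activity)) {
        activity
      } else {
        read_activity_csv(config$stats$table)
      }
      tab <- filter(tab, is.finite(.data$relative_activity))
      scheme <- config$stats$scheme %||% "methods"
      res <- compare_groups(tab, scheme = scheme)
      normality <- normality_screen(tab)
      flagged <- flag_outliers(tab)
      out <- list(
        test = glance(res),
        pairwise = res$pairwise,
        normality = normality,
        n_outliers = sum(flagged$.outlier, na.rm = TRUE)
      )
      js <- file.path(s_dir, "stats.json")
      jsonlite::write_json(out, js, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, na = "null")
      outputs <<- c(outputs, js)
      summary_prefix <- file.path(s_dir, "activity")
      if (isTRUE(config$stats$figure)) {
        rep <- swarm_report(tab, comparison = res, path_prefix = summary_prefix)
        outputs <<- c(outputs, paste0(summary_prefix, "_swarm.png"),
                      paste0(summary_prefix, "_summary.csv"))
      } else {
        rep <- swarm_summary_csv(tab, paste0(summary_prefix, "_summary.csv"))
        outputs <<- c(outputs, paste0(summary_prefix, "_summary.csv"))
      }
      invisible(NULL)
    })
  }

  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  manifest_entry <- list(
    run_id = config$run_id,
    package_version = as.character(utils::packageVersion("enhancerquant")),
    master_seed = config$master_seed,
    stages = config$stages,
    stage_status = stage_status,
    config_md5 = md5_of(cfg_file),
    outputs = lapply(sort(outputs), function(p) {
      rel <- sub(run_dir, "", p, fixed = TRUE)
      list(path = sub("^/", "", rel), md5 = md5_of(p))
    })
  )
  manifest_path <- file.path(run_dir, "manifest.json")
  history <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  } else {
    list()
  }
  history[[length(history) + 1]] <- manifest_entry
  jsonlite::write_json(history, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest_entry)
}

# group summary CSV without the figure
swarm_summary_csv <- function(tab, path) {
  summary <- map(unique(tab$group), function(g) {
    v <- tab$relative_activity[tab$group == g]
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    tibble(group = g, n = length(v), median = median(v),
           q1 = q[1], q3 = q[2], iqr = q[2] - q[1])
  }) %>% bind_rows()
  readr::write_csv(summary, path, progress = FALSE)
  invisible(summary)
}

#' Validate pipeline inputs without mutating them
#'
#' Reports (never fixes) issues: image channel dimension mismatches,
#' missing annotation sidecars or fields, and incomplete PBM tables (a
#' complete double-stranded 8-mer table has 65,536 entries after
#' reverse-complement expansion).
#'
#' @param images_dir Optional directory of bundle TIFF/JSON pairs.
#' @param pbm_dir Optional directory of PBM TSVs.
#' @return A tibble of issues (`severity`, `item`, `message`); zero rows
#'   when everything checks out.
#' @export
validate_inputs <- function(images_dir = NULL, pbm_dir = NULL) {
  issues <- list()
  note <- function(severity, item, message) {
    issues[[length(issues) + 1]] <<- tibble(severity = severity, item = item,
                                            message = message)
  }
  if (!is.null(images_dir)) {
    tifs <- sort(list.files(images_dir, pattern = "\\.tiff?$",
                            full.names = TRUE))
    tifs <- tifs[!grepl("_truth\\.tiff?$", tifs)]
    if (length(tifs) == 0) {
      note("error", images_dir, "no image bundles found")
    }
    for (tif in tifs) {
      js <- sub("\\.tiff?$", ".json", tif)
      if (!file.exists(js)) {
        note("error", basename(tif), "missing annotation sidecar")
        next
      }
      meta <- jsonlite::read_json(js, simplifyVector = TRUE)
      for (f in c("embryo_id", "group", "boundary_polyline", "limb_side_point")) {
        if (is.null(meta[[f]])) {
          note("error", basename(js), paste("annotation missing field", f))
        }
      }
      pages <- tiff::readTIFF(tif, all = TRUE)
      if (length(pages) != 3) {
        note("error", basename(tif),
             sprintf("expected 3 channel pages, found %d", length(pages)))
      } else {
        dims <- vapply(pages, function(p) paste(dim(p)[1:2], collapse = "x"),
                       character(1))
        if (length(unique(dims)) != 1) {
          note("error", basename(tif),
               paste("channel dimensions differ:", paste(dims, collapse = ", ")))
        }
      }
    }
  }
  if (!is.null(pbm_dir)) {
    for (f in sort(list.files(pbm_dir, pattern = "\\.tsv$", full.names = TRUE))) {
      tab <- tryCatch(load_pbm_table(f), error = function(e) e)
      if (inherits(tab, "error")) {
        note("error", basename(f), conditionMessage(tab))
      } else if (nrow(tab) != 65536) {
        note("warning", basename(f),
             sprintf("incomplete PBM table: %d of the expected 65,536 8mers",
                     nrow(tab)))
      }
    }
  }
  if (length(issues) == 0) {
    return(tibble(severity = character(0), item = character(0),
                  message = character(0)))
  }
  bind_rows(issues)
}
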