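# full-precision TSV writers: numerics rendered with 17 significant digits so
# reading the file back reproduces the doubles exactly
format_full <- function(x) {
  if (is.double(x)) {
    out <- formatC(x, digits = 17, format = "g")
    out[is.na(x)] <- "NA"
    trimws(out)
  } else {
    as.character(x)
  }
}

write_tsv_full <- function(df, path) {
  out <- as.data.frame(lapply(df, format_full), stringsAsFactors = FALSE,
    check.names = FALSE
  )
  names(out) <- names(df)
  write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
  )
  invisible(path)
}

# cairo's SVG writer numbers embedded resources with a process-global counter
# (source-<k>, surface<k>), so two otherwise identical plots differ in their
# ids; renumber them in order of first appearance to keep output byte-stable
sanitize_svg_ids <- function(path) {
  txt <- readLines(path, warn = FALSE)
  all <- paste(txt, collapse = "\n")
  stems <- c("source-" = "source-[0-9]+", "surface" = "surface[0-9]+")
  for (stem in names(stems)) {
    found <- unique(regmatches(all, gregexpr(stems[[stem]], all))[[1]])
    # replace longer ids first so "source-1" cannot clobber "source-12"
    found <- found[order(-nchar(found), found)]
    for (i in seq_along(found)) {
      all <- gsub(found[i], sprintf("%sid%d", stem, i), all, fixed = TRUE)
    }
  }
  writeLines(strsplit(all, "\n", fixed = TRUE)[[1]], path)
  invisible(path)
}

#' Generate a synthetic dataset and write it to disk
#'
#' Thin wrapper around [generate_faers()] and [write_faers()]: validates the
#' configuration, generates the dataset and writes the five quarterly tables
#' plus the ground-truth sidecar. Identical configurations produce
#' byte-identical files.
#'
#' @param config a [faers_sim_config()] object.
#' @param out_dir output directory.
#' @param quarter quarter suffix for the file names.
#' @return invisibly, the named vector of paths written.
#' @export
faers_simulate <- function(config, out_dir, quarter = "20Q1") {
  dataset <- generate_faers(config)
  write_faers(dataset, out_dir, quarter = quarter)
}

#' Run the full signal-detection pipeline and write a report bundle
#'
#' Reads a directory of FAERS-dialect tables (or takes a parsed bundle),
#' cleans and joins them into the analysis table, and writes:
#' the analysis summary with per-country event tallies and stage row counts
#' (`analysis_summary.json`), per-stratum signal tables
#' (`signals_<stratum>.tsv`), volcano coordinates and plots
#' (`volcano_<stratum>.tsv` / `.svg` / `.png`), the patient-information
#' report (`patient_info.tsv`) and age-incidence curve (`age_curve.tsv`),
#' per-stratum model reports (`model_<stratum>.tsv`, `model_<stratum>.json`)
#' and a run manifest with configuration, row counts at every filter stage
#' and md5 checksums of every written file (`manifest.json`). Running twice
#' on the same inputs produces byte-identical files.
#'
#' @param input a directory path or a parsed table bundle.
#' @param out_dir output directory (created if needed).
#' @param event_pt Preferred Term of interest (default `"Hiccups"`).
#' @param criteria optional named list of [candidate_criteria()] overriding
#'   the per-stratum defaults, e.g. `list(all = ..., male = ...)`.
#' @param strata character vector of strata to model.
#' @param horizon optional [Date] for [filter_temporal()].
#' @param render_plots write SVG/PNG volcano plots (default `TRUE`).
#' @param fit_models fit the per-stratum logistic models (default `TRUE`).
#' @return invisibly, the manifest list.
#' @export
faers_run <- function(input, out_dir, event_pt = "Hiccups", criteria = NULL,
                      strata = c("all", "male", "female"), horizon = NULL,
                      render_plots = TRUE, fit_models = TRUE) {
  bundle <- if (is.character(input)) read_faers_bundle(input) else input
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE
      )
    })
  }

  ing <- stage("ingest", ingest_faers(bundle, event_pt = event_pt, horizon = horizon))
  analysis <- ing$analysis
  strata_tables <- c(
    list(all = analysis),
    stratify_gender(analysis)[intersect(c("male", "female"), strata)]
  )
  strata_tables <- strata_tables[intersect(names(strata_tables), strata)]

  files <- character(0)
  add <- function(path) files <<- c(files, path)

  summary_out <- ing$summary
  summary_out$stages <- as.list(ing$stages)
  summary_out$dedup_removed <- as.list(ing$dedup_removed)
  summary_out$temporal <- ing$temporal
  path <- file.path(out_dir, "analysis_summary.json")
  jsonlite::write_json(summary_out, path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA, dataframe = "rows"
  )
  add(path)

  notes <- list()
  signal_tables <- list()
  for (nm in names(strata_tables)) {
    tbl <- strata_tables[[nm]]
    if (!nrow(tbl)) {
      notes[[nm]] <- "empty stratum: no rows after gender split"
      next
    }
    sig <- stage(paste0("signals/", nm), detect_signals(tbl, event_pt = event_pt))
    signal_tables[[nm]] <- sig
    add(write_tsv_full(sig, file.path(out_dir, sprintf("signals_%s.tsv", nm))))
    if (any(!sig$degenerate)) {
      coords <- volcano_coordinates(sig)
      add(write_tsv_full(coords, file.path(out_dir, sprintf("volcano_%s.tsv", nm))))
      if (render_plots) {
        plt <- volcano_plot(sig)
        svg_path <- file.path(out_dir, sprintf("volcano_%s.svg", nm))
        grDevices::svg(svg_path, width = 7, height = 5)
        print(plt)
        grDevices::dev.off()
        sanitize_svg_ids(svg_path)
        add(svg_path)
        png_path <- file.path(out_dir, sprintf("volcano_%s.png", nm))
        grDevices::png(png_path, width = 1400, height = 1000, res = 200,
          type = "cairo"
        )
        print(plt)
        grDevices::dev.off()
        add(png_path)
      }
    } else {
      notes[[nm]] <- "all RORs degenerate: no volcano plot"
    }
  }

  cases <- stage("patient statistics", case_table(analysis))
  gender_res <- gender_association(cases)
  patient_rows <- list()
  for (nm in names(strata_tables)) {
    sub <- switch(nm,
      all = cases,
      male = cases[cases$gender == "male", , drop = FALSE],
      female = cases[cases$gender == "female", , drop = FALSE]
    )
    if (!nrow(sub)) next
    for (v in c("age", "weight")) {
      cmp <- continuous_compare(sub, v)
      patient_rows[[paste(nm, v)]] <- tibble(
        panel = nm, variable = v, n_used = cmp$n_used,
        mean_event = cmp$mean_event, sem_event = cmp$sem_event,
        mean_non = cmp$mean_non, sem_non = cmp$sem_non,
        p_value = cmp$p_value
      )
    }
  }
  patient_tbl <- bind_rows(patient_rows)
  gender_row <- tibble(
    panel = "all", variable = "gender_male_event", n_used = sum(cases$gender != "unknown"),
    mean_event = gender_res$table$n11, sem_event = gender_res$table$n21,
    mean_non = gender_res$table$n12, sem_non = gender_res$table$n22,
    p_value = gender_res$p_value
  )
  add(write_tsv_full(
    bind_rows(gender_row, patient_tbl),
    file.path(out_dir, "patient_info.tsv")
  ))
  add(write_tsv_full(
    age_incidence_curve(cases), file.path(out_dir, "age_curve.tsv")
  ))

  model_aucs <- list()
  if (fit_models) {
    for (nm in names(strata_tables)) {
      res <- stage(paste0("model/", nm), tryCatch(
        run_stratum(analysis,
          stratum = nm,
          criteria = criteria[[nm]], event_pt = event_pt
        ),
        error = function(e) e
      ))
      if (inherits(res, "error")) {
        notes[[paste0("model_", nm)]] <- conditionMessage(res)
        next
      }
      add(write_tsv_full(
        res$report, file.path(out_dir, sprintf("model_%s.tsv", nm))
      ))
      meta <- list(
        stratum = nm,
        criteria = unclass(res$criteria),
        candidates = res$candidates$drug_name,
        auc = res$auc, n_used = res$n_used,
        converged = res$fit$converged, separated = res$fit$separated,
        log_likelihood = res$fit$log_likelihood,
        collinearity_flagged = if (!is.null(res$collinearity)) {
          nrow(res$collinearity$flagged)
        } else {
          0L
        }
      )
      mpath <- file.path(out_dir, sprintf("model_%s.json", nm))
      jsonlite::write_json(meta, mpath,
        auto_unbox = TRUE, pretty = TRUE, digits = NA
      )
      add(mpath)
      model_aucs[[nm]] <- res$auc
    }
  }

  manifest <- list(
    package = "faersignal",
    version = as.character(utils::packageVersion("faersignal")),
    event_pt = event_pt,
    strata = names(strata_tables),
    criteria = lapply(
      setNames(names(strata_tables), names(strata_tables)),
      function(nm) unclass(criteria[[nm]] %||% default_candidate_criteria(nm))
    ),
    stages = as.list(ing$stages),
    dedup_removed = as.list(ing$dedup_removed),
    temporal = ing$temporal,
    model_auc = model_aucs,
    notes = notes,
    gender_male_share_pct = gender_res$male_share_pct,
    files = as.list(setNames(
      unname(tools::md5sum(sort(files))), basename(sort(files))
    ))
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(manifest)
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads generator settings (`n_cases`, `seed`, `drugs`, `events`,
#' `planted_effects`, rates), the event Preferred Term and per-stratum
#' candidate thresholds from a single YAML document, returning a list ready
#' to pass to [faers_simulate()] and [faers_run()].
#'
#' @param path path to a YAML file.
#' @return a list with `generator` (a [faers_sim_config()] or `NULL`),
#'   `event_pt` and `criteria` (named list of [candidate_criteria()]).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  generator <- NULL
  if (!is.null(raw$generator)) {
    g <- raw$generator
    args <- list()
    for (nm in c(
      "n_cases", "male_fraction", "age_mean", "age_sd", "weight_mean",
      "weight_sd", "duplicate_rate", "partial_date_rate",
      "outside_window_rate", "seed"
    )) {
      if (!is.null(g[[nm]])) args[[nm]] <- g[[nm]]
    }
    if (!is.null(g$drugs)) args$drugs <- unlist(g$drugs)
    if (!is.null(g$events)) args$events <- unlist(g$events)
    if (!is.null(g$missingness)) args$missingness <- unlist(g$missingness)
    if (!is.null(g$planted_effects)) {
      args$planted_effects <- bind_rows(lapply(g$planted_effects, as_tibble))
    }
    generator <- do.call(faers_sim_config, args)
  }
  criteria <- NULL
  if (!is.null(raw$criteria)) {
    criteria <- lapply(raw$criteria, function(x) {
      candidate_criteria(x$min_reports, x$max_p, x$min_ror %||% 1)
    })
  }
  list(
    generator = generator,
    event_pt = raw$event_pt %||% "Hiccups",
    criteria = criteria
  )
}
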