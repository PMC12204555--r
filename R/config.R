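config_keys <- c("model", "members", "abundances", "scenario", "objective",
                 "pins", "grid", "coupling", "sources", "metabolite",
                 "fractions", "shared", "outdir", "seed", "log_level")

scenario_names <- c("fba", "xfba", "screen_sources", "scan_exchange",
                    "scan_abundance", "scan_oxygen")

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, rejects unknown keys, loads the model
#' file(s) immediately (so missing files and pins on nonexistent reactions
#' fail at load time, not mid-run), fills defaults and records a content
#' hash for provenance.
#'
#' @param path YAML file.
#' @return A `run_config` list with the loaded model(s) attached.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(raw$scenario) || !raw$scenario %in% scenario_names) {
    stop("config needs a scenario, one of: ",
         paste(scenario_names, collapse = ", "), call. = FALSE)
  }
  cfg <- raw
  cfg$outdir <- raw$outdir %||% "."
  cfg$seed <- raw$seed %||% 1L
  cfg$log_level <- raw$log_level %||% "info"
  cfg$pins <- unlist(raw$pins) %||% NULL
  cfg$hash <- rlang::hash(raw)

  community_scenarios <- c("xfba", "scan_exchange", "scan_abundance",
                           "scan_oxygen")
  if (cfg$scenario %in% community_scenarios) {
    if (is.null(raw$members) || is.null(raw$abundances)) {
      stop("scenario ", sQuote(cfg$scenario),
           " needs 'members' and 'abundances'", call. = FALSE)
    }
    models <- lapply(raw$members, function(p) {
      if (!file.exists(p)) stop("missing model file: ", p, call. = FALSE)
      read_model_table(p)
    })
    cfg$community <- build_community(models, unlist(raw$abundances),
                                     shared = raw$shared)
    if (!is.null(raw$coupling)) {
      cfg$coupling_spec <- do.call(coupling_spec, raw$coupling)
    }
    target <- cfg$community$model
  } else {
    if (is.null(raw$model)) {
      stop("scenario ", sQuote(cfg$scenario), " needs a 'model' path",
           call. = FALSE)
    }
    if (!file.exists(raw$model)) {
      stop("missing model file: ", raw$model, call. = FALSE)
    }
    cfg$loaded_model <- read_model_table(raw$model)
    target <- cfg$loaded_model
  }
  if (!is.null(cfg$pins)) {
    bad <- setdiff(names(cfg$pins), target$reactions$id)
    if (length(bad) > 0) {
      stop("pin(s) on reaction(s) absent from the model: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(raw$grid)) {
    g <- raw$grid
    cfg$grid_values <- if (!is.null(g$values)) as.numeric(unlist(g$values))
                       else seq(g$from, g$to, by = g$by)
    if (any(!is.finite(cfg$grid_values))) {
      stop("grid contains non-finite values", call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

#' Execute a run configuration
#'
#' Dispatches to the analysis the configuration names and writes a results
#' TSV, a JSON summary and a plain-text log under `outdir`. Infeasible
#' solver statuses are recorded results, not errors.
#'
#' @param config A [load_config()] result.
#' @return Invisibly, a list with the result object and the output paths.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  t0 <- Sys.time()
  res <- switch(config$scenario,
    fba = {
      sol <- solve_fba(config$loaded_model, objective = config$objective,
                       fixed = config$pins)
      list(table = tidy(sol), summary = as.list(glance(sol)))
    },
    xfba = {
      sol <- solve_xfba(config$community, config$coupling_spec,
                        fixed = config$pins)
      list(table = tidy(sol), summary = as.list(glance(sol)))
    },
    screen_sources = {
      src <- dplyr::bind_rows(lapply(config$sources, tibble::as_tibble))
      scr <- nitrogen_carbon_screen(config$loaded_model, src)
      list(table = tibble::as_tibble(scr),
           summary = list(n_runs = nrow(scr),
                          best = scr$name[which.max(scr$mu)]))
    },
    scan_exchange = {
      scn <- exchange_robustness(config$community, config$coupling_spec,
                                 config$metabolite, config$grid_values,
                                 fixed = config$pins)
      list(table = tibble::as_tibble(scn),
           summary = list(base_growth = max(scn$community_growth,
                                            na.rm = TRUE)))
    },
    scan_abundance = {
      scn <- abundance_sensitivity(config$community, config$coupling_spec,
                                   fractions = config$fractions %||%
                                     seq(0.05, 0.30, by = 0.05),
                                   fixed = config$pins)
      list(table = tibble::as_tibble(scn),
           summary = list(mu1_range = range(scn$mu1, na.rm = TRUE)))
    },
    scan_oxygen = {
      scn <- oxygen_cytochrome_scan(config$community, config$coupling_spec,
                                    grid = config$grid_values,
                                    fixed = config$pins)
      list(table = tibble::as_tibble(scn), summary = attr(scn, "summary"))
    })

  paths <- list(table = file.path(config$outdir, "results.tsv"),
                summary = file.path(config$outdir, "summary.json"),
                log = file.path(config$outdir, "run.log"))
  readr::write_tsv(drop_list_columns(res$table), paths$table,
                   progress = FALSE)
  jsonlite::write_json(res$summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, null = "null")
  writeLines(c(
    paste0("xfba ", as.character(utils::packageVersion("xfba"))),
    paste0("scenario: ", config$scenario),
    paste0("config hash: ", config$hash),
    paste0("seed: ", config$seed),
    "solver: boot::simplex (two-phase), eps 1e-9",
    paste0("started: ", format(t0, "%Y-%m-%d %H:%M:%S")),
    paste0("elapsed: ",
           formatC(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                   digits = 2, format = "f"), " s")),
    paths$log)
  invisible(list(result = res, paths = paths))
}

drop_list_columns <- function(df) {
  df[!vapply(df, is.list, logical(1))]
}
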