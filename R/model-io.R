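#' Read a metabolic model from tabular or JSON files
#'
#' Three on-disk layouts are supported and auto-detected from the path:
#'
#' * **TSV directory** (`path` is a directory): `reactions.tsv` with columns
#'   `id, name, formula, lower_bound, upper_bound, subsystem` and
#'   `metabolites.tsv` with `id, name, formula, compartment`. Only `id` and
#'   the reaction `formula` are mandatory.
#' * **JSON** (`*.json`): the layout written by [write_model()], close to the
#'   common constraint-based JSON schema (`metabolites`, `reactions` with a
#'   `metabolites` coefficient map, `objective`).
#' * **XLSX** (`*.xlsx`, needs the readxl package): one reaction sheet and one
#'   metabolite sheet, matched by name (`reaction*`/`metabolite*`, falling
#'   back to sheets 1 and 2). Column headers are matched case- and
#'   whitespace-insensitively; unmapped extra columns are reported with a
#'   warning rather than guessed at.
#'
#' @param path File or directory to read.
#' @param id Model id; defaults to the file name.
#' @param objective Objective reaction id (JSON files carry their own).
#' @return A [metabolic_model()].
#' @export
read_model_table <- function(path, id = NULL, objective = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  id <- id %||% sub("\\.[A-Za-z]+$", "", basename(path))
  if (dir.exists(path)) {
    read_model_tsv(path, id = id, objective = objective)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    read_model_json(path, id = id, objective = objective)
  } else if (grepl("\\.xlsx$", path, ignore.case = TRUE)) {
    read_model_xlsx(path, id = id, objective = objective)
  } else {
    stop("unrecognised model format: ", path,
         " (expected a TSV directory, .json or .xlsx)", call. = FALSE)
  }
}

canonical_header <- function(x) {
  x <- tolower(gsub("[^a-z0-9]+", "_", tolower(trimws(x))))
  gsub("^_|_$", "", x)
}

# map header-name variants onto canonical column names; returns the renamed
# data frame, warning on unmapped extras
map_columns <- function(df, mapping, required, what) {
  names(df) <- canonical_header(names(df))
  for (target in names(mapping)) {
    hit <- intersect(mapping[[target]], names(df))
    if (length(hit) > 0) names(df)[match(hit[1L], names(df))] <- target
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing mandatory column(s) in ", what, " table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), names(mapping))
  if (length(extra) > 0) {
    warning("ignoring unmapped column(s) in ", what, " table: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  df
}

reaction_col_map <- list(
  id = c("id", "reaction", "reaction_id", "rxn", "abbreviation"),
  name = c("name", "reaction_name", "description"),
  formula = c("formula", "equation", "reaction_formula"),
  lower_bound = c("lower_bound", "lb", "lowerbound", "lower"),
  upper_bound = c("upper_bound", "ub", "upperbound", "upper"),
  subsystem = c("subsystem", "pathway"),
  member = "member")

metabolite_col_map <- list(
  id = c("id", "metabolite", "metabolite_id", "met", "abbreviation"),
  name = c("name", "metabolite_name", "full_name", "description"),
  formula = c("formula", "elemental_formula", "composition"),
  compartment = c("compartment", "comp"),
  member = "member")

build_model_from_tables <- function(rxn, met, id, objective) {
  rxn <- map_columns(rxn, reaction_col_map, c("id", "formula"), "reaction")
  if (nrow(rxn) == 0L) stop("empty reaction table", call. = FALSE)
  met <- map_columns(met, metabolite_col_map, "id", "metabolite")
  rxn <- dplyr::distinct(tibble::as_tibble(rxn))
  met <- dplyr::distinct(tibble::as_tibble(met))
  dup <- unique(rxn$id[duplicated(rxn$id)])
  if (length(dup) > 0) {
    stop("duplicate reaction id(s) with conflicting definitions: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  for (col in c("lower_bound", "upper_bound")) {
    if (col %in% names(rxn)) rxn[[col]] <- as.numeric(rxn[[col]])
  }
  for (col in c("name", "subsystem", "member")) {
    if (col %in% names(rxn)) rxn[[col]] <- as.character(rxn[[col]])
    if (col %in% names(met)) met[[col]] <- as.character(met[[col]])
  }
  if ("compartment" %in% names(met)) met$compartment <- as.character(met$compartment)
  # metabolites referenced by reactions but absent from the sheet are added
  parsed <- lapply(rxn$formula, parse_reaction_formula)
  refd <- unique(unlist(lapply(parsed, function(p) names(p$stoichiometry))))
  extra <- setdiff(refd, met$id)
  if (length(extra) > 0) {
    met <- dplyr::bind_rows(met, tibble::tibble(id = extra))
  }
  metabolic_model(id, metabolites = met, reactions = rxn,
                  objective = objective)
}

read_model_tsv <- function(path, id, objective = NULL) {
  rpath <- file.path(path, "reactions.tsv")
  mpath <- file.path(path, "metabolites.tsv")
  if (!file.exists(rpath)) stop("no reactions.tsv under ", path, call. = FALSE)
  if (!file.exists(mpath)) stop("no metabolites.tsv under ", path, call. = FALSE)
  rxn <- readr::read_tsv(rpath, show_col_types = FALSE, progress = FALSE)
  met <- readr::read_tsv(mpath, show_col_types = FALSE, progress = FALSE)
  obj <- objective
  meta <- file.path(path, "model.json")
  if (is.null(obj) && file.exists(meta)) {
    info <- jsonlite::read_json(meta)
    obj <- info$objective
    if (!is.null(info$id)) id <- info$id
  }
  build_model_from_tables(rxn, met, id, obj)
}

read_model_json <- function(path, id = NULL, objective = NULL) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  met <- dplyr::bind_rows(lapply(doc$metabolites, function(m) {
    tibble::tibble(id = m$id, name = m$name %||% m$id,
                   compartment = m$compartment %||% NA_character_,
                   formula = m$formula %||% NA_character_,
                   member = m$member %||% NA_character_)
  }))
  rxn <- dplyr::bind_rows(lapply(doc$reactions, function(r) {
    tibble::tibble(id = r$id, name = r$name %||% r$id,
                   stoichiometry = list(unlist(r$metabolites)),
                   lower_bound = r$lower_bound %||% 0,
                   upper_bound = r$upper_bound %||% 1000,
                   subsystem = r$subsystem %||% NA_character_,
                   member = r$member %||% NA_character_)
  }))
  if (nrow(rxn) == 0L) stop("empty reaction table in ", path, call. = FALSE)
  if (is.na(met$compartment[1]) || all(is.na(met$compartment))) {
    met$compartment <- compartment_of(met$id)
  }
  metabolic_model(doc$id %||% id, metabolites = met, reactions = rxn,
                  objective = objective %||% doc$objective)
}

read_model_xlsx <- function(path, id, objective = NULL) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("reading .xlsx models needs the readxl package", call. = FALSE)
  }
  sheets <- readxl::excel_sheets(path)
  pick <- function(pattern, fallback) {
    hit <- grep(pattern, sheets, ignore.case = TRUE, value = TRUE)
    if (length(hit) > 0) hit[1L] else sheets[fallback]
  }
  rsheet <- pick("^reaction", 1L)
  msheet <- pick("^metabolite", min(2L, length(sheets)))
  rxn <- readxl::read_excel(path, sheet = rsheet)
  met <- readxl::read_excel(path, sheet = msheet)
  build_model_from_tables(rxn, met, id, objective)
}

#' Write a metabolic model to disk
#'
#' `format = "tsv"` writes a directory holding `reactions.tsv`,
#' `metabolites.tsv` and a small `model.json` carrying the id and objective;
#' `format = "json"` writes a single JSON file. Both round-trip exactly
#' through [read_model_table()] (ids, stoichiometry, bounds, compartments).
#'
#' @param model A [metabolic_model()].
#' @param path Destination directory (tsv) or file (json).
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  validate_model(model)
  if (format == "tsv") {
    if (!dir.exists(path)) {
      ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
      if (!ok && !dir.exists(path)) {
        stop("cannot create directory ", path, call. = FALSE)
      }
    }
    rxn <- model$reactions
    rev <- rxn$lower_bound < 0
    rxn_out <- tibble::tibble(
      id = rxn$id, name = rxn$name,
      formula = mapply(format_reaction_formula, rxn$stoichiometry, rev),
      lower_bound = rxn$lower_bound, upper_bound = rxn$upper_bound,
      subsystem = rxn$subsystem, member = rxn$member)
    readr::write_tsv(rxn_out, file.path(path, "reactions.tsv"), progress = FALSE)
    readr::write_tsv(model$metabolites, file.path(path, "metabolites.tsv"),
                     progress = FALSE)
    jsonlite::write_json(list(id = model$id, objective = model$objective),
                         file.path(path, "model.json"), auto_unbox = TRUE,
                         null = "null")
  } else {
    doc <- list(
      id = model$id,
      objective = model$objective,
      metabolites = purrr::pmap(model$metabolites,
        function(id, name, compartment, formula, member, ...) {
          drop_na_fields(list(id = id, name = name, compartment = compartment,
                              formula = formula, member = member))
        }),
      reactions = purrr::pmap(model$reactions,
        function(id, name, stoichiometry, lower_bound, upper_bound, subsystem,
                 member, ...) {
          drop_na_fields(list(id = id, name = name,
                              metabolites = as.list(stoichiometry),
                              lower_bound = lower_bound,
                              upper_bound = upper_bound,
                              subsystem = subsystem, member = member))
        }))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

drop_na_fields <- function(x) {
  keep <- !vapply(x, function(v) length(v) == 1L && is.na(v), logical(1))
  x[keep]
}
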