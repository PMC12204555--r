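#' Construct a metabolic model
#'
#' A `metabolic_model` bundles a metabolite table, a reaction table and an
#' objective reaction id. Metabolite ids carry their compartment as a
#' bracketed suffix (`"succ[c]"` cytosol, `"succ[e]"` extracellular,
#' `"succ[u]"` shared community pool); the compartment column is derived
#' from the id when not supplied. Reaction stoichiometries are stored as a
#' list column of named numeric vectors (negative = consumed).
#'
#' @param id Model name.
#' @param metabolites A data frame with at least an `id` column; optional
#'   `name`, `compartment`, `formula`, `member` columns are filled with
#'   defaults.
#' @param reactions A data frame with columns `id` and `stoichiometry`
#'   (list of named numeric vectors) or `formula` (strings parsed with
#'   [parse_reaction_formula()]); optional `name`, `lower_bound`,
#'   `upper_bound`, `subsystem`, `member`. Default bounds are `(0, 1000)`
#'   for irreversible and `(-1000, 1000)` for reversible formulas, in
#'   mmol/gDW/h.
#' @param objective Reaction id used as default FBA objective (or `NULL`).
#' @return An object of class `metabolic_model`.
#' @examples
#' m <- metabolic_model(
#'   "demo",
#'   metabolites = tibble::tibble(id = c("a[e]", "a[c]", "b[c]")),
#'   reactions = tibble::tibble(
#'     id = c("EX_a", "T_a", "R1", "DM_b"),
#'     formula = c("a[e] <=> ", "a[e] -> a[c]", "a[c] -> b[c]", "b[c] -> ")
#'   ),
#'   objective = "DM_b"
#' )
#' m
#' @export
metabolic_model <- function(id, metabolites, reactions, objective = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  if (nrow(reactions) == 0L) {
    stop("model ", sQuote(id), " has an empty reaction table", call. = FALSE)
  }
  if (!"id" %in% names(metabolites) || !"id" %in% names(reactions)) {
    stop("metabolite and reaction tables need an 'id' column", call. = FALSE)
  }

  if (!"stoichiometry" %in% names(reactions)) {
    if (!"formula" %in% names(reactions)) {
      stop("reaction table needs a 'stoichiometry' or 'formula' column",
           call. = FALSE)
    }
    parsed <- lapply(reactions$formula, parse_reaction_formula)
    reactions$stoichiometry <- lapply(parsed, `[[`, "stoichiometry")
    rev <- vapply(parsed, `[[`, logical(1), "reversible")
    if (!"lower_bound" %in% names(reactions)) {
      reactions$lower_bound <- ifelse(rev, -1000, 0)
    } else {
      reactions$lower_bound <- ifelse(is.na(reactions$lower_bound),
                                      ifelse(rev, -1000, 0),
                                      reactions$lower_bound)
    }
  }
  metabolites <- fill_column(metabolites, "name", metabolites$id)
  metabolites <- fill_column(metabolites, "compartment",
                             compartment_of(metabolites$id))
  metabolites <- fill_column(metabolites, "formula", NA_character_)
  metabolites <- fill_column(metabolites, "member", NA_character_)

  reactions <- fill_column(reactions, "name", reactions$id)
  reactions <- fill_column(reactions, "lower_bound", 0)
  reactions <- fill_column(reactions, "upper_bound", 1000)
  reactions$upper_bound[is.na(reactions$upper_bound)] <- 1000
  reactions <- fill_column(reactions, "subsystem", NA_character_)
  reactions <- fill_column(reactions, "member", NA_character_)
  reactions$formula <- NULL

  model <- structure(
    list(id = id,
         metabolites = metabolites[c("id", "name", "compartment", "formula",
                                     "member")],
         reactions = reactions[c("id", "name", "stoichiometry", "lower_bound",
                                 "upper_bound", "subsystem", "member")],
         objective = objective),
    class = "metabolic_model")
  model$reactions$is_exchange <- is_exchange_reaction(model)
  validate_model(model)
}

fill_column <- function(df, col, default) {
  if (!col %in% names(df)) df[[col]] <- default
  df
}

#' Compartment tag of a metabolite id
#'
#' Extracts the innermost bracketed suffix of an id: `"succ[e]"` gives
#' `"e"`, ids without a bracket give `"c"` (cytosol by convention).
#'
#' @param ids Character vector of metabolite ids.
#' @return Character vector of compartment tags.
#' @export
compartment_of <- function(ids) {
  has <- grepl("\\[[^][]+\\]$", ids)
  out <- rep("c", length(ids))
  out[has] <- sub("^.*\\[([^][]+)\\]$", "\\1", ids[has])
  out
}

is_exchange_reaction <- function(model) {
  comp <- stats::setNames(model$metabolites$compartment, model$metabolites$id)
  vapply(model$reactions$stoichiometry, function(s) {
    length(s) == 1L && !is.na(comp[names(s)[1L]]) &&
      comp[names(s)[1L]] %in% c("e", "u")
  }, logical(1))
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique ids, non-empty stoichiometries,
#' every referenced metabolite present, bounds ordered, objective present.
#' Returns the model invisibly on success, errors otherwise.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly.
#' @export
validate_model <- function(model) {
  met <- model$metabolites
  rxn <- model$reactions
  dup_m <- unique(met$id[duplicated(met$id)])
  dup_r <- unique(rxn$id[duplicated(rxn$id)])
  if (length(dup_m) > 0) {
    stop("duplicate metabolite ids: ", paste(dup_m, collapse = ", "),
         call. = FALSE)
  }
  if (length(dup_r) > 0) {
    stop("duplicate reaction ids: ", paste(dup_r, collapse = ", "),
         call. = FALSE)
  }
  if (any(lengths(rxn$stoichiometry) == 0L)) {
    bad <- rxn$id[lengths(rxn$stoichiometry) == 0L]
    stop("empty stoichiometry in reaction(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  refd <- unique(unlist(lapply(rxn$stoichiometry, names)))
  missing <- setdiff(refd, met$id)
  if (length(missing) > 0) {
    stop("reactions reference unknown metabolites: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(rxn$lower_bound > rxn$upper_bound)) {
    bad <- rxn$id[rxn$lower_bound > rxn$upper_bound]
    stop("lower bound above upper bound in: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(model$objective) && !model$objective %in% rxn$id) {
    stop("objective reaction ", sQuote(model$objective), " not in model",
         call. = FALSE)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  reactions:   ", nrow(x$reactions), "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites), "\n", sep = "")
  cat("  objective:   ", x$objective %||% "<none>", "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of reactions / metabolites
#' @param model A `metabolic_model`.
#' @return Integer count.
#' @export
n_reactions <- function(model) nrow(model$reactions)

#' @rdname n_reactions
#' @export
n_metabolites <- function(model) nrow(model$metabolites)

#' Exchange reactions of a model
#'
#' Boundary reactions touching exactly one extracellular (`[e]`) or shared
#' (`[u]`) species. Flux convention: positive = secretion, uptake is a
#' negative flux enabled by a negative lower bound.
#'
#' @param model A `metabolic_model`.
#' @return Tibble of the exchange rows of the reaction table.
#' @export
exchange_reactions <- function(model) {
  model$reactions[model$reactions$is_exchange, ]
}

#' Set flux bounds on a reaction
#'
#' @param model A `metabolic_model`.
#' @param reaction Reaction id.
#' @param lower,upper New bounds; `NULL` leaves a bound unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction, lower = NULL, upper = NULL) {
  i <- match(reaction, model$reactions$id)
  if (is.na(i)) stop("no reaction ", sQuote(reaction), " in model", call. = FALSE)
  if (!is.null(lower)) model$reactions$lower_bound[i] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[i] <- upper
  validate_model(model)
  model
}

#' Set the objective reaction
#' @param model A `metabolic_model`.
#' @param reaction Reaction id.
#' @return The modified model.
#' @export
set_objective <- function(model, reaction) {
  if (!reaction %in% model$reactions$id) {
    stop("no reaction ", sQuote(reaction), " in model", call. = FALSE)
  }
  model$objective <- reaction
  model
}

#' Add a reaction to a model
#'
#' @param model A `metabolic_model`.
#' @param reaction A one-row data frame (or named list) with the reaction
#'   fields; `stoichiometry` must be a named numeric vector.
#' @return The modified model.
#' @export
add_reaction <- function(model, reaction) {
  row <- tibble::tibble(
    id = reaction$id,
    name = reaction$name %||% reaction$id,
    stoichiometry = list(reaction$stoichiometry),
    lower_bound = reaction$lower_bound %||% 0,
    upper_bound = reaction$upper_bound %||% 1000,
    subsystem = reaction$subsystem %||% NA_character_,
    member = reaction$member %||% NA_character_)
  new_mets <- setdiff(names(reaction$stoichiometry), model$metabolites$id)
  if (length(new_mets) > 0) {
    model$metabolites <- dplyr::bind_rows(
      model$metabolites,
      tibble::tibble(id = new_mets, name = new_mets,
                     compartment = compartment_of(new_mets),
                     formula = NA_character_, member = NA_character_))
  }
  model$reactions <- dplyr::bind_rows(
    model$reactions[setdiff(names(model$reactions), "is_exchange")], row)
  model$reactions$is_exchange <- is_exchange_reaction(model)
  validate_model(model)
  model
}

#' Drop reactions (and any orphaned metabolites) from a model
#'
#' @param model A `metabolic_model`.
#' @param reactions Character vector of reaction ids.
#' @param prune Drop metabolites no longer referenced by any reaction.
#' @return The modified model.
#' @export
remove_reactions <- function(model, reactions, prune = TRUE) {
  missing <- setdiff(reactions, model$reactions$id)
  if (length(missing) > 0) {
    stop("no such reaction(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  model$reactions <- model$reactions[!model$reactions$id %in% reactions, ]
  if (prune) {
    used <- unique(unlist(lapply(model$reactions$stoichiometry, names)))
    model$metabolites <- model$metabolites[model$metabolites$id %in% used, ]
  }
  if (!is.null(model$objective) && !model$objective %in% model$reactions$id) {
    model$objective <- NULL
  }
  validate_model(model)
  model
}
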