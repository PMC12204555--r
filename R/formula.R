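#' Parse a reaction formula string
#'
#' Turns a human-readable reaction string such as
#' `"2 qh2[c] + o2[c] -> 2 q[c] + 2 h2o[c]"` into a signed stoichiometry
#' vector. Species on the left of the arrow get negative coefficients
#' (consumed), species on the right positive ones (produced). An omitted
#' coefficient counts as 1. The arrow decides reversibility: `->` and `=>`
#' are irreversible, `<->` and `<=>` reversible.
#'
#' @param text A single reaction formula string containing exactly one arrow.
#' @return A list with elements `stoichiometry` (named numeric vector,
#'   metabolite id -> signed coefficient) and `reversible` (logical).
#' @examples
#' parse_reaction_formula("A -> B")
#' parse_reaction_formula("2 qh2 + o2 + 2 h_in -> 2 q + 2 h2o + 2 h_out")
#' @export
parse_reaction_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  arrows <- c("<=>", "<->", "=>", "->")
  # count arrow occurrences on the raw string (longest first so "<->" is not
  # double-counted as "->")
  probe <- text
  hits <- 0L
  arrow <- NA_character_
  for (a in arrows) {
    n <- length(gregexpr(a, probe, fixed = TRUE)[[1L]])
    if (attr(gregexpr(a, probe, fixed = TRUE)[[1L]], "match.length")[1L] == -1L) n <- 0L
    if (n > 0L && is.na(arrow)) arrow <- a
    hits <- hits + n
    probe <- gsub(a, " @ ", probe, fixed = TRUE)
  }
  if (hits == 0L) {
    stop("no arrow ('->', '=>', '<->', '<=>') in reaction formula: ", sQuote(text),
         call. = FALSE)
  }
  if (hits > 1L) {
    stop("more than one arrow in reaction formula: ", sQuote(text), call. = FALSE)
  }
  reversible <- arrow %in% c("<=>", "<->")
  sides <- strsplit(probe, "@", fixed = TRUE)[[1L]]
  if (length(sides) == 1L) sides <- c(sides, "")
  lhs <- parse_formula_side(sides[[1L]], -1, text)
  rhs <- parse_formula_side(sides[[2L]], +1, text)
  stoich <- c(lhs, rhs)
  # merge species appearing on both sides
  if (anyDuplicated(names(stoich))) {
    stoich <- vapply(split(unname(stoich), names(stoich)), sum, numeric(1))
    stoich <- stoich[stoich != 0]
  }
  list(stoichiometry = stoich, reversible = reversible)
}

# One side of a formula: "2 a + b + 0.5 c". `sign` is -1 for substrates.
parse_formula_side <- function(side, sign, text) {
  side <- trimws(side)
  if (side == "" || side == "0") return(stats::setNames(numeric(0), character(0)))
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1L]])
  terms <- terms[terms != ""]
  out <- numeric(length(terms))
  ids <- character(length(terms))
  for (i in seq_along(terms)) {
    tok <- strsplit(terms[[i]], "[[:space:]]+")[[1L]]
    tok <- tok[tok != ""]
    if (length(tok) == 1L) {
      coef <- 1
      id <- tok
    } else if (length(tok) == 2L) {
      coef <- suppressWarnings(as.numeric(tok[[1L]]))
      if (is.na(coef)) {
        stop("non-numeric coefficient ", sQuote(tok[[1L]]),
             " in reaction formula: ", sQuote(text), call. = FALSE)
      }
      id <- tok[[2L]]
    } else {
      stop("cannot parse term ", sQuote(terms[[i]]),
           " in reaction formula: ", sQuote(text), call. = FALSE)
    }
    out[[i]] <- sign * coef
    ids[[i]] <- id
  }
  stats::setNames(out, ids)
}

#' Serialise a stoichiometry vector back to a formula string
#'
#' Inverse of [parse_reaction_formula()]: every string it emits re-parses to
#' the same stoichiometry. Coefficients are written with full double
#' precision so round-trips are exact.
#'
#' @param stoichiometry Named numeric vector (negative = consumed).
#' @param reversible Logical; emit `<=>` instead of `->`.
#' @return A single formula string.
#' @export
format_reaction_formula <- function(stoichiometry, reversible = FALSE) {
  stopifnot(is.numeric(stoichiometry), !is.null(names(stoichiometry)))
  fmt_side <- function(v) {
    if (length(v) == 0L) return("")
    paste(vapply(seq_along(v), function(i) {
      cf <- abs(v[[i]])
      if (cf == 1) names(v)[[i]] else paste(format(cf, digits = 15, trim = TRUE,
                                                   scientific = FALSE),
                                            names(v)[[i]])
    }, character(1)), collapse = " + ")
  }
  lhs <- fmt_side(stoichiometry[stoichiometry < 0])
  rhs <- fmt_side(stoichiometry[stoichiometry > 0])
  arrow <- if (reversible) "<=>" else "->"
  trimws(paste(lhs, arrow, rhs))
}
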