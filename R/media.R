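#' Define an in silico media condition
#'
#' A media condition maps exchange reactions to maximum uptake rates.
#' Rates are stated positive (mmol/gDW/h) and applied as negative lower
#' bounds under the COBRA sign convention (negative exchange flux =
#' uptake). The study conditions are:
#' free-living — malate 1.44, succinate 1.38, oxygen 1.26, glutamate 2,
#' inositol 0.01; symbiosis — succinate 1.38, malate 1.44.
#'
#' @param uptakes named numeric: exchange reaction id -> uptake rate (>= 0)
#' @param label condition label, e.g. `"free-living"` or `"symbiosis"`
#' @return an object of class `media_condition`
#' @export
media_condition <- function(uptakes, label = "custom") {
  uptakes <- unlist(uptakes)
  if (any(uptakes < 0)) stop("uptake rates must be >= 0 (sign convention: ",
                             "rates are magnitudes, applied as negative lower bounds)")
  structure(list(uptakes = uptakes, label = label), class = "media_condition")
}

#' Read a media condition from a two-column TSV
#'
#' Format: header line `exchange_id<TAB>uptake_rate`, `#` comments allowed.
#'
#' @param path file path
#' @param label condition label
#' @return a `media_condition`
#' @export
read_media_tsv <- function(path, label = "custom") {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("media TSV needs columns exchange_id, uptake_rate")
  media_condition(stats::setNames(as.numeric(df[[2]]), df[[1]]), label = label)
}

#' Apply a media condition to a model
#'
#' Sets the lower bound of each listed exchange reaction to minus its
#' uptake rate. With `close_others = TRUE` the lower bound of every
#' unlisted exchange reaction is set to 0 (uptake closed; secretion stays
#' open). Stoichiometry is never modified.
#'
#' @param model a `metabolic_model`
#' @param media a `media_condition`
#' @param close_others close uptake through unlisted exchanges?
#' @return the constrained model
#' @export
apply_media <- function(model, media, close_others = FALSE) {
  stopifnot(inherits(media, "media_condition"))
  ex <- reactions_of_class(model, "exchange")
  unknown <- setdiff(names(media$uptakes), ex)
  if (length(unknown)) {
    stop("media lists non-exchange or unknown reactions: ",
         paste(unknown, collapse = ", "))
  }
  if (close_others) {
    others <- setdiff(ex, names(media$uptakes))
    if (length(others)) model <- set_bounds(model, others, lower = 0)
  }
  if (length(media$uptakes)) {
    model <- set_bounds(model, names(media$uptakes), lower = -media$uptakes)
  }
  model
}

#' Study media compositions
#'
#' Convenience constructors for the two study conditions, keyed by the
#' exchange ids used in the shipped toy networks (pass `ids` to rekey for
#' another model).
#'
#' @param ids named character mapping nutrient -> exchange reaction id
#' @return a `media_condition`
#' @name study_media
NULL

#' @rdname study_media
#' @export
symbiosis_media <- function(ids = c(succinate = "EX_succ", malate = "EX_mal")) {
  rates <- c(succinate = 1.38, malate = 1.44)
  media_condition(stats::setNames(rates[names(ids)], ids), label = "symbiosis")
}

#' @rdname study_media
#' @export
free_living_media <- function(ids = c(malate = "EX_mal", succinate = "EX_succ",
                                      oxygen = "EX_o2", glutamate = "EX_glu",
                                      inositol = "EX_inost")) {
  rates <- c(malate = 1.44, succinate = 1.38, oxygen = 1.26,
             glutamate = 2, inositol = 0.01)
  media_condition(stats::setNames(rates[names(ids)], ids), label = "free-living")
}
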