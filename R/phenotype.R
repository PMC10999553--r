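#' Sole-carbon-source growth test
#'
#' Emulates one well of a Biolog-style plate: uptake through every carbon
#' exchange is closed except the tested one, the non-carbon components of
#' the minimal medium stay open, and growth is called when the FBA
#' optimum of the biomass objective exceeds `growth_threshold`.
#'
#' @param model a `metabolic_model`
#' @param minimal_medium a `media_condition` holding the non-carbon
#'   nutrients (applied with `close_others = TRUE`)
#' @param carbon_exchange exchange reaction id of the tested source
#' @param uptake_rate uptake allowance for the tested source
#'   (mmol/gDW/h, default 10)
#' @param growth_threshold objective flux above which growth is called
#'   (default 1e-6: above LP tolerance, below any biological rate)
#' @return `"growth"` or `"no-growth"`
#' @export
sole_source_growth <- function(model, minimal_medium, carbon_exchange,
                               uptake_rate = 10, growth_threshold = 1e-6) {
  rxn_row(model, carbon_exchange)
  m <- apply_media(model, minimal_medium, close_others = TRUE)
  m <- set_bounds(m, carbon_exchange, lower = -uptake_rate)
  sol <- fba(m)
  if (sol$status == "optimal" && sol$objective_value > growth_threshold) "growth"
  else "no-growth"
}

#' Run a phenotype plate against a model
#'
#' For each well, looks up the substrate's exchange reaction in the
#' mapping table; unmapped substrates (absent from the model and the
#' underlying databases) are called `unmappable`. Mapped substrates are
#' tested with [sole_source_growth()].
#'
#' @param model a `metabolic_model`
#' @param plate data.frame with columns `well`, `substrate_name`,
#'   `observed` (1 = used, 0 = not used)
#' @param mapping data.frame with columns `substrate_name`, `exchange_id`
#' @param minimal_medium a `media_condition` of non-carbon nutrients
#' @param uptake_rate,growth_threshold passed to [sole_source_growth()]
#' @return data.frame of phenotype calls: `well`, `carbon_source`,
#'   `exchange_id`, `predicted`, `observed`
#' @export
phenotype_plate <- function(model, plate, mapping, minimal_medium,
                            uptake_rate = 10, growth_threshold = 1e-6) {
  ex_of <- stats::setNames(mapping$exchange_id, mapping$substrate_name)
  calls <- lapply(seq_len(nrow(plate)), function(i) {
    sub <- plate$substrate_name[i]
    ex <- if (sub %in% names(ex_of)) ex_of[[sub]] else NA_character_
    predicted <- if (is.na(ex) || !ex %in% model$reactions$id) {
      ex <- "absent-from-model"
      "unmappable"
    } else {
      sole_source_growth(model, minimal_medium, ex,
                         uptake_rate = uptake_rate,
                         growth_threshold = growth_threshold)
    }
    data.frame(well = plate$well[i], carbon_source = sub, exchange_id = ex,
               predicted = predicted,
               observed = ifelse(plate$observed[i] == 1, "used", "not-used"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, calls)
}

#' Summarise plate calls into a confusion table
#'
#' Accuracy is (TP + TN) / number of tested wells. Unmappable substrates
#' count as mismatches: a well the model cannot even represent cannot be
#' called consistent with the experiment.
#'
#' @param calls result of [phenotype_plate()]
#' @return list: `tp`, `tn`, `fp`, `fn`, `unmappable`, `tested`,
#'   `accuracy` (percent)
#' @export
plate_accuracy <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0) stop("empty phenotype call list")
  tested <- calls[calls$observed %in% c("used", "not-used"), ]
  unmappable <- sum(tested$predicted == "unmappable")
  mapped <- tested[tested$predicted != "unmappable", ]
  tp <- sum(mapped$predicted == "growth" & mapped$observed == "used")
  tn <- sum(mapped$predicted == "no-growth" & mapped$observed == "not-used")
  fp <- sum(mapped$predicted == "growth" & mapped$observed == "not-used")
  fn <- sum(mapped$predicted == "no-growth" & mapped$observed == "used")
  list(tp = tp, tn = tn, fp = fp, fn = fn, unmappable = unmappable,
       tested = nrow(tested), accuracy = 100 * (tp + tn) / nrow(tested))
}
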