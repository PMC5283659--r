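#' Interview weights by cell-based inverse response propensity
#'
#' Mimics a survey interview weight at cell level: within each sex x age
#' band x region cell, participants receive weight (sampled adults in cell)
#' / (participants in cell), i.e. the inverse of the cell response
#' propensity, and the weights are then rescaled to mean 1 over
#' participants. Non-participants carry no weight.
#'
#' If a cell contains sampled adults but no participants, its age band is
#' collapsed within sex x region before weighting, in a fixed documented
#' order: 18-34 merges into 35-54, then 55+ into 35-54, and if necessary all
#' three bands merge. A message reports any collapse.
#'
#' @param data A `cor_survey` data frame with `sex`, `age_group`, `region`
#'   and `responded` columns (all sampled adults, not only participants).
#' @return The input with its `int_weight` column filled in for
#'   participants (`NA` for non-participants).
#' @examples
#' svy <- simulate_survey(default_config(n_sampled = 2000L))
#' summary(participants(svy)$int_weight)
#' @export
compute_weights <- function(data) {
  stopifnot(
    is.data.frame(data),
    all(c("sex", "age_group", "region", "responded") %in% names(data))
  )
  age <- as.character(data$age_group)
  collapse_steps <- list(
    c("18-34" = "35-54"),
    c("18-34" = "35-54", "55+" = "35-54"),
    c("18-34" = "all", "35-54" = "all", "55+" = "all")
  )
  cell_of <- function(age) paste(data$sex, age, data$region, sep = " / ")
  cells <- cell_of(age)
  step <- 0
  repeat {
    sampled <- table(cells)
    resp <- table(factor(cells[data$responded], levels = names(sampled)))
    empty <- names(sampled)[resp == 0 & sampled > 0]
    if (!length(empty) || step >= length(collapse_steps)) break
    step <- step + 1
    map <- collapse_steps[[step]]
    age2 <- age
    hit <- age2 %in% names(map)
    age2[hit] <- map[age2[hit]]
    message(
      "compute_weights: no participants in cell(s) ",
      paste(utils::head(empty, 3), collapse = "; "),
      if (length(empty) > 3) " ..." else "",
      " - collapsing age bands (step ", step, ")"
    )
    cells <- cell_of(age2)
  }
  sampled <- table(cells)
  resp <- table(factor(cells[data$responded], levels = names(sampled)))
  if (any(resp == 0 & sampled > 0) && any(data$responded)) {
    message(
      "compute_weights: cells without participants remain after collapse; ",
      "their sampled adults are not represented in the weights"
    )
  }
  w <- as.numeric(sampled[cells]) / as.numeric(resp[cells])
  w[!data$responded] <- NA_real_
  w[is.infinite(w)] <- NA_real_
  part <- data$responded & !is.na(w)
  if (any(part)) w[part] <- w[part] / mean(w[part])
  data$int_weight <- w
  data
}
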