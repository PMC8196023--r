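#' Phenophase vocabulary
#'
#' The six standardized phenophases of the tundra plant annual cycle, in
#' seasonal order, and the paired phenophases that delimit the three
#' phenoperiods (growth: green up to leaf senescence; flowering: start to end
#' of flowering; fruiting: fruiting to seed dispersal).
#'
#' @return `phenophase_levels()` returns a character vector of the six
#'   phenophase labels; `phenoperiod_pairs()` a data frame with columns
#'   `period`, `start`, `end`.
#' @export
#' @examples
#' phenophase_levels()
#' phenoperiod_pairs()
phenophase_levels <- function() {
  c("green_up", "flowering", "end_of_flowering",
    "fruiting", "seed_dispersal", "leaf_senescence")
}

#' @rdname phenophase_levels
#' @export
phenoperiod_pairs <- function() {
  data.frame(
    period = c("growth", "flowering", "fruiting"),
    start  = c("green_up", "flowering", "fruiting"),
    end    = c("leaf_senescence", "end_of_flowering", "seed_dispersal"),
    stringsAsFactors = FALSE
  )
}

# internal: validate phenophase labels
check_phenophase <- function(x) {
  bad <- setdiff(unique(as.character(x)), phenophase_levels())
  if (length(bad) > 0L) {
    stop("unknown phenophase label(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
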