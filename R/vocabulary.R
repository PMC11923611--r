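#' Behaviour vocabulary and category map
#'
#' The ethogram used throughout the package: 14 behaviours regularly
#' observed in tunnel-system observations of Damaraland mole-rats, grouped
#' into four analysis categories. Excavating activities are digging,
#' sweeping soil backwards and back-kicking for soil tightening; movement
#' is running, walking and food carrying; everything that is neither of
#' those nor rest (eating, grooming, gnawing, ...) falls into \code{other}.
#'
#' @return `behaviour_vocabulary()` returns a character vector of the 14
#'   behaviour names; `behaviour_categories()` returns a named character
#'   vector mapping each behaviour to one of `"rest"`, `"excavate"`,
#'   `"move"`, `"other"`.
#' @export
behaviour_vocabulary <- function() {
  names(behaviour_categories())
}

#' @rdname behaviour_vocabulary
#' @export
behaviour_categories <- function() {
  c(
    rest          = "rest",
    dig           = "excavate",
    sweep         = "excavate",
    `back-kick`   = "excavate",
    run           = "move",
    walk          = "move",
    `food-carry`  = "move",
    eat           = "other",
    groom         = "other",
    gnaw          = "other",
    `dust-bathe`  = "other",
    rear          = "other",
    sniff         = "other",
    scratch       = "other"
  )
}

#' Map behaviours to their analysis category
#'
#' Total function from the 14-behaviour vocabulary onto the four analysis
#' categories `rest`, `excavate`, `move`, `other`.
#'
#' @param behaviour character vector of behaviour names.
#' @return character vector of categories, same length as `behaviour`.
#' @examples
#' map_to_categories(c("back-kick", "food-carry", "rest"))
#' @export
map_to_categories <- function(behaviour) {
  map <- behaviour_categories()
  bad <- setdiff(unique(behaviour), names(map))
  if (length(bad) > 0) {
    stop("unknown behaviour(s): ", paste(bad, collapse = ", "))
  }
  unname(map[behaviour])
}

category_levels <- function() c("rest", "excavate", "move", "other")
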