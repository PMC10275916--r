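## Media conditions: which extracellular metabolites the model may take up,
## and how fast.  "complete" media opens every exchange reaction.

#' Define a media condition
#'
#' @param name media name.
#' @param uptake named numeric vector: extracellular metabolite id -> maximal
#'   uptake rate (mmol/gDW/h, strictly positive).  Omit (NULL) together with
#'   \code{complete = TRUE} for complete media.
#' @param complete open every exchange at the default rate of 1000.
#' @return a \code{media_condition}.
#' @export
media_condition <- function(name, uptake = NULL, complete = FALSE) {
  if (!complete) {
    if (is.null(uptake) || is.null(names(uptake)) || any(names(uptake) == ""))
      stop("non-complete media needs a named uptake vector")
    if (any(uptake <= 0)) stop("uptake rates must be strictly positive")
  }
  structure(list(name = name, uptake = uptake, complete = complete),
            class = "media_condition")
}

#' The distinguished complete media (all exchanges open)
#' @return a \code{media_condition} with every exchange open at 1000.
#' @export
media_complete <- function() media_condition("complete", complete = TRUE)

is_complete_media <- function(media) isTRUE(media$complete)

#' Read a media definition from JSON
#'
#' Schema: \code{{"name": ..., "uptake": {"cpd00027_e": 10, ...}}}, or
#' \code{{"name": "complete", "complete": true}}.
#' @param path JSON file path.
#' @return a \code{media_condition}.
#' @export
read_media <- function(path) {
  doc <- jsonlite::read_json(path)
  if (isTRUE(doc$complete)) return(media_condition(doc$name %||% "complete",
                                                   complete = TRUE))
  media_condition(doc$name %||% basename(path), uptake = unlist(doc$uptake))
}

#' Apply a media condition to a model
#'
#' Complete media sets every exchange lower bound to -1000.  A named media
#' zeroes every exchange lower bound, then opens the exchange of each media
#' metabolite to -uptake.  Exchange upper bounds (secretion) are always 1000.
#' Media metabolites without an exchange reaction in the model are skipped
#' with a warning.
#'
#' @param model a \code{genre}.
#' @param media a \code{media_condition}.
#' @return the model with exchange bounds set.
#' @export
set_media <- function(model, media) {
  ex <- names(model$reactions)[vapply(model$reactions, is_exchange, TRUE)]
  if (!length(ex)) stop("model has no exchange reactions")
  for (id in ex) {
    model$reactions[[id]]$lb <- if (is_complete_media(media)) -1000 else 0
    model$reactions[[id]]$ub <- 1000
  }
  if (!is_complete_media(media)) {
    for (mid in names(media$uptake)) {
      ex_id <- paste0("EX_", mid)
      if (!ex_id %in% ex) {
        warning("media metabolite ", mid, " has no exchange reaction in the ",
                "model; skipped")
        next
      }
      model$reactions[[ex_id]]$lb <- -media$uptake[[mid]]
    }
  }
  model
}
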