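#' Facet labels of the priority questionnaire
#'
#' Ten facets of an adult outcome over which respondents allocate up to 100
#' points. The labels (and the default facet-to-outcome mapping) are the
#' package's own curated set covering the 14 study outcomes.
#'
#' @return character vector of length 10.
#' @export
default_facet_labels <- function() {
  c("cognitive_ability", "daily_living_skills", "independent_living",
    "work", "friendships", "autism_symptoms", "behavior_problems",
    "mood_depression", "positive_emotions", "contentedness")
}

#' An elicited priority profile
#'
#' @param points non-negative points per facet, total at most 100.
#' @param labels facet labels.
#' @return object of class `priority_profile`.
#' @export
#' @examples
#' priority_profile(rep(10, 10))
priority_profile <- function(points, labels = default_facet_labels()) {
  if (length(points) != length(labels))
    stop("`points` must have one entry per facet")
  if (any(points < 0)) stop("priority points must be non-negative")
  if (sum(points) > 100 + 1e-9)
    stop("priority points must sum to at most 100")
  names(points) <- labels
  structure(list(facet_points = points, labels = labels),
            class = "priority_profile")
}

#' @export
print.priority_profile <- function(x, ...) {
  cat("priority profile (", sum(x$facet_points), "/100 points):\n", sep = "")
  print(x$facet_points)
  invisible(x)
}

#' Map facets onto study outcomes
#'
#' A 10 x K matrix of non-negative shares; each facet's row sums to 1, so a
#' facet's points are fully distributed over the outcomes it maps to.
#'
#' @param M matrix (facets x outcomes) of shares.
#' @param facets,outcomes dimnames (defaults taken from `M`).
#' @return object of class `facet_outcome_map`.
#' @export
facet_outcome_map <- function(M, facets = rownames(M),
                              outcomes = colnames(M)) {
  if (!is.matrix(M) || any(M < 0))
    stop("`M` must be a non-negative matrix")
  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-8))
    stop("each facet row of `M` must sum to 1")
  dimnames(M) <- list(facets, outcomes)
  structure(list(M = M), class = "facet_outcome_map")
}

#' Default facet-to-outcome mapping
#'
#' Distributes each of the ten questionnaire facets uniformly over a curated
#' subset of the 14 default outcomes (e.g. `cognitive_ability` splits evenly
#' between verbal and non-verbal IQ). The mapping used with the original
#' questionnaire is not publicly available, so this is a configurable
#' synthetic stand-in.
#'
#' @return a [facet_outcome_map()].
#' @export
default_facet_outcome_map <- function() {
  outcomes <- names(default_outcome_specs())
  facets <- default_facet_labels()
  M <- matrix(0, length(facets), length(outcomes),
              dimnames = list(facets, outcomes))
  put <- function(facet, cols) M[facet, cols] <<- 1 / length(cols)
  put("cognitive_ability", c("out_viq", "out_nviq"))
  put("daily_living_skills", "out_dls")
  put("independent_living", "out_living")
  put("work", "out_work")
  put("friendships", "out_friends")
  put("autism_symptoms", "out_css")
  put("behavior_problems", c("out_irr", "out_hyp", "out_abcl"))
  put("mood_depression", c("out_bdi", "out_panas_n"))
  put("positive_emotions", "out_panas_p")
  put("contentedness", "out_wbq")
  facet_outcome_map(M)
}

#' Turn priority points into outcome weights
#'
#' `w = (points / 100)' M`: every facet's points are spread over its mapped
#' outcomes, giving non-negative weights with `sum(w) = sum(points) / 100`.
#'
#' @param profile a [priority_profile()].
#' @param map a [facet_outcome_map()] (default [default_facet_outcome_map()]).
#' @return named non-negative weight vector of length K.
#' @export
#' @examples
#' map_priorities_to_weights(priority_profile(rep(10, 10)))
map_priorities_to_weights <- function(profile,
                                      map = default_facet_outcome_map()) {
  stopifnot(inherits(profile, "priority_profile"),
            inherits(map, "facet_outcome_map"))
  if (nrow(map$M) != length(profile$facet_points))
    stop("map and profile disagree on the number of facets")
  drop(crossprod(map$M, profile$facet_points / 100))[colnames(map$M)]
}
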