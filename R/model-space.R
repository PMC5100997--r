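# Enumeration of the modulation model space.
#
# Each candidate model frees a subset of the six modulation terms
# {Ai, Ad, Sei, Sed, Sri, Srd} on top of the always-free mean slopes Sem and
# Srm (the amplitude baseline Am is fixed to 1 for identifiability). Of the
# 2^6 = 64 subsets, only 20 can a priori produce the three robust behavioural
# effects of the task (longer efforts with incentive, shorter rests with
# incentive, shorter efforts with difficulty): the cross of 4 incentive
# subsets with 5 difficulty subsets.

MODULATION_NAMES <- c("Ai", "Ad", "Sei", "Sed", "Sri", "Srd")

INCENTIVE_SUBSETS <- list(
  c("Ai", "Sei", "Sri"),
  c("Ai", "Sei"),
  c("Ai", "Sri"),
  c("Sei", "Sri")
)

DIFFICULTY_SUBSETS <- list(
  c("Ad", "Sed", "Srd"),
  c("Ad", "Sed"),
  c("Ad", "Srd"),
  c("Sed", "Srd"),
  c("Sed")
)

#' Construct a modulation model specification
#'
#' @param modulations Character vector of active modulation terms, a subset of
#'   `c("Ai", "Ad", "Sei", "Sed", "Sri", "Srd")`. The mean slopes `Sem` and
#'   `Srm` are always free and the amplitude baseline `Am` is always fixed at
#'   1, so they are not listed.
#' @return An object of class `eat_model_spec`: a named logical vector over
#'   the six modulation terms.
#' @examples
#' model_spec(c("Ai", "Sed", "Sri"))
#' @export
model_spec <- function(modulations = character()) {
  bad <- setdiff(modulations, MODULATION_NAMES)
  if (length(bad)) stopf("unknown modulation term(s): %s", paste(bad, collapse = ", "))
  has <- stats::setNames(MODULATION_NAMES %in% modulations, MODULATION_NAMES)
  structure(has, class = "eat_model_spec")
}

#' @export
print.eat_model_spec <- function(x, ...) {
  cat("<cost-evidence model>", model_label(x), "\n")
  invisible(x)
}

#' Compact label for a model specification
#'
#' Concatenates the active modulation terms in canonical order
#' (Ai, Ad, Sei, Sed, Sri, Srd), e.g. `"AiSedSri"`. The null model (no
#' modulations) is labelled `"null"`.
#'
#' @param spec An `eat_model_spec`.
#' @return A character scalar.
#' @export
model_label <- function(spec) {
  act <- names(spec)[as.logical(spec)]
  if (!length(act)) "null" else paste(act, collapse = "")
}

#' Free parameter names of a model
#'
#' @param spec An `eat_model_spec`.
#' @return Character vector: `Sem`, `Srm`, then the active modulations.
#' @export
free_parameters <- function(spec) {
  c("Sem", "Srm", names(spec)[as.logical(spec)])
}

#' Enumerate the candidate model space
#'
#' With `admissible_only = TRUE` (the default) returns the 20 models obtained
#' by crossing the 4 incentive-modulation subsets \{Ai,Sei,Sri\}, \{Ai,Sei\},
#' \{Ai,Sri\}, \{Sei,Sri\} with the 5 difficulty-modulation subsets
#' \{Ad,Sed,Srd\}, \{Ad,Sed\}, \{Ad,Srd\}, \{Sed,Srd\}, \{Sed\} — the
#' combinations able to reproduce the task's behavioural effects. Ordering is
#' deterministic: incentive subset major, difficulty subset minor. With
#' `admissible_only = FALSE` returns all 64 subsets of the six modulations
#' (binary order).
#'
#' @param admissible_only Logical; restrict to the 20 admissible models.
#' @return A list of `eat_model_spec` objects, named by [model_label()].
#' @export
enumerate_model_space <- function(admissible_only = TRUE) {
  specs <- if (admissible_only) {
    unlist(lapply(INCENTIVE_SUBSETS, function(inc) {
      lapply(DIFFICULTY_SUBSETS, function(dif) model_spec(c(inc, dif)))
    }), recursive = FALSE)
  } else {
    lapply(0:63, function(bits) {
      model_spec(MODULATION_NAMES[bitwAnd(bits, 2^(0:5)) > 0])
    })
  }
  names(specs) <- vapply(specs, model_label, character(1))
  specs
}
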