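# The nine-state consent vocabulary and its three-way quality aggregation.

.CONSENT_STATES <- c(
  "ACCEPTED",     # answered "yes"
  "DECLINED",     # answered "no"
  "UNKNOWN",      # policy did not apply / no answer option could be chosen
  "NOT_ASKED",    # specialisation of unknown: the question was not posed
  "NOT_CHOSEN",   # specialisation of unknown: the question was left blank
  "WITHDRAWN",    # revoked by the participant
  "INVALIDATED",  # document invalidated retrospectively
  "REFUSED",      # participant refused to answer at all
  "EXPIRED"       # validity period elapsed; computed, never stored
)

# States a capture workflow may record. WITHDRAWN enters only through the
# withdrawal operation and EXPIRED is derived at query time.
.CAPTURE_STATES <- c("ACCEPTED", "DECLINED", "UNKNOWN", "NOT_ASKED", "NOT_CHOSEN", "REFUSED")

.QUALITY_CLASSES <- c("ACCEPTED", "DECLINED", "UNKNOWN")

#' The consent state vocabulary
#'
#' The engine depicts a participant's will for one policy in exactly nine raw
#' states. `ACCEPTED` and `DECLINED` record express answers; `UNKNOWN` covers
#' policies that did not apply or could not be answered, with `NOT_ASKED` and
#' `NOT_CHOSEN` as its two specialisations; `WITHDRAWN`, `INVALIDATED` and
#' `REFUSED` record revocation, retrospective exclusion and refusal to answer;
#' `EXPIRED` marks an accepted consent whose validity period has elapsed and
#' is always computed at query time, never stored.
#'
#' @return Character vector of the nine state names.
#' @examples
#' consent_states()
#' @export
consent_states <- function() .CONSENT_STATES

#' The three quality classes
#'
#' Boolean consent queries aggregate the nine raw states into
#' accepted / declined / unknown.
#'
#' @return Character vector of the three class names.
#' @export
quality_classes <- function() .QUALITY_CLASSES

#' Aggregate a raw state into its quality class
#'
#' `ACCEPTED` maps to `ACCEPTED`; `DECLINED`, `WITHDRAWN`, `INVALIDATED`,
#' `REFUSED` and `EXPIRED` map to `DECLINED`; `UNKNOWN`, `NOT_ASKED` and
#' `NOT_CHOSEN` map to `UNKNOWN`, collapsed to `DECLINED` when
#' `unknown_as_decline` is set (the conservative interpretation used when an
#' unanswered policy must not grant access).
#'
#' @param raw_state One of [consent_states()].
#' @param unknown_as_decline Collapse the unknown class to `DECLINED`?
#' @return `"ACCEPTED"`, `"DECLINED"` or `"UNKNOWN"`.
#' @examples
#' quality_of("NOT_ASKED")                      # "UNKNOWN"
#' quality_of("NOT_ASKED", unknown_as_decline = TRUE)  # "DECLINED"
#' @export
quality_of <- function(raw_state, unknown_as_decline = FALSE) {
  if (!is_string(raw_state) || !(raw_state %in% .CONSENT_STATES)) {
    stop_consentry("UnknownState", sprintf("'%s' is not a consent state", raw_state))
  }
  q <- switch(raw_state,
    ACCEPTED = "ACCEPTED",
    DECLINED = , WITHDRAWN = , INVALIDATED = , REFUSED = , EXPIRED = "DECLINED",
    UNKNOWN = , NOT_ASKED = , NOT_CHOSEN = "UNKNOWN"
  )
  if (q == "UNKNOWN" && isTRUE(unknown_as_decline)) "DECLINED" else q
}
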