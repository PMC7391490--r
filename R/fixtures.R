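# Synthetic consent histories and the independent replay oracle.
#
# The generator emulates a longitudinal cohort: a catalogue whose template
# evolves across versions (later versions add policies, so participants
# consented under early versions were never asked the additions), captures
# spread over the study period, and withdrawals — partial or full — at a
# configurable rate. Every generated event sequence is valid by
# construction and fully determined by its seed.
#
# The oracle answers status queries by a single linear replay of the event
# list with no indexes and no calls into the engine's resolution path; the
# property suites check the engine against it on many seeded histories.

#' Specification of a synthetic consent history
#'
#' Defaults describe a small longitudinal study: a catalogue evolving over
#' two template versions, captures across a six-year window, one in ten
#' participants withdrawing, half of those only partially.
#'
#' @param seed Integer seed; the same spec always yields the same events.
#' @param n_participants Number of participants.
#' @param template_versions Number of template versions `1.0 .. k.0`; each
#'   version after the first adds one policy.
#' @param p_withdrawal Per-participant probability of a withdrawal event.
#' @param p_partial Probability that a withdrawal is partial rather than
#'   full.
#' @param date_range Character/Date vector of length 2; captures fall in the
#'   first part of the window, withdrawals strictly after the capture.
#' @param validity_properties Optional named map of domain properties (e.g.
#'   `VALIDITY_PERIOD`) applied to the generated domain.
#' @param base_policies Number of policies in template version 1.
#' @return A list of class `"history_spec"`.
#' @examples
#' history_spec(seed = 42, n_participants = 20)
#' @export
history_spec <- function(seed, n_participants, template_versions = 2L,
                         p_withdrawal = 0.1, p_partial = 0.5,
                         date_range = c("2015-01-01", "2020-12-31"),
                         validity_properties = NULL, base_policies = 3L) {
  if (!is.numeric(seed) || length(seed) != 1L) {
    stop_consentry("InvalidSpec", "seed must be a single integer")
  }
  if (!is.numeric(n_participants) || n_participants < 1L) {
    stop_consentry("InvalidSpec", "n_participants must be >= 1")
  }
  if (template_versions < 1L) stop_consentry("InvalidSpec", "need >= 1 template version")
  if (p_withdrawal < 0 || p_withdrawal > 1 || p_partial < 0 || p_partial > 1) {
    stop_consentry("InvalidSpec", "probabilities must lie in [0, 1]")
  }
  start <- as_consent_date(date_range[[1]])
  end <- as_consent_date(date_range[[2]])
  if (end <= start) stop_consentry("InvalidSpec", "date_range must be non-empty")
  if (!is.null(validity_properties)) validate_properties(validity_properties, strict = TRUE)
  structure(list(
    seed = as.integer(seed), n_participants = as.integer(n_participants),
    template_versions = as.integer(template_versions),
    p_withdrawal = p_withdrawal, p_partial = p_partial,
    date_range = c(start, end),
    validity_properties = validity_properties,
    base_policies = as.integer(base_policies)
  ), class = "history_spec")
}

with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  expr
}

#' Generate a synthetic consent history
#'
#' @param spec A [history_spec()].
#' @return A chronologically ordered list of events (class
#'   `"consent_history"`): catalogue definitions followed by consent
#'   captures and withdrawals. Feed it to [apply_history()] to build a
#'   store, or to [replay_oracle()] for independent query answers.
#' @export
generate_history <- function(spec) {
  if (!inherits(spec, "history_spec")) stop_consentry("InvalidSpec", "need a history_spec")
  with_preserved_rng({
    set.seed(spec$seed)
    domain <- "synth"
    def_date <- spec$date_range[1] - 1L
    events <- list()
    push <- function(e) events[[length(events) + 1L]] <<- e

    push(list(type = "create_domain", date = def_date, name = domain,
              label = "Synthetic cohort",
              properties = as.list(spec$validity_properties %||% list()),
              signer_id_types = "pseudonym"))
    n_pol_of <- function(v) spec$base_policies + (v - 1L)
    total_policies <- n_pol_of(spec$template_versions)
    pol_ks <- sprintf("%s/p%02d/1.0", domain, seq_len(total_policies))
    for (i in seq_len(total_policies)) {
      push(list(type = "define_policy", date = def_date, key = pol_ks[i],
                label = sprintf("Do you consent to purpose %d?", i)))
    }
    for (v in seq_len(spec$template_versions)) {
      mod_ks <- sprintf("%s/core/%d.0", domain, v)
      push(list(type = "define_module", date = def_date, key = mod_ks,
                title = "Core module", policy_keys = pol_ks[seq_len(n_pol_of(v))]))
      push(list(type = "define_template", date = def_date,
                key = sprintf("%s/consent/%d.0", domain, v),
                module_assignments = list(list(module = mod_ks, mandatory = FALSE,
                                               display_order = 1L))))
    }

    span <- as.integer(spec$date_range[2] - spec$date_range[1])
    capture_cut <- as.integer(floor(span * 0.6))
    signers <- sprintf("pseudonym:P%04d", seq_len(spec$n_participants))
    birthdate_needed <- !is.null(spec$validity_properties) &&
      !is.null(spec$validity_properties[["VALIDITY_PERIOD_FROM_BIRTHDATE"]])

    participant_events <- list()
    for (i in seq_len(spec$n_participants)) {
      v <- sample.int(spec$template_versions, 1L)
      cdate <- spec$date_range[1] + sample.int(capture_cut + 1L, 1L) - 1L
      npol <- n_pol_of(v)
      decision <- sample(c("ACCEPTED", "DECLINED", "NOT_CHOSEN", "REFUSED"), 1L,
                         prob = c(0.85, 0.07, 0.04, 0.04))
      overrides <- list()
      for (p in seq_len(npol)) {
        if (stats::runif(1) < 0.15) {
          overrides[[pol_ks[p]]] <- sample(.CAPTURE_STATES, 1L)
        }
      }
      if (birthdate_needed) {
        bd <- as.Date("1950-01-01") + sample.int(20000L, 1L) - 1L
        participant_events[[length(participant_events) + 1L]] <-
          list(type = "set_birthdate", date = cdate, signer = signers[i],
               birthdate = bd)
      }
      participant_events[[length(participant_events) + 1L]] <-
        list(type = "consent", date = cdate, signer = signers[i],
             template = sprintf("%s/consent/%d.0", domain, v),
             decisions = list(core = decision), overrides = overrides,
             capture_mode = if (stats::runif(1) < 0.5) "PAPER_DIGITIZED" else "ELECTRONIC")
      if (stats::runif(1) < spec$p_withdrawal) {
        gap <- as.integer(spec$date_range[2] - cdate)
        wdate <- cdate + sample.int(max(gap, 1L), 1L)
        answered <- pol_ks[seq_len(npol)]
        scope <- if (stats::runif(1) < spec$p_partial && npol > 1L) {
          sample(answered, sample.int(npol - 1L, 1L))
        } else "FULL"
        participant_events[[length(participant_events) + 1L]] <-
          list(type = "withdrawal", date = wdate, signer = signers[i],
               domain = domain, scope = scope)
      }
    }
    # chronological order; generation sequence breaks date ties
    o <- order(vapply(participant_events, function(e) as.numeric(e$date), 0),
               seq_along(participant_events), method = "radix")
    events <- c(events, participant_events[o])
    for (i in seq_along(events)) events[[i]]$seq <- i
    structure(events, class = "consent_history")
  })
}

#' Build a store from an event list
#'
#' Dispatches every event to the corresponding engine operation, with
#' deterministic capture timestamps derived from event order.
#'
#' @param events A `"consent_history"` (see [generate_history()]) or a plain
#'   event list.
#' @param config Store configuration, passed to [consent_system()].
#' @return A populated [consent_system()].
#' @export
apply_history <- function(events, config = list()) {
  sys <- consent_system(config = config)
  for (e in events) {
    ts <- as.POSIXct(e$date, tz = "UTC") + (e$seq %||% 0L)
    switch(e$type,
      create_domain = create_domain(sys, e$name, e$label %||% e$name,
                                    e$properties %||% list(),
                                    e$signer_id_types %||% "pseudonym"),
      define_policy = define_policy(sys, e$key, e$label %||% e$key),
      define_module = define_module(sys, e$key, e$title %||% e$key,
                                    e$text %||% "", e$policy_keys),
      define_template = define_template(sys, e$key, e$header %||% "", e$footer %||% "",
                                        e$module_assignments,
                                        e$free_text_defs %||% list(),
                                        e$properties %||% list(),
                                        e$template_kind %||% "CONSENT"),
      set_birthdate = set_signer_birthdate(sys, e$signer, e$birthdate),
      consent = record_consent(sys, e$signer, e$template, e$date, e$decisions,
                               e$free_text %||% list(),
                               e$capture_mode %||% "PAPER_DIGITIZED",
                               policy_overrides = e$overrides %||% list(),
                               capture_timestamp = ts),
      withdrawal = record_withdrawal(sys, e$signer, e$domain, e$scope, e$date,
                                     capture_timestamp = ts),
      invalidate = invalidate_document(sys, e$document_id, e$reason %||% "", e$date),
      stop_consentry("InvalidSpec", sprintf("unknown event type '%s'", e$type))
    )
  }
  sys
}

# ---- the oracle -------------------------------------------------------------

# Everything below is a deliberately naive, index-free replay used only in
# tests: documents are materialised event by event, the governing document
# is found by pairwise comparison, and expiry is recomputed from the
# definition events on every query.

oracle_vcmp <- function(a, b) {
  pa <- as.integer(strsplit(a, ".", fixed = TRUE)[[1]])
  pb <- as.integer(strsplit(b, ".", fixed = TRUE)[[1]])
  length(pa) <- length(pb) <- 4L
  pa[is.na(pa)] <- 0L; pb[is.na(pb)] <- 0L
  for (i in 1:4) {
    if (pa[i] > pb[i]) return(1L)
    if (pa[i] < pb[i]) return(-1L)
  }
  0L
}

oracle_key_parts <- function(ks) strsplit(ks, "/", fixed = TRUE)[[1]]

# materialise the full document table by linear replay
oracle_documents <- function(events) {
  defs <- list(domain_props = list(), policies = list(), modules = list(),
               templates = list(), birthdates = list())
  docs <- list()
  doc_n <- 0L
  better <- function(a, b, weighting) {
    # TRUE when a governs over b
    cmp <- function(x, y) if (x > y) 1L else if (x < y) -1L else 0L
    keys <- if (weighting == "VERSION_THEN_DATE") {
      list(oracle_vcmp(a$tpl_version, b$tpl_version), cmp(a$date, b$date), cmp(a$ts, b$ts))
    } else {
      list(cmp(a$date, b$date), oracle_vcmp(a$tpl_version, b$tpl_version), cmp(a$ts, b$ts))
    }
    for (k in keys) { if (k > 0L) return(TRUE); if (k < 0L) return(FALSE) }
    a$id < b$id
  }
  for (e in events) {
    if (e$type == "create_domain") {
      defs$domain_props[[e$name]] <- lapply(e$properties %||% list(), as.character)
    } else if (e$type == "define_policy") {
      defs$policies[[e$key]] <- e
    } else if (e$type == "define_module") {
      defs$modules[[e$key]] <- e
    } else if (e$type == "define_template") {
      defs$templates[[e$key]] <- e
    } else if (e$type == "set_birthdate") {
      defs$birthdates[[e$signer]] <- as.Date(e$birthdate)
    } else if (e$type == "consent") {
      tpl <- defs$templates[[e$template]]
      states <- list()
      for (a in tpl$module_assignments) {
        mod <- defs$modules[[if (is.character(a$module)) a$module else key_string(a$module)]]
        mname <- oracle_key_parts(mod$key)[2]
        for (pk in mod$policy_keys) {
          states[[pk]] <- (e$overrides %||% list())[[pk]] %||% e$decisions[[mname]]
        }
      }
      doc_n <- doc_n + 1L
      docs[[doc_n]] <- list(
        id = sprintf("doc-%06d", doc_n), signer = e$signer,
        template = e$template,
        tpl_version = oracle_key_parts(e$template)[3],
        domain = oracle_key_parts(e$template)[1],
        date = as.Date(e$date), ts = e$seq %||% doc_n,
        capture_mode = e$capture_mode %||% "PAPER_DIGITIZED",
        states = states, invalidated = FALSE)
    } else if (e$type == "withdrawal") {
      mine <- Filter(function(d) d$signer == e$signer && d$domain == e$domain &&
                       !d$invalidated && d$date <= as.Date(e$date), docs)
      answered <- unique(unlist(lapply(mine, function(d) names(d$states))))
      carried <- list()
      gov_all <- NULL
      for (d in mine) if (is.null(gov_all) || better(d, gov_all, "DATE_THEN_VERSION")) gov_all <- d
      for (ks in answered) {
        gov <- NULL
        for (d in mine) {
          if (!is.null(d$states[[ks]]) &&
              (is.null(gov) || better(d, gov, "DATE_THEN_VERSION"))) gov <- d
        }
        carried[[ks]] <- gov$states[[ks]]
      }
      scope_ks <- if (identical(e$scope, "FULL")) answered else {
        out <- character()
        for (el in e$scope) {
          if (el %in% answered) out <- c(out, el)
          else if (!is.null(defs$modules[[el]])) {
            out <- c(out, intersect(defs$modules[[el]]$policy_keys, answered))
          }
        }
        unique(out)
      }
      for (ks in scope_ks) carried[[ks]] <- "WITHDRAWN"
      doc_n <- doc_n + 1L
      docs[[doc_n]] <- list(
        id = sprintf("doc-%06d", doc_n), signer = e$signer,
        template = gov_all$template, tpl_version = gov_all$tpl_version,
        domain = e$domain, date = as.Date(e$date), ts = e$seq %||% doc_n,
        capture_mode = "ELECTRONIC", states = carried, invalidated = FALSE)
    } else if (e$type == "invalidate") {
      for (i in seq_along(docs)) {
        if (docs[[i]]$id == e$document_id) docs[[i]]$invalidated <- TRUE
      }
    }
  }
  list(defs = defs, docs = docs, better = better)
}

oracle_expiry <- function(defs, doc, policy_ks) {
  pparts <- oracle_key_parts(policy_ks)
  cands <- list()
  harvest <- function(props, anchor_consent, anchor_birth) {
    if (!is.null(props[["VALIDITY_FIXED_DATE"]])) {
      cands[[length(cands) + 1L]] <<- as.Date(props[["VALIDITY_FIXED_DATE"]])
    }
    if (!is.null(props[["VALIDITY_PERIOD"]])) {
      cands[[length(cands) + 1L]] <<- add_period(doc$date, props[["VALIDITY_PERIOD"]])
    }
    if (!is.null(props[["VALIDITY_PERIOD_FROM_BIRTHDATE"]])) {
      bd <- defs$birthdates[[doc$signer]]
      if (is.null(bd)) stop("oracle: missing birthdate")
      cands[[length(cands) + 1L]] <<- add_period(bd, props[["VALIDITY_PERIOD_FROM_BIRTHDATE"]])
    }
  }
  harvest(defs$domain_props[[doc$domain]] %||% list())
  tpl <- defs$templates[[doc$template]]
  if (!is.null(tpl)) {
    harvest(lapply(tpl$properties %||% list(), as.character))
    for (a in tpl$module_assignments) {
      mk <- if (is.character(a$module)) a$module else key_string(a$module)
      mod <- defs$modules[[mk]]
      if (!is.null(mod) &&
          pparts[2] %in% vapply(mod$policy_keys, function(k) oracle_key_parts(k)[2], "")) {
        harvest(lapply(mod$properties %||% list(), as.character))
      }
    }
  }
  pol <- defs$policies[[policy_ks]]
  if (!is.null(pol)) harvest(lapply(pol$properties %||% list(), as.character))
  if (!length(cands)) NULL else as.Date(min(vapply(cands, as.numeric, 0)), origin = "1970-01-01")
}

oracle_quality <- function(raw, unknown_as_decline) {
  if (raw == "ACCEPTED") return("ACCEPTED")
  if (raw %in% c("DECLINED", "WITHDRAWN", "INVALIDATED", "REFUSED", "EXPIRED")) return("DECLINED")
  if (unknown_as_decline) "DECLINED" else "UNKNOWN"
}

oracle_resolve <- function(state, signer, policy_ks, config) {
  at_date <- as.Date(config$at_date %||% Sys.Date())
  weighting <- config$weighting %||% "DATE_THEN_VERSION"
  ivn <- isTRUE(config$ignore_version_number)
  uad <- isTRUE(config$unknown_as_decline)
  pparts <- oracle_key_parts(policy_ks)
  match_entry <- function(d) {
    if (!ivn) {
      if (!is.null(d$states[[policy_ks]])) return(policy_ks)
      return(NULL)
    }
    hits <- Filter(function(ks) {
      kp <- oracle_key_parts(ks)
      kp[1] == pparts[1] && kp[2] == pparts[2]
    }, names(d$states))
    if (!length(hits)) return(NULL)
    best <- hits[[1]]
    for (h in hits) if (oracle_vcmp(oracle_key_parts(h)[3], oracle_key_parts(best)[3]) > 0) best <- h
    best
  }
  mine <- Filter(function(d) d$signer == signer && d$domain == pparts[1] &&
                   d$date <= at_date && !is.null(match_entry(d)), state$docs)
  valid <- Filter(function(d) !d$invalidated, mine)
  if (length(valid)) {
    gov <- NULL
    for (d in valid) if (is.null(gov) || state$better(d, gov, weighting)) gov <- d
    entry <- match_entry(gov)
    raw <- gov$states[[entry]]
    expiry <- oracle_expiry(state$defs, gov, entry)
    if (raw == "ACCEPTED" && !is.null(expiry) && at_date > expiry) raw <- "EXPIRED"
    return(list(raw_state = raw, quality = oracle_quality(raw, uad),
                source_document = gov$id))
  }
  if (length(mine)) {
    gov <- NULL
    for (d in mine) if (is.null(gov) || state$better(d, gov, weighting)) gov <- d
    return(list(raw_state = "INVALIDATED", quality = "DECLINED",
                source_document = gov$id))
  }
  list(raw_state = "UNKNOWN", quality = oracle_quality("UNKNOWN", uad),
       source_document = NULL)
}

#' Answer a status query by brute-force replay
#'
#' Replays the event list linearly with no indexes and answers the query
#' with an implementation independent of the engine's resolution path. Used
#' by the property-test suites as the ground truth.
#'
#' @param events A `"consent_history"` event list.
#' @param query A list with a `kind` field: `"resolve"` /`"is_consented"`
#'   (fields `signer`, `policy`, `config`), `"participants_consented_to"`
#'   (`policy`, `config`), `"policies_consented_by"` (`signer`, `domain`,
#'   `config`), or `"current_document"` (`signer`, `domain`, `config`).
#' @return For `resolve`: list with `raw_state`, `quality`,
#'   `source_document`. For `is_consented`: a logical. For the list queries:
#'   a sorted character vector (signer strings / policy key strings). For
#'   `current_document`: the governing document id or `NULL`.
#' @export
replay_oracle <- function(events, query) {
  state <- oracle_documents(events)
  config <- query$config %||% list()
  switch(query$kind,
    resolve = oracle_resolve(state, query$signer, query$policy, config),
    is_consented = identical(
      oracle_resolve(state, query$signer, query$policy, config)$quality, "ACCEPTED"),
    participants_consented_to = {
      signers <- sort(unique(vapply(
        Filter(function(d) d$domain == oracle_key_parts(query$policy)[1], state$docs),
        `[[`, "", "signer")))
      sort(Filter(function(s) {
        identical(oracle_resolve(state, s, query$policy, config)$quality, "ACCEPTED")
      }, signers))
    },
    policies_consented_by = {
      pks <- sort(Filter(function(ks) oracle_key_parts(ks)[1] == query$domain,
                         names(state$defs$policies)))
      sort(Filter(function(ks) {
        identical(oracle_resolve(state, query$signer, ks, config)$quality, "ACCEPTED")
      }, pks))
    },
    current_document = {
      at_date <- as.Date(config$at_date %||% Sys.Date())
      weighting <- config$weighting %||% "DATE_THEN_VERSION"
      mine <- Filter(function(d) d$signer == query$signer && d$domain == query$domain &&
                       !d$invalidated && d$date <= at_date, state$docs)
      if (!length(mine)) return(NULL)
      gov <- NULL
      for (d in mine) if (is.null(gov) || state$better(d, gov, weighting)) gov <- d
      gov$id
    },
    stop_consentry("InvalidSpec", sprintf("unknown query kind '%s'", query$kind))
  )
}

#' Check engine/oracle agreement over a whole history
#'
#' Resolves every (signer, policy version) pair plus the per-policy and
#' per-signer consent queries both through the engine and through
#' [replay_oracle()] and reports the first divergence, naming the signer,
#' policy and both answers — the debugging handle for the equivalence
#' property.
#'
#' @param events A `"consent_history"` event list.
#' @param config Plain list of query-config fields (see [query_config()]).
#' @return List with `ok` (logical), `n_checked`, and on failure
#'   `first_divergence`.
#' @export
oracle_agreement <- function(events, config = list()) {
  sys <- apply_history(events)
  state_domains <- unique(vapply(Filter(function(e) e$type == "create_domain", events),
                                 `[[`, "", "name"))
  n <- 0L
  for (domain in state_domains) {
    qc <- do.call(query_config, config)
    signers <- list_signers(sys, domain)
    pols <- list_policies(sys, domain, include_deprecated = TRUE)
    for (i in seq_len(nrow(signers))) {
      s <- sprintf("%s:%s", signers$id_type[i], signers$value[i])
      for (p in pols) {
        n <- n + 1L
        eng <- resolve_policy_status(sys, s, p$key, qc)
        ora <- replay_oracle(events, list(kind = "resolve", signer = s,
                                          policy = key_string(p$key), config = config))
        if (!identical(eng$raw_state, ora$raw_state) ||
            !identical(eng$quality, ora$quality) ||
            !identical(eng$source_document %||% NULL, ora$source_document %||% NULL)) {
          return(list(ok = FALSE, n_checked = n, first_divergence = list(
            signer = s, policy = key_string(p$key),
            engine = list(raw = eng$raw_state, quality = eng$quality,
                          source = eng$source_document),
            oracle = ora)))
        }
      }
      mine <- policies_consented_by(sys, s, domain, qc)
      eng_pols <- sort(sprintf("%s/%s/%s", mine$policy_domain, mine$policy_name,
                               mine$policy_version))
      ora_pols <- replay_oracle(events, list(kind = "policies_consented_by",
                                             signer = s, domain = domain, config = config))
      n <- n + 1L
      if (!identical(eng_pols, as.character(ora_pols))) {
        return(list(ok = FALSE, n_checked = n, first_divergence = list(
          signer = s, query = "policies_consented_by",
          engine = eng_pols, oracle = ora_pols)))
      }
      cur <- current_document_of(sys, s, domain, qc)
      ora_cur <- replay_oracle(events, list(kind = "current_document", signer = s,
                                            domain = domain, config = config))
      n <- n + 1L
      if (!identical(cur$document_id %||% NULL, ora_cur %||% NULL)) {
        return(list(ok = FALSE, n_checked = n, first_divergence = list(
          signer = s, query = "current_document",
          engine = cur$document_id, oracle = ora_cur)))
      }
    }
    for (p in pols) {
      qc2 <- do.call(query_config, config)
      eng_rows <- participants_consented_to(sys, p$key, qc2)
      eng_sig <- sort(sprintf("%s:%s", eng_rows$signer_id_type, eng_rows$signer_id))
      ora_sig <- replay_oracle(events, list(kind = "participants_consented_to",
                                            policy = key_string(p$key), config = config))
      n <- n + 1L
      if (!identical(eng_sig, as.character(ora_sig))) {
        return(list(ok = FALSE, n_checked = n, first_divergence = list(
          policy = key_string(p$key), query = "participants_consented_to",
          engine = eng_sig, oracle = ora_sig)))
      }
    }
  }
  list(ok = TRUE, n_checked = n)
}
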