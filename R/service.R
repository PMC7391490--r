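# Programmatic service interface: a machine-readable operation catalogue,
# a JSON request dispatcher covering every public operation, and a
# line-delimited JSON request loop that binds the dispatcher to any pair of
# connections (the CLI `serve` subcommand uses stdin/stdout). Actor identity
# is a caller-supplied string; authentication is explicitly out of scope.

.OPERATION_TABLE <- list(
  # category, needs_system, dispatchable
  consent_system = c("system", FALSE, TRUE),
  get_config = c("system", TRUE, TRUE),
  set_config = c("system", TRUE, TRUE),
  save_system = c("system", TRUE, TRUE),
  load_system = c("system", FALSE, TRUE),
  create_domain = c("registry", TRUE, TRUE),
  get_domain = c("registry", TRUE, TRUE),
  list_domains = c("registry", TRUE, TRUE),
  set_domain_property = c("registry", TRUE, TRUE),
  get_domain_property = c("registry", TRUE, TRUE),
  register_signer_id_type = c("registry", TRUE, TRUE),
  deprecate_domain = c("registry", TRUE, TRUE),
  define_policy = c("registry", TRUE, TRUE),
  get_policy = c("registry", TRUE, TRUE),
  list_policies = c("registry", TRUE, TRUE),
  update_policy = c("registry", TRUE, TRUE),
  define_module = c("registry", TRUE, TRUE),
  get_module = c("registry", TRUE, TRUE),
  list_modules = c("registry", TRUE, TRUE),
  update_module = c("registry", TRUE, TRUE),
  define_template = c("registry", TRUE, TRUE),
  get_template = c("registry", TRUE, TRUE),
  list_templates = c("registry", TRUE, TRUE),
  update_template = c("registry", TRUE, TRUE),
  finalize = c("registry", TRUE, TRUE),
  is_finalized = c("registry", TRUE, TRUE),
  deprecate_entity = c("registry", TRUE, TRUE),
  delete_draft = c("registry", TRUE, TRUE),
  free_text_field = c("registry", FALSE, TRUE),
  export_definitions = c("definitions", TRUE, TRUE),
  import_definitions = c("definitions", TRUE, TRUE),
  definitions_schema = c("definitions", FALSE, TRUE),
  consent_key = c("vocabulary", FALSE, TRUE),
  parse_key = c("vocabulary", FALSE, TRUE),
  key_string = c("vocabulary", FALSE, TRUE),
  signer_id = c("vocabulary", FALSE, TRUE),
  consent_states = c("vocabulary", FALSE, TRUE),
  quality_classes = c("vocabulary", FALSE, TRUE),
  quality_of = c("vocabulary", FALSE, TRUE),
  compare_versions = c("vocabulary", FALSE, TRUE),
  parse_version = c("vocabulary", FALSE, TRUE),
  parse_validity_period = c("vocabulary", FALSE, TRUE),
  add_period = c("vocabulary", FALSE, TRUE),
  known_property_keys = c("vocabulary", FALSE, TRUE),
  validate_properties = c("vocabulary", FALSE, TRUE),
  record_consent = c("store", TRUE, TRUE),
  record_withdrawal = c("store", TRUE, TRUE),
  invalidate_document = c("store", TRUE, TRUE),
  attach_scan = c("store", TRUE, TRUE),
  get_document = c("store", TRUE, TRUE),
  list_scans = c("store", TRUE, TRUE),
  set_signer_birthdate = c("store", TRUE, TRUE),
  get_signer_birthdate = c("store", TRUE, TRUE),
  list_signers = c("store", TRUE, TRUE),
  query_config = c("status", FALSE, TRUE),
  effective_expiry = c("status", TRUE, TRUE),
  latest_document = c("status", TRUE, TRUE),
  resolve_policy_status = c("status", TRUE, TRUE),
  is_consented = c("status", TRUE, TRUE),
  participants_consented_to = c("query", TRUE, TRUE),
  policies_consented_by = c("query", TRUE, TRUE),
  documents_missing_scan = c("query", TRUE, TRUE),
  documents_of = c("query", TRUE, TRUE),
  current_document_of = c("query", TRUE, TRUE),
  export_consented = c("query", TRUE, TRUE),
  audit_append = c("audit", TRUE, TRUE),
  audit_list = c("audit", TRUE, TRUE),
  service_health = c("service", TRUE, TRUE),
  operation_catalogue = c("service", FALSE, TRUE),
  requirements_matrix = c("conformance", FALSE, TRUE),
  requirements_coverage = c("conformance", FALSE, TRUE),
  history_spec = c("fixtures", FALSE, TRUE),
  generate_history = c("fixtures", FALSE, TRUE),
  apply_history = c("fixtures", FALSE, TRUE),
  replay_oracle = c("fixtures", FALSE, TRUE),
  oracle_agreement = c("fixtures", FALSE, TRUE),
  handle_request = c("transport", TRUE, FALSE),
  serve_requests = c("transport", TRUE, FALSE),
  cli_main = c("transport", FALSE, FALSE)
)

#' The machine-readable operation catalogue
#'
#' Introspection over the public interface: every operation the library
#' exposes, its category, whether it acts on a store, and whether the JSON
#' dispatcher serves it (the three transport entry points are listed but not
#' dispatched through themselves).
#'
#' @return Data frame with columns `operation`, `category`, `needs_system`,
#'   `dispatchable`.
#' @examples
#' nrow(operation_catalogue())
#' @export
operation_catalogue <- function() {
  data.frame(
    operation = names(.OPERATION_TABLE),
    category = vapply(.OPERATION_TABLE, `[[`, "", 1),
    needs_system = vapply(.OPERATION_TABLE, function(x) as.logical(x[2]), logical(1)),
    dispatchable = vapply(.OPERATION_TABLE, function(x) as.logical(x[3]), logical(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Service health and version information
#'
#' @param sys A [consent_system()].
#' @return List with service name, package version, store schema version,
#'   operation count and document count.
#' @export
service_health <- function(sys) {
  assert_system(sys)
  list(
    service = "consentry",
    version = as.character(utils::packageVersion("consentry")),
    schema_version = "1.0",
    operations = nrow(operation_catalogue()),
    documents = length(sys$documents)
  )
}

# recursively convert engine objects into JSON-serialisable structures
jsonable <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "Date")) return(iso_date(x))
  if (inherits(x, "POSIXct")) return(format(x, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"))
  if (is.raw(x)) return(jsonlite::base64_enc(x))
  if (is.data.frame(x)) return(x)
  if (inherits(x, "consent_system")) return(list(store = "consent_system",
                                                 documents = length(x$documents)))
  if (is.list(x)) return(lapply(unclass(x), jsonable))
  x
}

#' Dispatch one service request
#'
#' The request names a public operation and its parameters; the response
#' mirrors an HTTP exchange: status 200 with the operation's result, 400
#' with the engine's error name for rejected or malformed requests, 404 for
#' unknown operations. Every dispatchable catalogue operation is reachable
#' by exactly its own name.
#'
#' @param sys A [consent_system()] serving as the request's store.
#' @param request A list `list(operation =, params = list(...))` or a JSON
#'   string encoding the same.
#' @return A list with fields `status`, `operation`, and `result` (success)
#'   or `error` + `message` (failure).
#' @examples
#' sys <- consent_system()
#' handle_request(sys, list(operation = "consent_states"))
#' @export
handle_request <- function(sys, request) {
  assert_system(sys)
  if (is.character(request)) {
    request <- tryCatch(jsonlite::parse_json(request, simplifyVector = FALSE),
                        error = function(e) NULL)
    if (is.null(request)) {
      return(list(status = 400L, error = "MalformedRequest",
                  message = "request body is not valid JSON"))
    }
  }
  op <- request$operation
  if (!is_string(op)) {
    return(list(status = 400L, error = "MalformedRequest",
                message = "request must name an operation"))
  }
  entry <- .OPERATION_TABLE[[op]]
  if (is.null(entry) || !as.logical(entry[3])) {
    return(list(status = 404L, error = "UnknownOperation",
                message = sprintf("no dispatchable operation '%s'", op)))
  }
  params <- request$params %||% list()
  if (!is.null(params$blob) && is.character(params$blob) && !file.exists(params$blob)) {
    params$blob <- jsonlite::base64_dec(params$blob)
  }
  if (!is.null(params$config) && is.list(params$config)) {
    params$config <- do.call(query_config, params$config)
  }
  fn <- get(op, envir = asNamespace("consentry"))
  args <- if (as.logical(entry[2])) c(list(sys), params) else params
  tryCatch({
    result <- do.call(fn, args)
    list(status = 200L, operation = op, result = jsonable(result))
  }, consentry_error = function(e) {
    list(status = 400L, operation = op, error = class(e)[1],
         message = conditionMessage(e))
  }, error = function(e) {
    list(status = 400L, operation = op, error = "BadRequest",
         message = conditionMessage(e))
  })
}

#' Serve line-delimited JSON requests
#'
#' Reads one JSON request per line from `input`, dispatches it against the
#' store and writes one JSON response per line to `output`, until end of
#' input or a `{"operation": "shutdown"}` request. This is the service
#' transport; the CLI binds it to stdin/stdout.
#'
#' @param sys A [consent_system()].
#' @param input,output Connections (or paths) for requests and responses.
#' @return Number of requests served, invisibly.
#' @export
serve_requests <- function(sys, input = stdin(), output = stdout()) {
  assert_system(sys)
  if (is.character(input)) { input <- file(input, "r"); on.exit(close(input), add = TRUE) }
  if (is.character(output)) { output <- file(output, "w"); on.exit(close(output), add = TRUE) }
  n <- 0L
  repeat {
    line <- readLines(input, n = 1L, warn = FALSE)
    if (length(line) == 0L) break
    if (!nzchar(trimws(line))) next
    shutdown <- FALSE
    req <- tryCatch(jsonlite::parse_json(line, simplifyVector = FALSE),
                    error = function(e) NULL)
    if (!is.null(req) && identical(req$operation, "shutdown")) {
      resp <- list(status = 200L, operation = "shutdown", result = "bye")
      shutdown <- TRUE
    } else {
      resp <- handle_request(sys, line)
    }
    writeLines(as.character(jsonlite::toJSON(resp, auto_unbox = TRUE, null = "null",
                                             digits = NA, force = TRUE)), output)
    n <- n + 1L
    if (shutdown) break
  }
  invisible(n)
}
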