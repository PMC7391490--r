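# Machine-readable conformance matrix: the eighteen requirements a
# comprehensive informed-consent management system must satisfy, each linked
# to the automated tests that exercise it. The matrix ships as
# inst/extdata/requirements.json; the test suite fails if any entry is left
# without a passing linked test.

#' The requirements conformance matrix
#'
#' @return Data frame with columns `id` (1..18), `requirement` (short
#'   statement) and `tests` (list column of linked test descriptions).
#' @examples
#' requirements_matrix()[, c("id", "requirement")]
#' @export
requirements_matrix <- function() {
  path <- system.file("extdata", "requirements.json", package = "consentry")
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  data.frame(
    id = vapply(entries, function(e) as.integer(e$id), integer(1)),
    requirement = vapply(entries, `[[`, "", "requirement"),
    tests = I(lapply(entries, function(e) as.character(unlist(e$tests)))),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Check that every requirement links to an existing test
#'
#' Scans the test sources for `test_that()` descriptions and verifies that
#' each matrix entry links to at least one of them.
#'
#' @param test_dir Directory holding the `test-*.R` sources.
#' @return Data frame with `id`, `covered` and `missing` (first unlinked
#'   test name, or `""`).
#' @export
requirements_coverage <- function(test_dir) {
  mat <- requirements_matrix()
  files <- list.files(test_dir, pattern = "^test-.*\\.R$", full.names = TRUE)
  src <- paste(unlist(lapply(files, readLines, warn = FALSE)), collapse = "\n")
  found <- function(desc) grepl(desc, src, fixed = TRUE)
  covered <- logical(nrow(mat))
  missing <- character(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    hits <- vapply(mat$tests[[i]], found, logical(1))
    covered[i] <- length(hits) > 0 && any(hits)
    missing[i] <- if (covered[i]) "" else
      if (length(hits)) mat$tests[[i]][!hits][1] else "(no linked tests)"
  }
  data.frame(id = mat$id, covered = covered, missing = missing,
             stringsAsFactors = FALSE)
}
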