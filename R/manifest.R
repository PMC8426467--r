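#' Run manifests
#'
#' Every operation that creates, moves, deletes or replaces files writes a
#' JSON manifest (`histotile_manifest.json`) beside its output root, recording
#' the operation name, its parameters, the effective random seed (if any) and
#' one action entry per file touched. Manifests make any derived image set
#' traceable back to its sources.
#'
#' @param operation Name of the operation (e.g. `"patch"`, `"balance"`).
#' @param parameters Named list of the parameters the operation ran with.
#' @param actions Tibble with columns `src`, `action`
#'   (one of `created`, `moved`, `deleted`, `replaced`) and `dst`
#'   (`""` where not applicable).
#' @param seed Integer seed used, or `NULL` for unseeded operations.
#' @param dir Directory the manifest is written into.
#' @return Path of the written manifest, invisibly.
#' @name run_manifest
NULL

manifest_actions <- function(src = character(), action = character(),
                             dst = character()) {
  stopifnot(all(action %in% c("created", "moved", "deleted", "replaced")))
  tibble::tibble(src = as.character(src), action = as.character(action),
                 dst = as.character(dst))
}

#' @rdname run_manifest
#' @export
write_manifest <- function(dir, operation, parameters = list(),
                           actions = manifest_actions(), seed = NULL) {
  stopifnot(dir.exists(dir))
  payload <- list(
    operation = operation,
    parameters = parameters,
    seed = if (is.null(seed)) NULL else as.integer(seed),
    actions = as.data.frame(actions)
  )
  path <- file.path(dir, "histotile_manifest.json")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname run_manifest
#' @param path Path to a manifest file.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$actions <- tibble::as_tibble(m$actions)
  if (nrow(m$actions) == 0) m$actions <- manifest_actions()
  m
}
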