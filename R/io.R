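#' Read a pathway model from a YAML config file
#'
#' The config has top-level keys `fixed` (acetyl_coa, g3p, c16_1_acp,
#' ppgpp), `acp_total`, and `reactions` (one block per reaction with `vmax`,
#' `km_a`, optional `km_b`, `ki_ppgpp`, and `inhibitors` as a list of
#' `{species, ki}`).  Omitted fixed inputs fall back to the defaults of
#' [fixed_inputs()]; every invariant is checked at load and violations are
#' reported with the offending key.  Round-trips losslessly with
#' [write_model_config()].
#'
#' @param path Path to a YAML file.
#' @return A validated [pathway_model()].
#' @export
parse_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  allowed <- c("fixed", "acp_total", "reactions")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$reactions)) stop("config missing 'reactions'",
                                   call. = FALSE)
  kin <- lapply(cfg$reactions, function(k) {
    if (!is.null(k$inhibitors)) {
      k$inhibitors <- data.frame(
        species = vapply(k$inhibitors, `[[`, character(1), "species"),
        ki = vapply(k$inhibitors, function(x) as.numeric(x$ki), numeric(1))
      )
    }
    k
  })
  fixed <- do.call(fixed_inputs, as.list(cfg$fixed %||% list()))
  pathway_model(kinetics = kin, fixed = fixed,
                acp_total = cfg$acp_total %||% 30)
}

#' Write a pathway model to a YAML config file
#'
#' @param model A [pathway_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "pathway_model"))
  kin <- lapply(model$kinetics, function(k) {
    if (!is.null(k$inhibitors)) {
      k$inhibitors <- lapply(seq_len(nrow(k$inhibitors)), function(i) {
        list(species = k$inhibitors$species[i], ki = k$inhibitors$ki[i])
      })
    }
    k
  })
  cfg <- list(fixed = unclass(model$fixed), acp_total = model$acp_total,
              reactions = kin)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read / write a condition table as TSV
#'
#' Tab-delimited, UTF-8, Unix newlines; columns as documented in
#' [correlation_report()].
#'
#' @param path File path.
#' @return `read_condition_table()`: a validated condition-table tibble.
#' @export
read_condition_table <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  .check_condition_table(tb)
}

#' @rdname read_condition_table
#' @param table A condition table.
#' @export
write_condition_table <- function(table, path) {
  .check_condition_table(table)
  readr::write_tsv(table, path)
  invisible(path)
}

#' Export a result table to TSV plus a JSON summary with provenance
#'
#' Writes the tabular result with deterministic column order and floats at
#' 12 significant digits, and a JSON sidecar carrying a provenance record
#' (package version, content hash, seed if the object records one).
#'
#' @param result A data frame result (scan, report, trajectories, ...).
#' @param path Output TSV path; the JSON summary goes to `<path>.json`.
#' @param seed Optional seed to record in the provenance block.
#' @return Invisibly, the provenance list.
#' @export
export_results <- function(result, path, seed = NULL) {
  stopifnot(is.data.frame(result))
  out <- as.data.frame(result)  # column order preserved from the result
  is_listcol <- vapply(out, is.list, logical(1))
  out[is_listcol] <- lapply(out[is_listcol], function(col) {
    vapply(col, function(x) paste(x, collapse = ";"), character(1))
  })
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 12))
  readr::write_tsv(tibble::as_tibble(out), path)
  prov <- list(
    package = "lipidflux",
    version = as.character(utils::packageVersion("lipidflux")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    rows = nrow(out),
    columns = names(out),
    content_hash = rlang::hash(out),
    seed = seed %||% attr(result, "seed")
  )
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(prov)
}

#' @importFrom rlang .data %||%
NULL
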