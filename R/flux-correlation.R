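# Condition tables are tidy tibbles with one row per (condition, biological
# replicate, sampling replicate, analyte):
#   condition  chr   growth-condition label (e.g. carbon source)
#   bio_rep    chr/int  biological replicate series
#   tech_rep   chr/int  sampling replicate within the culture
#   mu         dbl   specific growth rate (1/h), > 0
#   od         dbl   optical density at sampling, > 0
#   analyte    chr   analyte id ("total_pe" rows carry the summed PE signal)
#   counts     dbl   raw LC/MS counts, >= 0
#   is_counts  dbl   matched internal-standard counts, > 0
#   class      chr   "soluble", "enzyme", "pl_intermediate" or "total_pe"

CONDITION_TABLE_COLS <- c("condition", "bio_rep", "tech_rep", "mu", "od",
                          "analyte", "counts", "is_counts", "class")

.check_condition_table <- function(table) {
  missing_cols <- setdiff(CONDITION_TABLE_COLS, names(table))
  if (length(missing_cols)) {
    stop("condition table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(table$mu <= 0) || any(table$od <= 0)) {
    stop("mu and od must be positive", call. = FALSE)
  }
  if (any(table$counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (!any(table$class == "total_pe")) {
    stop("condition table needs total_pe rows (the PL-flux basis)",
         call. = FALSE)
  }
  invisible(table)
}

#' Operational phospholipid flux
#'
#' The steady-state PL synthesis rate proxy: total PE signal multiplied by
#' the specific growth rate.  Valid because PE turnover is slow relative to
#' synthesis and the PG/PE ratio is stable, so new PE tracks new membrane.
#'
#' @param total_pe_counts Total-PE LC/MS counts (or internal-standard
#'   ratio), nonnegative; vectorized.
#' @param mu Specific growth rate (1/h), nonnegative; vectorized.
#' @return `total_pe_counts * mu` (counts/h).
#' @examples
#' compute_pl_flux(1e6, 0.5)
#' @export
compute_pl_flux <- function(total_pe_counts, mu) {
  if (any(total_pe_counts < 0) || any(mu < 0)) {
    stop("total_pe_counts and mu must be nonnegative", call. = FALSE)
  }
  total_pe_counts * mu
}

# per-sample internal-standard ratio and basis denominators
.sample_ratios <- function(table) {
  tot <- dplyr::filter(table, .data$class == "total_pe")
  tot <- dplyr::transmute(tot, .data$condition, .data$bio_rep, .data$tech_rep,
                          total_pe_ratio = .data$counts / .data$is_counts)
  dplyr::left_join(
    dplyr::mutate(table, ratio = .data$counts / .data$is_counts),
    tot,
    by = c("condition", "bio_rep", "tech_rep")
  )
}

#' Normalize one analyte's series across conditions
#'
#' Applies the study's normalization conventions: internal-standard ratio
#' first, then division by the volume basis (OD for soluble metabolites and
#' enzymes, whose concentrations live in cell volume; total PE for PL
#' intermediates, whose concentrations live in membrane volume), averaging
#' of sampling replicates, then log2 transformation centred on the
#' across-series geometric mean (so included points average to zero on the
#' log2 scale).  Excluded conditions are dropped before centering.
#'
#' @param table A condition table (see package docs for the column
#'   contract).
#' @param analyte Analyte id to normalize.
#' @param basis `"per_od"` or `"per_total_pe"`.
#' @param exclude_conditions Condition labels to drop before centering.
#' @param pool `"bio"` keeps biological replicate series as separate points
#'   (one value per condition x bio_rep, the default, matching n = 12 for
#'   6 media x 2 series); `"condition"` averages everything within a
#'   condition.
#' @return A tibble of class `normalized_series`: `condition`, `bio_rep`
#'   (if `pool = "bio"`), `log2_value` with mean 0 over included rows.
#' @export
normalize_series <- function(table, analyte,
                             basis = c("per_od", "per_total_pe"),
                             exclude_conditions = character(0),
                             pool = c("bio", "condition")) {
  basis <- match.arg(basis)
  pool <- match.arg(pool)
  .check_condition_table(table)
  d <- .sample_ratios(table)
  d <- dplyr::filter(d, .data$analyte == !!analyte)
  if (!nrow(d)) stop("analyte not present in table: ", analyte, call. = FALSE)
  d$value <- switch(basis,
    per_od = d$ratio / d$od,
    per_total_pe = d$ratio / d$total_pe_ratio
  )
  bad <- !is.finite(d$value)
  if (any(bad)) {
    warning("dropping ", sum(bad), " sample(s) of ", analyte,
            " with zero/invalid denominator", call. = FALSE)
    d <- d[!bad, ]
  }
  d <- dplyr::filter(d, !(.data$condition %in% exclude_conditions))
  keys <- if (pool == "bio") c("condition", "bio_rep") else "condition"
  d <- dplyr::summarise(dplyr::group_by(d, dplyr::across(dplyr::all_of(keys))),
                        value = mean(.data$value), .groups = "drop")
  # centre in log space (divide by the geometric mean) so the included
  # points always average to exactly zero on the log2 scale
  d$log2_value <- log2(d$value) - mean(log2(d$value))
  out <- d[, c(keys, "log2_value")]
  class(out) <- c("normalized_series", class(out))
  attr(out, "analyte") <- analyte
  attr(out, "basis") <- basis
  out
}

# normalized log2 PL-flux series on the same replicate grid
.flux_series <- function(table, pool = "bio") {
  d <- .sample_ratios(table)
  d <- dplyr::filter(d, .data$class == "total_pe")
  d$flux <- compute_pl_flux(d$ratio / d$od, d$mu)
  keys <- if (pool == "bio") c("condition", "bio_rep") else "condition"
  d <- dplyr::summarise(dplyr::group_by(d, dplyr::across(dplyr::all_of(keys))),
                        flux = mean(.data$flux), .groups = "drop")
  d$log2_flux <- log2(d$flux) - mean(log2(d$flux))
  d[, c(keys, "log2_flux")]
}

#' Pearson correlation with two-tailed t significance
#'
#' Sample Pearson correlation and the two-tailed P value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` against Student's t with `n - 2`
#' degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, each with nonzero
#'   variance.
#' @return One-row tibble: `r`, `n`, `p`.
#' @examples
#' pearson_with_significance(1:4, c(2, 4, 5, 9))
#' @export
pearson_with_significance <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) {
    0
  } else {
    tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(r = r, n = n, p = p)
}

#' Per-analyte correlation of abundance with phospholipid flux
#'
#' For every configured analyte: normalize its across-condition series on
#' the class-appropriate volume basis, normalize the PL-flux series the same
#' way, and report the Pearson correlation with its two-tailed significance.
#' Per-analyte condition exclusions (e.g. the glycerol condition for G3P,
#' where catabolic supply inflates G3P without raising flux) are applied to
#' both series before centering.
#'
#' @param table A condition table.
#' @param config Optional tibble with columns `analyte`, `basis`, and
#'   optionally a list-column `exclude` of condition labels.  By default
#'   every non-`total_pe` analyte in the table is used, with basis
#'   `per_total_pe` for class `pl_intermediate` and `per_od` otherwise.
#' @param pool Replicate pooling, see [normalize_series()].
#' @return A tibble of class `correlation_report`: `analyte`, `basis`, `n`,
#'   `r`, `p`, `excluded` (list-column).  Analytes configured but missing
#'   from the table are skipped with a warning.
#' @export
correlation_report <- function(table, config = NULL,
                               pool = c("bio", "condition")) {
  pool <- match.arg(pool)
  .check_condition_table(table)
  if (is.null(config)) {
    cls <- dplyr::distinct(table[table$class != "total_pe", ],
                           .data$analyte, .data$class)
    config <- tibble::tibble(
      analyte = cls$analyte,
      basis = ifelse(cls$class == "pl_intermediate",
                     "per_total_pe", "per_od"),
      exclude = vector("list", nrow(cls))
    )
  }
  if (!"exclude" %in% names(config)) {
    config$exclude <- vector("list", nrow(config))
  }
  flux <- .flux_series(table, pool = pool)
  keys <- if (pool == "bio") c("condition", "bio_rep") else "condition"
  present <- unique(table$analyte)
  rows <- purrr::pmap(config, function(analyte, basis, exclude, ...) {
    if (!analyte %in% present) {
      warning("analyte missing from table, skipped: ", analyte,
              call. = FALSE)
      return(NULL)
    }
    excl <- if (is.null(exclude)) character(0) else as.character(exclude)
    ser <- normalize_series(table, analyte, basis = basis,
                            exclude_conditions = excl, pool = pool)
    fl <- dplyr::filter(flux, !(.data$condition %in% excl))
    fl$log2_flux <- fl$log2_flux - mean(fl$log2_flux)  # recentre after drops
    j <- dplyr::inner_join(ser, fl, by = keys)
    st <- tryCatch(pearson_with_significance(j$log2_value, j$log2_flux),
                   error = function(e) {
                     tibble::tibble(r = NA_real_, n = nrow(j), p = NA_real_)
                   })
    tibble::tibble(analyte = analyte, basis = basis, n = st$n,
                   r = st$r, p = st$p, excluded = list(excl))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("correlation_report", class(out))
  out
}
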