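# Internal helpers shared across the pipeline.

DAYS_PER_MONTH <- 365.25 / 12

RACE_LEVELS <- c("Asian NH", "Black NH", "Hispanic", "White NH", "Other NH")
INSURANCE_LEVELS <- c("commercial", "Medicaid", "Medicare", "other")
SEX_LEVELS <- c("male", "female")
COMORBIDITIES <- c("diabetes", "dyslipidemia", "hypertension")

#' Derive a sub-stream seed from a master seed
#'
#' All randomness in the package flows from one master seed; each stage draws
#' from its own sub-stream so that changing one stage's consumption of random
#' numbers does not perturb the others. Streams are indexed by a small
#' non-negative offset and kept inside the 32-bit integer range.
#'
#' @param seed master integer seed
#' @param offset non-negative integer stream index
#' @return an integer usable with [set.seed()]
#' @keywords internal
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + 7919 * offset) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_date <- function(x) as.Date(x, origin = "1970-01-01")

#' Standardized mean difference between two groups
#'
#' Pooled-SD standardized difference for a numeric (or 0/1) covariate;
#' the usual balance diagnostic for matched cohorts.
#'
#' @param x covariate values
#' @param g logical/0-1 group indicator (TRUE = treated)
#' @return absolute standardized mean difference (0 when both SDs are 0)
#' @export
smd <- function(x, g) {
  g <- as.logical(g)
  x1 <- x[g & !is.na(x)]
  x0 <- x[!g & !is.na(x)]
  s2 <- (stats::var(x1) + stats::var(x0)) / 2
  if (!is.finite(s2) || s2 <= 0) return(0)
  abs(mean(x1) - mean(x0)) / sqrt(s2)
}

# Last value of `value` on or before `at` within `lookback` days; NA if none.
# `dates`/`values` belong to one person and need not be sorted.
last_value_before <- function(dates, values, at, lookback = 365) {
  ok <- !is.na(dates) & dates <= at & dates >= at - lookback
  if (!any(ok)) return(NA_real_)
  values[ok][which.max(dates[ok])]
}

# Simple append-only log used by the pipeline for auditable attrition.
new_log <- function() {
  env <- new.env(parent = emptyenv())
  env$lines <- character(0)
  env$counts <- list()
  env
}

log_msg <- function(log, ..., verbose = FALSE) {
  if (is.null(log)) return(invisible(NULL))
  line <- paste0(...)
  log$lines <- c(log$lines, line)
  if (verbose) message(line)
  invisible(NULL)
}

log_count <- function(log, stage, n, note = "") {
  if (is.null(log)) return(invisible(NULL))
  log$counts[[length(log$counts) + 1L]] <-
    list(stage = stage, n = as.integer(n), note = note)
  log_msg(log, sprintf("[count] %s: %d%s", stage, n,
                       if (nzchar(note)) paste0(" (", note, ")") else ""))
  invisible(NULL)
}

counts_df <- function(log) {
  if (is.null(log) || length(log$counts) == 0) {
    return(data.frame(stage = character(0), n = integer(0),
                      note = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    stage = vapply(log$counts, `[[`, "", "stage"),
    n = vapply(log$counts, `[[`, 0L, "n"),
    note = vapply(log$counts, `[[`, "", "note"),
    stringsAsFactors = FALSE
  )
}
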