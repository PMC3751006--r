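#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves carried away from zero,
#' the convention used for all reported parameter values (e.g. a computed
#' utility of 0.6785 is reported as 0.679).  Base [round()] uses banker's
#' rounding and would give 0.678.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## internal: assert a scalar/vector lies in [0, 1], naming the field
check_probability <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]; got %s",
                 field, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

check_nonnegative <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop(sprintf("'%s' must be non-negative; got %s",
                 field, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

## recursive list merge: values in 'override' win; new keys are appended
merge_lists <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}
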