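#' Read a life table from a delimited text file
#'
#' The file format is two tab- (or comma-) separated columns with a header:
#' `age` (integer) and `qx` (annual all-cause death probability).
#'
#' @param path path to the life-table file.
#' @return a `dm_life_table`: a data.frame with columns `age` and `qx`.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life-table file not found: ", path)
  lt <- utils::read.delim(path, sep = "", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("age", "qx") %in% names(lt)))
    stop("life-table file must have header columns 'age' and 'qx'")
  as_life_table(lt[, c("age", "qx")])
}

#' Write a life table to a delimited text file
#'
#' @param life_table a `dm_life_table`.
#' @param path output path; tab-separated with header.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(life_table, path) {
  stopifnot(inherits(life_table, "dm_life_table"))
  ## %.17g round-trips doubles exactly through the text file
  lines <- c("age\tqx",
             sprintf("%d\t%.17g", life_table$age, life_table$qx))
  writeLines(lines, path)
  invisible(path)
}

#' Coerce to a life table
#'
#' @param x data.frame with integer `age` and probability `qx` columns.
#' @return a validated `dm_life_table`.
#' @export
as_life_table <- function(x) {
  stopifnot(is.data.frame(x), all(c("age", "qx") %in% names(x)))
  x$age <- as.integer(x$age)
  check_probability(x$qx, "qx")
  if (any(diff(x$age) != 1L))
    stop("life table must cover consecutive integer ages")
  x <- x[, c("age", "qx")]
  class(x) <- c("dm_life_table", "data.frame")
  x
}

#' Bundled synthetic life-table fixture
#'
#' Returns the frozen Gompertz-Makeham life table shipped with the package
#' (ages 25-100), generated by [generate_life_table()] with the default
#' [life_table_spec()].  It is a synthetic stand-in calibrated so residual
#' life expectancy at ages 25/40/60 is plausible for a contemporary Chinese
#' population (roughly 52/38/20 years); it is not an official national
#' table.
#'
#' @return a `dm_life_table`.
#' @export
default_life_table <- function() {
  path <- system.file("extdata", "life_table_synthetic.tsv",
                      package = "dmprevent", mustWork = TRUE)
  read_life_table(path)
}

## internal: vector of qx for ages start .. start+n-1, with range check
qx_lookup <- function(life_table, ages) {
  idx <- match(ages, life_table$age)
  if (anyNA(idx))
    stop("life table does not cover ages ",
         paste(ages[is.na(idx)], collapse = ", "))
  life_table$qx[idx]
}

#' Life-table generator specification
#'
#' Parameters of the Gompertz-Makeham mortality law used to synthesise the
#' background all-cause mortality schedule:
#' `qx(age) = 1 - exp(-(a + b * c^age))`, where `a` is the age-independent
#' (Makeham) hazard, `b` the Gompertz hazard scale and `c` the per-year
#' hazard growth factor.
#'
#' @param model `"gompertz_makeham"` (the only built-in law).
#' @param makeham_a age-independent annual hazard (default 5e-4).
#' @param gompertz_b Gompertz hazard scale (default 3e-5).
#' @param gompertz_c Gompertz exponent base (default 1.094).
#' @param age_range integer `c(min, max)` of tabulated ages.
#' @return a `dm_life_table_spec` list.
#' @export
life_table_spec <- function(model = "gompertz_makeham",
                            makeham_a = 5e-4,
                            gompertz_b = 3e-5,
                            gompertz_c = 1.094,
                            age_range = c(25L, 100L)) {
  model <- match.arg(model)
  spec <- list(model = model, makeham_a = makeham_a,
               gompertz_b = gompertz_b, gompertz_c = gompertz_c,
               age_range = as.integer(age_range))
  class(spec) <- "dm_life_table_spec"
  spec
}

#' Generate a synthetic life table
#'
#' Tabulates the annual death probability per integer age from a
#' Gompertz-Makeham specification.  The default specification is the frozen
#' fixture used throughout the package.
#'
#' @param spec a [life_table_spec()].
#' @return a `dm_life_table`.
#' @export
#' @examples
#' lt <- generate_life_table()
#' plot(lt$age, lt$qx, type = "l", log = "y")
generate_life_table <- function(spec = life_table_spec()) {
  stopifnot(inherits(spec, "dm_life_table_spec"))
  ages <- seq.int(spec$age_range[1], spec$age_range[2])
  hz <- spec$makeham_a + spec$gompertz_b * spec$gompertz_c^ages
  qx <- 1 - exp(-hz)
  if (any(qx <= 0 | qx >= 1))
    stop("life-table spec produces qx outside (0, 1)")
  lt <- as_life_table(data.frame(age = ages, qx = qx))
  over30 <- lt$age >= 30
  if (any(diff(lt$qx[over30]) < 0))
    stop("life-table spec produces non-monotone qx above age 30")
  lt
}

#' Horizon-capped expected survival from a life table
#'
#' Deterministic product-limit expectation of half-cycle-weighted years
#' alive over `horizon` annual cycles for a subject facing only the
#' life-table mortality.  Used as a calibration check on the synthetic
#' fixture.
#'
#' @param life_table a `dm_life_table`.
#' @param start_age initiation age.
#' @param horizon number of annual cycles.
#' @return expected years alive (0.5 + sum of survival probabilities at
#'   cycles 1..horizon-1 + 0.5 * survival at horizon).
#' @export
expected_survival_years <- function(life_table, start_age, horizon = 40L) {
  qx <- qx_lookup(life_table, start_age + seq_len(horizon) - 1L)
  surv <- cumprod(1 - qx)               # P(alive at cycle t), t = 1..horizon
  w <- c(rep(1, horizon - 1L), 0.5)
  0.5 + sum(w * surv)
}
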