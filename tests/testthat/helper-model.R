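## Shared fixtures: built in code, no external data.

## life table with constant annual death probability q over ages 20..105
flat_life_table <- function(q) {
  as_life_table(data.frame(age = 20:105, qx = q))
}

## default parameters with arbitrary nested overrides
params_with <- function(...) {
  load_parameters(overrides = list(...))
}

## parameters in which nothing ever moves: all disease transitions zero
frozen_params <- function() {
  strat0 <- function(st) {
    st$igt_to_dm[] <- 0
    st$complication_incidence[] <- 0
    st$complication_mortality[] <- 0
    st
  }
  p <- unclass(default_parameters())
  p$shared$normal_to_igt <- 0
  p$shared$igt_to_normal <- 0
  p$strategies <- lapply(p$strategies, strat0)
  class(p) <- "dm_parameters"
  p
}

## the bundled fixture, read once per test file
fixture_lt <- local({
  lt <- NULL
  function() {
    if (is.null(lt)) lt <<- default_life_table()
    lt
  }
})

## qx at a single age from a life table (tests' own lookup)
qx_lookup_test <- function(lt, age) lt$qx[match(age, lt$age)]
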