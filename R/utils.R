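#' @importFrom data.table data.table as.data.table setorder setorderv rbindlist
#' @importFrom data.table := .N .SD setnames setkeyv fifelse shift copy
#' @importFrom stats rexp rpois runif rbinom setNames
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `code` with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a stream-specific seed from a master seed, kept within 32-bit range.
derive_seed <- function(seed, salt) {
  (as.integer(seed) + 7919L * as.integer(salt)) %% 2147483587L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Canonical unordered pair: a < b element-wise (ids are character or integer).
order_pair <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(a = a, b = b)
}

WEEKDAYS <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
              "Saturday", "Sunday")

# Weekday name for day index `day` (1-based) when day 1 falls on `day0`.
weekday_of <- function(day, day0) {
  i0 <- match(day0, WEEKDAYS)
  WEEKDAYS[((i0 - 1L + day - 1L) %% 7L) + 1L]
}
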