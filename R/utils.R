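# internal validation / misc helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, kind = c("numeric", "integerish"),
                         lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  kind <- match.arg(kind)
  if (length(x) != 1L || !is.numeric(x) || is.na(x))
    stop_bad(sprintf("`%s` must be a single non-missing number", name))
  if (kind == "integerish" && x != as.integer(x))
    stop_bad(sprintf("`%s` must be a whole number", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_bad(sprintf("`%s` = %g is outside its valid range", name, x))
  invisible(x)
}

check_flag <- function(x, name) {
  if (length(x) != 1L || !is.logical(x) || is.na(x))
    stop_bad(sprintf("`%s` must be TRUE or FALSE", name))
  invisible(x)
}

# set.seed only when a seed is supplied; NULL means "use the current RNG
# stream" so nested generators can share one seeded run
maybe_seed <- function(seed) {
  if (!is.null(seed)) {
    check_scalar(seed, "seed", "integerish")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

#' Derive a replicate seed from a master seed
#'
#' Counter-based scheme used by every sweep and scenario runner: replicate
#' `index` of a run with `master_seed` is simulated under
#' `child_seed(master_seed, index)`. The map is deterministic, stays inside
#' the 32-bit integer range R requires of `set.seed()`, and separates
#' consecutive indices widely so replicate streams do not overlap trivially.
#'
#' @param master_seed integer master seed of the whole experiment.
#' @param index positive integer replicate counter (1, 2, ...).
#' @return A single integer seed.
#' @examples
#' child_seed(1, 1:3)
#' @export
child_seed <- function(master_seed, index) {
  check_scalar(master_seed, "master_seed", "integerish")
  m <- as.double(master_seed) %% 2147483647
  as.integer((m * 48271 + as.double(index) * 2654435761) %% 2147483647) + 1L
}

# fixed-precision numeric formatting for byte-stable CSV bodies
format_num <- function(x, digits = 9L) {
  out <- formatC(x, digits = digits, format = "g")
  out[is.na(x)] <- "NA"
  out
}
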