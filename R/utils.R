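#' Derive a named RNG substream seed from a master seed
#'
#' Each stochastic operation in the package draws its random numbers from a
#' substream whose seed is a deterministic function of a master seed and the
#' operation's name. Reordering pipeline stages therefore never changes the
#' numbers any single stage produces.
#'
#' @param master Integer master seed.
#' @param name Character scalar naming the substream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.character(name), length(name) == 1L, nzchar(name))
  m <- 2147483647 # 2^31 - 1, keeps derived seeds valid 32-bit integers
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% m
  as.integer((abs(master) %% m * 48271 + h) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert genome size between picograms and gigabases
#'
#' Flow-cytometry genome sizes are reported in picograms of DNA while
#' sequence-based quantities are in gigabases. The conversion constant
#' (1 pg = 0.978 Gb) is exposed so an alternative can be supplied.
#'
#' @param x Numeric vector of genome sizes.
#' @param gb_per_pg Gigabases per picogram.
#' @return Numeric vector in the other unit.
#' @export
pg_to_gb <- function(x, gb_per_pg = 0.978) x * gb_per_pg

#' @rdname pg_to_gb
#' @export
gb_to_pg <- function(x, gb_per_pg = 0.978) x / gb_per_pg

check_fraction <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  if (!ok) stop(sprintf("'%s' must be a fraction in %s", name,
                        if (open) "(0,1)" else "[0,1]"), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && all(is.finite(x)) && all(x >= min) &&
    all(x == round(x))
  if (!ok) stop(sprintf("'%s' must be an integer count >= %d", name, min),
                call. = FALSE)
  invisible(x)
}
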