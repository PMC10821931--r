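# Internal helpers shared across modules.

# Canonical order of the ten per-molecule blinking statistics.
.STAT_NAMES <- c("N_I", "I_min", "I_max", "I_t_avg",
                 "t_on_seg", "t_off_seg", "t_on_int", "t_off_int",
                 "N_on_seg", "N_off_seg")

#' Names of the ten blinking statistics
#'
#' Returns the canonical column order used for statistic tables and classifier
#' feature matrices: number of distinct intensities `N_I`, minimum and maximum
#' emissive intensities `I_min`/`I_max` (counts/bin), time-averaged intensity
#' `I_t_avg`, mean on/off segment durations `t_on_seg`/`t_off_seg` (s), mean
#' on/off interval durations `t_on_int`/`t_off_int` (s), and on/off segment
#' counts `N_on_seg`/`N_off_seg`.
#'
#' @return Character vector of length 10.
#' @export
statNames <- function() .STAT_NAMES

# Deterministic derivation of per-molecule / per-replicate seeds from one
# master seed. Kept strictly below 2^31 - 1 so set.seed() accepts the result.
deriveSeed <- function(master, index, salt = 0L) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 +
                as.numeric(index) * 100003 +
                as.numeric(salt) * 7919) %% 2147483647)
}

# x * log(x / m) with the 0 * log(0) = 0 convention (Poisson profile
# log-likelihood terms).
xlogx <- function(s, m) {
  out <- numeric(length(s))
  pos <- s > 0
  out[pos] <- s[pos] * log(s[pos] / m[pos])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
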