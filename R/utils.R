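`%||%` <- function(x, y) if (is.null(x)) y else x

# meanlog/sdlog of a log-normal with given arithmetic mean and sd
lnorm_params <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(list(meanlog = log(mean), sdlog = 0))
  sdlog2 <- log1p((sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

is_spd_2x2 <- function(m) {
  is.matrix(m) && all(dim(m) == c(2L, 2L)) &&
    isTRUE(all.equal(m[1, 2], m[2, 1])) &&
    m[1, 1] > 0 && (m[1, 1] * m[2, 2] - m[1, 2]^2) > 0
}

abort_validation <- function(msg) stop(structure(
  class = c("evplex_validation_error", "error", "condition"),
  list(message = msg, call = NULL)
))

abort_insufficient <- function(msg) stop(structure(
  class = c("evplex_insufficient_data_error", "error", "condition"),
  list(message = msg, call = NULL)
))

abort_format <- function(msg) stop(structure(
  class = c("evplex_format_error", "error", "condition"),
  list(message = msg, call = NULL)
))
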