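# Error conditions: validation errors (bad inputs, exit code 2 at the CLI)
# vs computation errors (well-formed inputs on which the statistic is
# undefined, exit code 3).

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("allochrony_validation_error", "allochrony_error")))
}

stop_compute <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("allochrony_compute_error", "allochrony_error")))
}

# near-integer check tolerant of float representation of k * (1/3)
is_near_integer <- function(x, tol = 1e-6) {
  abs(x - round(x)) < tol
}
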