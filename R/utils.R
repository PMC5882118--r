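# internal helpers shared across modules

# round half away from zero (the convention used for reported risks and
# accuracies; base round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)

is_prob <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1

check_prob <- function(x, name) {
  if (!is_prob(x)) stop_param(sprintf("'%s' must be a single probability in [0, 1]", name))
  invisible(x)
}
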