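# Internal helpers shared across modules. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integerish = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    abort(sprintf("`%s` must be supplied", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort(sprintf("`%s` must be a whole number", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  }
  invisible(x)
}

check_columns <- function(df, cols, name) {
  if (!is.data.frame(df)) abort(sprintf("`%s` must be a data frame", name))
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  name, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# sample sd that returns 0 instead of NA for length-1 input
sample_sd <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

sem <- function(x) sample_sd(x) / sqrt(length(x))

# Welch two-sample t with a defined answer for zero-variance groups:
# identical constant groups give t = 0, p = 1; constant groups with
# different means give t = +/-Inf, p = 0.
welch_t <- function(x, y) {
  if (sample_sd(x) == 0 && sample_sd(y) == 0) {
    d <- mean(x) - mean(y)
    if (d == 0) {
      return(list(statistic = 0, df = length(x) + length(y) - 2, p_value = 1))
    }
    return(list(statistic = sign(d) * Inf,
                df = length(x) + length(y) - 2, p_value = 0))
  }
  ht <- stats::t.test(x, y)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}
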