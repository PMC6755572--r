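# internal numerical helpers

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  m <- max(x)
  if (!is.finite(m)) return(m)  # all -Inf (or contains +Inf)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gknn <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "gknn_error")))
}

check_scores <- function(x, what = "activity score") {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_gknn(what, " values must lie in [0, 1]", class = "gknn_value_error")
  invisible(x)
}
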