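# Classed conditions so callers (and the CLI) can distinguish failure modes.

cbct_abort <- function(class, message, ...) {
  stop(structure(
    class = c(class, "cbctnav_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

cbct_check <- function(ok, class, message) {
  if (!isTRUE(ok)) cbct_abort(class, message)
  invisible(TRUE)
}

as_point3 <- function(x, what = "point") {
  x <- as.numeric(x)
  cbct_check(length(x) == 3 && all(is.finite(x)), "cbctnav_validation",
             sprintf("%s must be a finite 3-vector", what))
  x
}

as_points_matrix <- function(x, what = "points") {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, lapply(x, as.numeric))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  cbct_check(ncol(x) == 3 && all(is.finite(x)), "cbctnav_validation",
             sprintf("%s must be an n x 3 matrix of finite coordinates", what))
  x
}
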