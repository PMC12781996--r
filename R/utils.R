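#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(class = c("organoidrig_invalid_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_illegal_state <- function(...) {
  stop(structure(class = c("organoidrig_illegal_state", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate a polynomial given coefficients in descending degree
#'
#' @param coeffs numeric vector, highest degree first.
#' @param x numeric vector of evaluation points.
#' @return numeric vector of polynomial values.
#' @examples
#' polyval(c(1, 0, -2), 3)  # x^2 - 2 at x = 3
#' @export
polyval <- function(coeffs, x) {
  y <- rep(0, length(x))
  for (c_i in coeffs) y <- y * x + c_i
  y
}

# Round half away from zero toward larger values; used where ties must fall
# toward the tube bottom (larger image row index).
round_half_down_row <- function(x) floor(x + 0.5)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

md5_file <- function(path) unname(tools::md5sum(path))
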