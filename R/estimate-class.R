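# Shared container for a single named point estimate of P.
# Polynomial-family estimates may legitimately fall outside [0, 1]; the
# in_range flag records this instead of silently clipping.
mi_estimate <- function(method, value, notes = character()) {
  structure(list(method = method,
                 value = value,
                 in_range = is.finite(value) && value >= 0 && value <= 1,
                 notes = notes),
            class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("%-6s %7.2f%%%s\n", x$method, 100 * x$value,
              if (!x$in_range) "  [outside 0-100%]" else ""))
  if (length(x$notes)) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.mi_estimate <- function(x, ...) {
  data.frame(method = x$method, value = x$value, in_range = x$in_range,
             notes = if (length(x$notes)) paste(x$notes, collapse = "; ") else "",
             stringsAsFactors = FALSE)
}
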