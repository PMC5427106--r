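# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
abort_etho <- function(subclass, msg, ...) {
  stop(structure(
    class = c(paste0("ethoscore_", subclass), "ethoscore_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

is_pos_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && is.finite(x) && x > 0
}

is_hex_color <- function(x) {
  is_string(x) && grepl("^#[0-9A-Fa-f]{6}$", x)
}

# round-half-up; base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)

# tolerance for treating interval endpoints as coincident (seconds)
EPS_T <- 1e-9

# data.frame() spends most of its time deparsing names/row-names; hot
# paths build frames from known-good equal-length vectors instead
fast_df <- function(...) {
  l <- list(...)
  structure(l, class = "data.frame",
            row.names = .set_row_names(length(l[[1L]])))
}
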