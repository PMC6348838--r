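#' @keywords internal
"_PACKAGE"

# stop() wrapper producing classed conditions so callers/tests can
# discriminate error families without matching message text.
mfi_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "mfi_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    mfi_stop("mfi_argument_error", "'%s' must be a single finite number", name)
  bad <- if (strict_min) x <= min else x < min
  if (bad)
    mfi_stop("mfi_argument_error", "'%s' must be %s %s, got %s", name,
             if (strict_min) ">" else ">=", format(min), format(x))
  invisible(x)
}

#' FNV-1a checksum of a character scalar
#'
#' Used to stamp pipeline outputs with a short provenance checksum of the
#' resolved configuration. 32-bit FNV-1a, returned as 8 hex digits.
#'
#' @param x Character scalar.
#' @return Character scalar, 8 hexadecimal digits.
#' @export
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    # xor with one byte only touches the low 8 bits; keep h a double so the
    # 32-bit modular multiply by the FNV prime 16777619 stays exact
    low <- h %% 256
    h <- h - low + bitwXor(low, b %% 256)
    h <- (h * 16777619) %% 4294967296
  }
  # h < 2^32 does not fit a 32-bit signed integer; format the two 16-bit
  # halves separately
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
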