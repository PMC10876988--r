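#' @keywords internal
"_PACKAGE"

# Abort with a classed condition so callers/tests can distinguish error kinds.
stop_rc <- function(msg, class) {
  stop(structure(
    class = c(class, "ramanclean_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

validation_error <- function(msg) stop_rc(msg, "ramanclean_validation_error")
parse_error <- function(msg) stop_rc(msg, "ramanclean_parse_error")
range_error <- function(msg) stop_rc(msg, "ramanclean_range_error")

# Exact decimal rendering of doubles: %.17g round-trips IEEE-754 via strtod,
# so text containers written with it are bitwise-lossless.
fmt_dbl <- function(x) sprintf("%.17g", x)

fmt_row <- function(x) paste(fmt_dbl(x), collapse = " ")

# Stable short hash (FNV-1a, 32 bit) of a character serialization; used for
# provenance stamps. Not cryptographic.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\x1f")))
  h <- 216613626
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648), b)
    # 31-bit modular multiply by 16777619 in double precision
    h <- (h * 16777619) %% 2147483648
  }
  sprintf("%08x", h)
}

config_hash <- function(cfg) {
  fnv1a32(paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                                   character(1)), sep = "=", collapse = ";"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)
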