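# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bdml <- function(code, msg) {
  cond <- structure(
    class = c(paste0("bdml_", code), "bdml_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_nonempty_string <- function(x) is_string(x) && nzchar(trimws(x))

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

UUID_REGEX <- "^[0-9a-fA-F]{8}-[0-9a-fA-F]{4}-[0-9a-fA-F]{4}-[0-9a-fA-F]{4}-[0-9a-fA-F]{12}$"

is_uuid <- function(x) is_string(x) && grepl(UUID_REGEX, x)

#' Generate a random version-4 UUID
#'
#' Draws 128 random bits from R's random number generator and formats them as
#' an RFC-4122 version-4 UUID (8-4-4-4-12 hex digits, version and variant
#' bits set). Decentralised generation means document identifiers can be
#' minted without coordination; seed the RNG for reproducible identifiers.
#'
#' @return A single UUID string.
#' @export
#' @examples
#' set.seed(1)
#' uuid4()
uuid4 <- function() {
  hex <- sample(c(0:9, letters[1:6]), 32, replace = TRUE)
  hex[13] <- "4"                                 # version nibble
  hex[17] <- sample(c("8", "9", "a", "b"), 1)    # variant nibble
  paste0(
    paste(hex[1:8], collapse = ""), "-",
    paste(hex[9:12], collapse = ""), "-",
    paste(hex[13:16], collapse = ""), "-",
    paste(hex[17:20], collapse = ""), "-",
    paste(hex[21:32], collapse = "")
  )
}

# URI sanity check: scheme ':' rest, no whitespace
is_uri <- function(x) {
  is_string(x) && grepl("^[A-Za-z][A-Za-z0-9+.-]*:\\S+$", x)
}

# shortest decimal representation that parses back to exactly x
fmt_num <- function(x) {
  vapply(as.numeric(x), function(v) {
    if (!is.finite(v)) stop_bdml("invalid-document", "non-finite numeric value")
    if (v == trunc(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

# run code with a private, restored RNG stream (R's own generator, seeded)
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
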