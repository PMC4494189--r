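#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif setNames
#' @importFrom utils modifyList head tail
NULL

# ---- findings ---------------------------------------------------------------

# A "finding" is one row of a data.frame(kind, subject, message).  Validators
# return zero rows when the object is conformant, so callers can test
# `nrow(findings) == 0` and bind findings from several checks together.

no_findings <- function() {
  data.frame(kind = character(), subject = character(), message = character(),
             stringsAsFactors = FALSE)
}

finding <- function(kind, subject, message) {
  data.frame(kind = kind, subject = subject, message = message,
             stringsAsFactors = FALSE)
}

bind_findings <- function(...) {
  fs <- Filter(function(x) !is.null(x) && nrow(x) > 0L, list(...))
  if (length(fs) == 0L) return(no_findings())
  do.call(rbind, c(fs, list(make.row.names = FALSE)))
}

# ---- logging ----------------------------------------------------------------

# Conversion notices (ignored ClinicalData, itemgroup boundaries dropped, ...)
# go through message() so callers can suppressMessages() or capture them.

odmcda_notice <- function(...) {
  message("odmcda: ", ...)
}

# ---- small helpers ----------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

assert_string <- function(x, what, allow_empty = FALSE) {
  if (!is_string(x) || (!allow_empty && !nzchar(x)))
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  x
}

# 32-bit FNV-1a over the UTF-8 bytes of a string; used to mint deterministic
# local codes and document ids.  Arithmetic kept below 2^53 so plain doubles
# are exact.
fnv1a32 <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(x))) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^31 * (h >= 2^31)), as.integer(b))
    if (h < 0) h <- h + 2^32
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%.0f", h)
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Normalize a per-language string map (ODM TranslatedText semantics): a bare
# scalar becomes c(en = x); NULL stays NULL; otherwise a named character
# vector keyed by language code.
normalize_lang_map <- function(x, what = "language map") {
  if (is.null(x) || length(x) == 0L) return(NULL)
  x <- unlist(x)
  if (!is.character(x)) stop(what, " must be character", call. = FALSE)
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    if (length(x) != 1L)
      stop(what, " entries must be named by language code", call. = FALSE)
    names(x) <- "en"
  }
  x
}
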