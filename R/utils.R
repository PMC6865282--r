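# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Factor with the canonical A/I/U/E levels; errors on anything else.
as_label_factor <- function(x, allow_na = FALSE) {
  x <- as.character(x)
  bad <- !(x %in% opi_labels()) & !(allow_na & is.na(x))
  if (any(bad)) {
    stop("unknown class label(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected one of ", paste(opi_labels(), collapse = ", "), ")",
         call. = FALSE)
  }
  factor(x, levels = opi_labels())
}

# Derive a reproducible 31-bit sub-seed from a base seed and a stage name.
# Documented fan-out rule: seed_stage = (seed * 69069 + sum of char codes of
# the stage name * 7919) mod (2^31 - 1). Keeps every derived seed a valid
# 32-bit R integer and distinct across stages for any base seed.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage)) * 7919
  as.integer((abs(seed) * 69069 + h) %% (2^31 - 1))
}

# Tokenizer used everywhere: lowercase, runs of ASCII letters/digits.
tokenize <- function(text) {
  text <- tolower(text)
  regmatches(text, gregexpr("[a-z0-9]+", text))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
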