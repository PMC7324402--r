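# internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# cache of full state-space bit matrices; rebuilt on demand, never serialized
.bgmn_cache <- new.env(parent = emptyenv())

# all 2^m states as a (2^m x m) 0/1 integer matrix; row r encodes state id r-1,
# module i contributing bit 2^(i-1) (M1 is the least significant bit)
all_states_matrix <- function(m) {
  key <- as.character(m)
  if (!is.null(.bgmn_cache[[key]])) return(.bgmn_cache[[key]])
  if (m > 24L) stopf("state space 2^%d exceeds the exhaustive enumeration bound (m <= 24)", m)
  ids <- seq_len(2^m) - 1L
  mat <- vapply(seq_len(m), function(i) as.integer(ids %/% (2^(i - 1L)) %% 2),
                integer(length(ids)))
  mat <- matrix(as.integer(mat), nrow = length(ids), ncol = m)
  .bgmn_cache[[key]] <- mat
  mat
}

state_id <- function(bits) as.integer(sum(bits * 2^(seq_along(bits) - 1L)))

id_to_state <- function(id, m) as.integer(id %/% 2^(seq_len(m) - 1L) %% 2L)

#' Render a module state as a bit-string
#'
#' Module M1 is the leftmost character, so `"000000000111"` denotes a
#' 12-module state with M10, M11 and M12 ON.
#'
#' @param bits integer vector of 0/1 module states (M1 first).
#' @return A single character string.
#' @export
state_to_string <- function(bits) {
  check_bits(bits)
  paste(bits, collapse = "")
}

#' Parse a bit-string into a module state
#'
#' @param s bit-string with module M1 leftmost, e.g. `"000000100100"`.
#' @return Integer vector of 0/1 values.
#' @export
string_to_state <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (!grepl("^[01]+$", s)) stopf("state string must contain only 0 and 1: %s", s)
  as.integer(strsplit(s, "")[[1]])
}

check_bits <- function(bits) {
  if (!is.numeric(bits) || any(is.na(bits)) || !all(bits %in% c(0, 1)))
    stopf("module state must be a vector of 0/1 values")
  invisible(as.integer(bits))
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, k) as.integer((as.numeric(seed) * 1103515245 + 12345 * k) %% .Machine$integer.max)
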