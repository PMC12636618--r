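# Seed plumbing and small shared helpers.

#' Set the RNG state locally
#'
#' Saves the current `.Random.seed`, seeds the RNG with `seed`, and returns
#' the saved state so callers can restore it via [restore_seed()]. All
#' randomized operations in the package are pure functions of their arguments
#' and their `seed`.
#'
#' @param seed integer seed.
#' @return the previous RNG state (or `NULL` if none existed).
#' @keywords internal
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

#' @rdname local_seed
#' @param old RNG state returned by [local_seed()].
#' @keywords internal
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Derive a module seed from a top-level run seed
#'
#' A single run seed deterministically derives per-purpose substream seeds so
#' that independent pipeline stages do not share RNG streams. The derivation
#' hashes the purpose label into an offset and keeps the result inside the
#' 32-bit integer range.
#'
#' @param seed top-level integer seed.
#' @param purpose character label of the consuming stage.
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, purpose) {
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)) %% 97)
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap degrees into [0, 360)
wrap_deg_360 <- function(x) x %% 360

# wrap degrees into [-180, 180)
wrap_deg_180 <- function(x) ((x + 180) %% 360) - 180
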