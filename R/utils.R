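# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# FNV-1a 32-bit hash of a character string; used only as a short config
# fingerprint in output headers (not cryptographic).
#' @keywords internal
#' @noRd
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low 16 bits (b < 256, h kept as a double below 2^32)
    lo <- bitwXor(as.integer(h %% 65536), b)
    h <- (h %/% 65536) * 65536 + lo
    # 32-bit modular multiply by 16777619, done in two 16-bit halves
    lo <- h %% 65536L
    hi <- h %/% 65536L
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Derive a stream of well-spread 31-bit seeds from one master seed, so each
# generator call can be independently reproducible.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, index) {
  x <- (as.numeric(seed) * 2654435761 + index * 40503) %% 2147483647
  as.integer(max(1, x))
}

#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

# Amino-acid alphabet in the conventional substitution-model order, plus the
# Kyte-Doolittle hydropathy scale.
AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' @keywords internal
#' @noRd
runs_of <- function(labels, value) {
  r <- rle(labels == value)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

# Standard file header written at the top of machine outputs: version, seed
# and config fingerprint, but nothing time-dependent (outputs must be
# byte-identical across reruns with one seed).
#' @keywords internal
#' @noRd
output_header <- function(seed, config_hash, comment_char = "#") {
  ver <- tryCatch(as.character(utils::packageVersion("statorevo")),
                  error = function(e) "dev")
  paste0(comment_char, " statorevo ", ver,
         " seed=", seed %||% "NA",
         " config=", config_hash %||% "NA")
}
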