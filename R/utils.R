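#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds with `seed`, evaluates `expr`, and
#' restores the state, so seeded pipeline stages never perturb the session
#' RNG stream.
#'
#' @param seed integer seed (must be representable as a 32-bit integer).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  if (abs(seed) >= 2^31)
    stop("seed must fit in a 32-bit integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed (< 2^31) from a parent seed and a label.
derive_seed <- function(seed, label) {
  h <- fnv1a32(paste0(seed, ":", label))
  as.integer(h %% 2147483647)
}

# FNV-1a 32-bit string hash, used for provenance config hashes and seed
# derivation (no digest package in the runtime).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(as.character(x)))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply split into 16-bit halves to stay exact in doubles
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- ((lo * 16777619) + ((hi * 16777619) %% 65536) * 65536) %% 2^32
  }
  h
}

format_hash <- function(x) {
  h <- fnv1a32(x)
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# Provenance logging -------------------------------------------------------

start_log <- function() {
  env <- new.env(parent = emptyenv())
  env$lines <- character(0)
  env
}

log_line <- function(log, ...) {
  if (is.null(log)) return(invisible(NULL))
  log$lines <- c(log$lines, paste0(...))
  invisible(NULL)
}

write_log <- function(log, path) {
  if (is.null(log)) return(invisible(NULL))
  writeLines(log$lines, path)
  invisible(path)
}
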