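# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# deterministic 31-bit seed derived from a base seed, a string id and an
# integer index; keeps per-country / per-iteration streams reproducible and
# independent of how many other units are simulated
mix_seed <- function(base, id, k = 0L) {
  h <- 0
  for (ch in utf8ToInt(as.character(id))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((h + as.numeric(base) * 2654435 + as.numeric(k) * 97003) %%
               2147483647)
}

# write a file atomically: stage in the same directory, then rename
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("could not move temporary file onto ", path)
  }
  invisible(path)
}

stop_validation <- function(...) {
  stop(structure(class = c("cea_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
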