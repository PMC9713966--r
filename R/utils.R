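`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

# Coerce an omics_matrix, sc_mask or plain matrix to a bare base matrix
# (no class, no extra attributes), so elementwise ops cannot leak
# attributes onto their results.
as_values <- function(x) {
  x <- as.matrix(x)
  out <- matrix(as.numeric(x), nrow(x), ncol(x))
  dimnames(out) <- dimnames(x)
  out
}
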