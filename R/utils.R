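# Run code with a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

check_frame <- function(frame) {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    rlang::abort("a frame must be a numeric matrix (rows = y, cols = x)")
  }
  invisible(frame)
}

odd_or_abort <- function(k, what) {
  if (length(k) != 1 || k < 3 || k %% 2 == 0) {
    rlang::abort(paste0(what, " must be an odd integer >= 3, got ", k))
  }
  as.integer(k)
}
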