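#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not disturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name))
  invisible(x)
}

#' Atomic file write
#'
#' Writes via a temporary file in the destination directory followed by
#' `file.rename()`, so readers never observe a half-written file.
#'
#' @param path destination path.
#' @param writer function of one argument (the temporary path) performing
#'   the actual write.
#' @return `path`, invisibly.
#' @keywords internal
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  tmp <- tempfile(tmpdir = dir, fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not rename temporary file to ", path)
  invisible(path)
}
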