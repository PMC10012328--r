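# internal helpers shared across modules

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals (network draws,
#' Poisson streams) never perturb the caller's RNG state.
#'
#' @param seed integer seed, must be non-NULL
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a single finite numeric seed is required for reproducibility")
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

# recursively merge user values into a default list, rejecting unknown keys
merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section '", paste(path, collapse = "."),
                           "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste(paste(c(path, unknown[1]), collapse = "."), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number")
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper)
    stop("'", name, "' = ", x, " violates constraint [",
         if (strict_lower) "> " else ">= ", lower, ", <= ", upper, "]")
  invisible(TRUE)
}
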