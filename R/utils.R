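# internal helpers shared across modules

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Wrap coordinates into [0, L); L may be a scalar or vector recycled over x.
wrap_coord <- function(x, L) x - floor(x / L) * L

# Minimum-image separation along one periodic axis.
min_image <- function(dx, L) {
  dx <- dx - round(dx / L) * L
  dx
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
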