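# Shared internal helpers: feature-volume checks, initializers, parameter-tree
# flattening (checkpoint naming convention `<block>.<stage>.<branch>.<param>`),
# and seeded RNG scoping.

#' Construct a feature volume
#'
#' Feature volumes are rank-5 numeric arrays holding a batch of multi-channel
#' 3D feature maps. The in-memory layout is R column-major
#' `(d1, d2, d3, channel, batch)`; all values must be finite.
#'
#' @param data numeric array or vector.
#' @param dim optional dimensions `(d1, d2, d3, channels, batch)` when `data`
#'   is not already a rank-5 array.
#' @return a rank-5 numeric array.
#' @export
feature_volume <- function(data, dim = NULL) {
  if (!is.null(dim)) {
    stopifnot(length(dim) == 5L)
    data <- array(as.numeric(data), dim = dim)
  }
  check_feature_volume(data)
  data
}

check_feature_volume <- function(x, what = "x") {
  d <- base::dim(x)
  if (is.null(d) || length(d) != 5L)
    stop(sprintf("%s must be a rank-5 array (d1, d2, d3, channel, batch)", what),
         call. = FALSE)
  if (any(d < 1L)) stop(sprintf("%s has a zero-length dimension", what), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  invisible(x)
}

fv_channels <- function(x) dim(x)[4L]
fv_spatial  <- function(x) dim(x)[1:3]
fv_batch    <- function(x) dim(x)[5L]

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Kaiming-normal initialization for a cubic conv kernel (k,k,k,in,out).
kaiming_kernel <- function(k, in_ch, out_ch) {
  fan_in <- k^3 * in_ch
  array(stats::rnorm(k^3 * in_ch * out_ch, sd = sqrt(2 / fan_in)),
        dim = c(k, k, k, in_ch, out_ch))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so generators have no hidden global effect.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a distinct 31-bit sub-seed from a base seed and a stream label.
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) * 7919 + sum(utf8ToInt(as.character(stream))) * 104729) %% 2147483647
  as.integer(max(1, s))
}

# ---- parameter-tree flattening --------------------------------------------

# Flatten a nested list of numeric leaves into a flat named list with
# dot-joined names; attributes other than dim are dropped.
flatten_params <- function(tree, prefix = NULL) {
  out <- list()
  for (nm in names(tree)) {
    v <- tree[[nm]]
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    if (is.list(v)) out <- c(out, flatten_params(v, key))
    else if (is.numeric(v)) out[[key]] <- v
    else out[[key]] <- v  # flags and strings survive round-trip
  }
  out
}

# Inverse of flatten_params given a template tree for the structure.
unflatten_params <- function(flat, template, prefix = NULL) {
  for (nm in names(template)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    v <- template[[nm]]
    if (is.list(v)) template[[nm]] <- unflatten_params(flat, v, key)
    else if (key %in% names(flat)) template[[nm]] <- flat[[key]]
  }
  template
}

# Elementwise combine two same-shaped parameter trees (used for SGD updates
# and gradient accumulation). Leaves absent from `b` are left untouched.
tree_map2 <- function(a, b, f) {
  for (nm in names(b)) {
    if (is.list(b[[nm]])) {
      if (is.null(a[[nm]])) a[[nm]] <- list()
      a[[nm]] <- tree_map2(a[[nm]], b[[nm]], f)
    } else if (is.numeric(b[[nm]])) {
      if (is.null(a[[nm]])) a[[nm]] <- b[[nm]] * 0
      a[[nm]] <- f(a[[nm]], b[[nm]])
    }
  }
  a
}

`%||%` <- function(a, b) if (is.null(a)) b else a
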