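# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Smooth zero-mean random field on a grid, scaled so |value| <= 1 with the
# bulk of the field near full amplitude (normalized by the 95th percentile
# of |value|, then clipped). White Gaussian noise passed twice through a box
# filter; correlation length of the order of the kernel width.
smooth_random_field <- function(dims, kernel = c(7L, 7L, 5L)) {
  x <- array(stats::rnorm(prod(dims)), dim = dims)
  x <- box_filter_cpp(as.numeric(x), as.integer(dims), as.integer(kernel))
  x <- box_filter_cpp(x, as.integer(dims), as.integer(kernel))
  x <- x - mean(x)
  x <- x / stats::quantile(abs(x), 0.95)
  array(pmin(pmax(x, -1), 1), dim = dims)
}

# Signed Euclidean distance (mm) to the boundary of a logical mask:
# negative inside, positive outside. Empty mask: +Inf everywhere; full
# mask: -Inf everywhere.
signed_distance <- function(mask, spacing_mm) {
  dims <- dim(mask)
  if (!any(mask)) return(array(Inf, dim = dims))
  if (all(mask)) return(array(-Inf, dim = dims))
  dout <- sqrt(edt_sq_cpp(as.logical(mask), as.integer(dims), as.numeric(spacing_mm)))
  din <- sqrt(edt_sq_cpp(!as.logical(mask), as.integer(dims), as.numeric(spacing_mm)))
  array(dout - din, dim = dims)
}

# Deterministic FNV-1a hash of a character scalar, as hex. Arithmetic done
# in doubles with a 16-bit split to stay exact modulo 2^32.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    h_lo <- h %% 65536
    h_hi <- (h - h_lo) / 65536
    h <- (h_lo * m + ((h_hi * m) %% 65536) * 65536) %% 4294967296
  }
  lo16 <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo16) / 65536), as.integer(lo16))
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

sample_sd <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
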