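#' @useDynLib swdgrid, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Annotation label vocabulary (closed) and detector output classes.
ANN_LABELS <- c("DSM", "DSF", "BC")
FLY_CLASSES <- c("DSF", "DSM")
GRID_CLASSES <- c("background", "DSF", "DSM")

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream of child seeds from one master seed; stays below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Read an RGB image from disk
#'
#' Reads a PNG image into a numeric `height x width x 3` array with values
#' in \[0, 1\]. Greyscale images are expanded to three channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path Path to a PNG file.
#' @return A numeric array of dimension `height x width x 3`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB image to disk
#'
#' @param img Numeric array `height x width x 3` with values in \[0, 1\].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(clamp(img, 0, 1), path)
  invisible(path)
}

# Separable Gaussian blur with replicate (clamped) boundary handling, applied
# per channel. Kernel truncated at 3 sigma.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur1 <- function(m, along) {
    n <- if (along == 1L) nrow(m) else ncol(m)
    out <- 0
    for (j in seq_along(k)) {
      off <- j - r - 1L
      idx <- clamp(seq_len(n) + off, 1L, n)
      out <- out + k[j] * (if (along == 1L) m[idx, , drop = FALSE]
                           else m[, idx, drop = FALSE])
    }
    out
  }
  for (c in seq_len(dim(img)[3])) {
    img[, , c] <- blur1(blur1(img[, , c], 1L), 2L)
  }
  img
}
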