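#' @keywords internal
"_PACKAGE"

## Shared validation and RNG helpers.
## Image convention throughout the package: numeric array height x width x 3,
## intensities in [0, 1] (the `png` package layout).  Point coordinates are
## 0-based, x rightward, y downward, with a point at a pixel's centre.

stop_contract <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_contract("`%s` must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    stop_contract("`%s` = %g is outside [%g, %g]", name, x, lower, upper)
  }
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  if (x != round(x)) stop_contract("`%s` must be an integer count", name)
  invisible(as.integer(x))
}

#' Derive a stage seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from one global seed plus a stage label, so a single integer reproduces a
#' full run while stages stay statistically decoupled.
#'
#' @param seed Global integer seed.
#' @param stage Character stage label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  check_number(seed, "seed")
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(as.character(stage))) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## image helpers ------------------------------------------------------------

check_image <- function(img, name = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop_contract("`%s` must be a height x width x 3 numeric array", name)
  }
  invisible(img)
}

image_size <- function(img) {
  d <- dim(img)
  c(width = d[2], height = d[1])
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

blank_image <- function(width, height, value = 0) {
  array(value, dim = c(height, width, 3L))
}

#' Read and write PNG images
#'
#' Thin wrappers over the `png` package using the package-wide
#' height x width x 3 array convention.
#'
#' @param path File path.
#' @param img Image array.
#' @rdname png_io
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  img[, , 1:3, drop = FALSE]
}

#' @rdname png_io
#' @export
write_image <- function(img, path) {
  check_image(img)
  png::writePNG(clip01(img), target = path)
  invisible(path)
}

## point-set helpers --------------------------------------------------------

#' Construct a point set
#'
#' A point set is the package's currency for seed annotations and
#' predictions: a data frame with 0-based pixel-centre `x`, `y` columns and,
#' for predictions, a `score` column in `[0, 1]`.
#'
#' @param x,y Numeric coordinate vectors.
#' @param score Optional confidence vector.
#' @param image_id Optional image identifier attached as an attribute.
#' @return A `point_set` data frame.
#' @export
point_set <- function(x = numeric(), y = numeric(), score = NULL,
                      image_id = NULL) {
  if (length(x) != length(y)) stop_contract("x and y lengths differ")
  df <- data.frame(x = as.numeric(x), y = as.numeric(y))
  if (!is.null(score)) {
    if (length(score) != length(x)) stop_contract("score length mismatch")
    df$score <- as.numeric(score)
  }
  class(df) <- c("point_set", "data.frame")
  attr(df, "image_id") <- image_id
  df
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set: %d points%s>\n", nrow(x),
              if ("score" %in% names(x)) ", scored" else ""))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10L))
  invisible(x)
}
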