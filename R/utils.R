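#' @useDynLib lakecover, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate complete.cases cor dbinom pchisq pt qt rnorm runif sd var
#' @importFrom utils read.csv write.csv
NULL

# Project-wide class code table: 0 is reserved for nodata in every raster.
LAKE_CLASSES <- c(nodata = 0L, water = 1L, vegetation = 2L, mudflat = 3L, sand = 4L)

#' Land-cover class codes
#'
#' Fixed project-wide coding of the categorical rasters: 0 nodata, 1 water,
#' 2 vegetation, 3 mudflat, 4 sand. Merged "mudflat&sand" reporting sums
#' codes 3 and 4.
#'
#' @return Named integer vector of class codes.
#' @export
lake_classes <- function() LAKE_CLASSES

class_name <- function(code) {
  names(LAKE_CLASSES)[match(code, LAKE_CLASSES)]
}

class_code <- function(name) {
  name <- as.character(name)
  if (suppressWarnings(!anyNA(as.integer(name)))) {
    code <- as.integer(name)
  } else {
    code <- unname(LAKE_CLASSES[match(name, names(LAKE_CLASSES))])
  }
  if (anyNA(code)) {
    stop("unknown class: ", paste(name[is.na(code)], collapse = ", "), call. = FALSE)
  }
  code
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
# All package randomness flows through this helper so one integer seed
# reproduces a run bit-identically.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation, kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset) %% .Machine$integer.max)
}

.log_levels <- c(debug = 1L, info = 2L, warning = 3L, error = 4L)

lake_log <- function(msg, level = "info") {
  threshold <- getOption("lakecover.log_level", "info")
  if (.log_levels[[level]] >= .log_levels[[threshold]]) {
    message(sprintf("[lakecover %s] %s", level, msg))
  }
  invisible(NULL)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
is_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
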