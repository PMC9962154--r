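#' @keywords internal
"_PACKAGE"

# Coordinate convention used throughout: images are numeric/integer matrices in
# row-major visual order (origin top-left); all user-facing pixel coordinates
# (detector sites, ROI) are 0-based, converted to R's 1-based indexing
# internally at the point of use.

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Clip and quantize an irradiance-integral image to 8-bit ADU
#'
#' Floor to integer after gain, clip to \[0, 255\]. A 1e-6 ADU guard is
#' added before flooring so that values sitting on an integer up to
#' floating-point rounding quantize stably.
#' @param x numeric matrix (irradiance integral times gain)
#' @return integer matrix of ADU values in \[0, 255\]
#' @keywords internal
quantize_adu <- function(x) {
  x <- floor(x + 1e-6)
  x[x < 0] <- 0
  x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user simulations.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
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
  }
  force(code)
}

vs_log <- function(...) {
  if (isTRUE(getOption("veinscan.verbose", FALSE))) {
    message("[veinscan] ", sprintf(...))
  }
  invisible(NULL)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

#' Parse a 12-bit diode code
#'
#' @param code character scalar of 12 binary digits, or an integer/logical
#'   vector of 12 bits.
#' @return integer vector of 12 zeros/ones
#' @keywords internal
parse_code <- function(code) {
  if (is.character(code)) {
    if (length(code) != 1L || !grepl("^[01]{12}$", code)) {
      stop_invalid("diode code must be a string of 12 binary digits, got %s",
                   deparse(code))
    }
    as.integer(strsplit(code, "")[[1]])
  } else {
    bits <- as.integer(code)
    if (length(bits) != 12L || anyNA(bits) || any(bits != 0L & bits != 1L)) {
      stop_invalid("diode code must have exactly 12 bits of 0/1")
    }
    bits
  }
}

format_code <- function(bits) paste(as.integer(bits), collapse = "")
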