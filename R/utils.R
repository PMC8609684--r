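#' @keywords internal
"_PACKAGE"

# Unit conversions used for reporting (all internal geometry is in micrometres).
UM3_PER_MM3 <- 1e9
UM_PER_M <- 1e6

#' Convert a length density between internal and reporting units
#'
#' Internally length density Lv is carried in um/um^3 (= um^-2); reports use
#' m/mm^3 as customary in microvascular morphometry. 1 um^-2 == 1000 m/mm^3.
#'
#' @param lv_um2 length density in um^-2
#' @return length density in m/mm^3
#' @export
lv_to_m_per_mm3 <- function(lv_um2) lv_um2 * UM3_PER_MM3 / UM_PER_M

#' @rdname lv_to_m_per_mm3
#' @param lv_m_mm3 length density in m/mm^3
#' @return length density in um^-2
#' @export
lv_from_m_per_mm3 <- function(lv_m_mm3) lv_m_mm3 * UM_PER_M / UM3_PER_MM3

# Derive a reproducible sub-seed for a named random stream so that, e.g.,
# changing cohort size does not perturb the draws of other animals.
# Kept well below .Machine$integer.max.
stream_seed <- function(master_seed, ...) {
  labels <- vapply(list(...), as.character, character(1))
  h <- as.double(master_seed %% 2147483647L)
  for (lab in labels) {
    for (ch in utf8ToInt(lab)) {
      h <- (h * 31 + ch) %% 2147480009
    }
  }
  as.integer(h)
}

with_stream_seed <- function(master_seed, ..., code) {
  seed <- stream_seed(master_seed, ...)
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
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stopf("invalid parameter: `%s` must be finite and > 0", name)
  }
  invisible(x)
}
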