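# Calendar constants. All episode windows are fixed day counts derived from
# the mean Gregorian year (365.25 d), so results do not depend on locale or
# calendar-month arithmetic. 3.25 years is pinned to 1186 days.
DAYS_PER_YEAR <- 365.25
DAYS_2Y <- 730.5
DAYS_6M <- 182.625
DAYS_1M <- 30.4375
DAYS_3Y3M <- 1186

# EDSS half-point grid: 0, then 1.0 to 10.0 in 0.5 steps (no 0.5 score).
EDSS_GRID <- c(0, seq(1, 10, by = 0.5))

#' Test membership of the EDSS half-point grid
#'
#' The Expanded Disability Status Scale takes values 0 and 1.0, 1.5, ..., 10.0;
#' 0.5 is not a valid score.
#'
#' @param x numeric vector.
#' @return logical vector, `TRUE` where `x` is a valid EDSS value.
#' @export
is_edss <- function(x) {
  !is.na(x) & ((x == 0) | (x >= 1 & x <= 10 & (x * 2) == round(x * 2)))
}

# Snap a numeric disability level to the nearest EDSS grid point, clamped to
# [0, 10]. Values in (0, 0.75) round to the closer of 0 and 1.
snap_edss <- function(x) {
  x <- pmin(pmax(x, 0), 10)
  g <- round(x * 2) / 2
  g[g == 0.5] <- ifelse(x[g == 0.5] < 0.5, 0, 1)
  g
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards. Keeps model training and simulation reproducible
# without clobbering the user's RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

years_between <- function(from, to) {
  as.numeric(to - from) / DAYS_PER_YEAR
}
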