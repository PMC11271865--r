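#' Fit a post-hoc calibration map on validation scores
#'
#' Platt scaling fits a two-parameter sigmoid on the log-odds of the
#' (clipped) scores by logistic-regression maximum likelihood; isotonic
#' regression fits a non-decreasing step function by pool-adjacent
#' violators. Both are fitted on validation data and applied to test scores,
#' never the other way around. `method = "auto"` fits both and keeps the one
#' with the lower validation expected calibration error.
#'
#' @param scores_val validation scores in `[0, 1]`.
#' @param labels_val validation 0/1 labels (both classes required).
#' @param method `"platt"`, `"isotonic"`, or `"auto"`.
#' @param bins bins used for the ECE-based selection under `"auto"`.
#' @return an `ms_calibration` object; apply with [calibrate_scores()] or
#'   `predict()`.
#' @export
fit_calibration <- function(scores_val, labels_val,
                            method = c("auto", "platt", "isotonic"),
                            bins = 20) {
  method <- match.arg(method)
  check_binary(labels_val)
  stopifnot(all(scores_val >= 0 & scores_val <= 1))
  y <- as.integer(labels_val)

  fit_platt <- function() {
    lo <- qlogis(pmin(pmax(scores_val, 1e-6), 1 - 1e-6))
    fit <- suppressWarnings(glm(y ~ lo, family = binomial()))
    list(kind = "platt", a = unname(coef(fit)[2]), b = unname(coef(fit)[1]))
  }
  fit_iso <- function() {
    ord <- order(scores_val)
    iso <- isoreg(scores_val[ord], y[ord])
    # collapse to unique knots for interpolation
    kx <- iso$x
    ky <- iso$yf
    keep <- !duplicated(kx, fromLast = TRUE)
    list(kind = "isotonic", x = kx[keep], y = pmin(pmax(ky[keep], 0), 1))
  }

  maps <- switch(method,
    platt = list(fit_platt()),
    isotonic = list(fit_iso()),
    auto = list(fit_platt(), fit_iso())
  )
  eces <- vapply(maps, function(m) {
    ece(apply_calibration(m, scores_val), y, bins)
  }, numeric(1))
  chosen <- maps[[which.min(eces)]]
  structure(
    list(
      map = chosen, method = chosen$kind, val_ece = min(eces),
      candidates = setNames(eces, vapply(maps, `[[`, "", "kind"))
    ),
    class = "ms_calibration"
  )
}

apply_calibration <- function(map, scores) {
  if (map$kind == "platt") {
    lo <- qlogis(pmin(pmax(scores, 1e-6), 1 - 1e-6))
    plogis(map$a * lo + map$b)
  } else {
    # non-decreasing step/linear interpolation, clamped at the ends
    approx(map$x, map$y,
      xout = scores, method = "linear", rule = 2,
      ties = list("ordered", max)
    )$y
  }
}

#' Apply a fitted calibration map to new scores
#'
#' @param calibration an `ms_calibration` from [fit_calibration()].
#' @param scores scores in `[0, 1]`.
#' @return calibrated probabilities in `[0, 1]`.
#' @export
calibrate_scores <- function(calibration, scores) {
  stopifnot(inherits(calibration, "ms_calibration"))
  apply_calibration(calibration$map, scores)
}

#' @export
predict.ms_calibration <- function(object, scores, ...) {
  calibrate_scores(object, scores)
}

#' @export
print.ms_calibration <- function(x, ...) {
  cat(sprintf(
    "<ms_calibration: %s> validation ECE %.4f\n", x$method, x$val_ece
  ))
  invisible(x)
}
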