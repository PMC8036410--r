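# Cell-death and viability read-outs: propidium iodide (PI) area and
# intensity relative to the bright-field (BF) spheroid area, normalization
# to untreated controls, and the trypan-blue viability formula.

#' PI-based cell-death metrics relative to the BF area
#'
#' The PI-positive mask is `pixels inside the BF mask with PI >= threshold`.
#' By default the threshold is Otsu's, computed on in-mask PI values only,
#' floored at `background + 3 * MAD` of the outside-mask PI (without the
#' floor, a PI channel containing only background noise would spuriously
#' mark half the spheroid). The background level subtracted from the summed
#' intensity is the median PI outside the BF mask, making the intensity
#' ratio invariant to constant offsets of the PI channel.
#'
#' @param bfMask a non-empty [Mask2D-class] of the whole spheroid
#' @param piImage an [Image2D-class], same geometry as `bfMask`
#' @param policy threshold policy: `"otsu"` (default), `"fixed"`, or
#'   `"quantile"` (in-mask quantile)
#' @param value threshold value for `"fixed"`, or probability for
#'   `"quantile"`
#' @param backgroundSubtract subtract the background level from the summed
#'   PI intensity (default `TRUE`)
#' @return a [DeathMetrics-class]
#' @export
piDeathMetrics <- function(bfMask, piImage,
                           policy = c("otsu", "fixed", "quantile"),
                           value = NULL, backgroundSubtract = TRUE) {
  stopifnot(is(bfMask, "Mask2D"), is(piImage, "Image2D"))
  policy <- match.arg(policy)
  if (!identical(dim(bfMask@data), dim(piImage@data)))
    stop("BF mask and PI image geometries differ")
  if (max(abs(bfMask@pixelSize - piImage@pixelSize)) > 1e-9)
    stop("BF mask and PI image pixel sizes differ")
  m <- bfMask@data
  if (!any(m)) stop("empty BF mask")
  pi_ <- piImage@data
  inVals <- pi_[m]
  outVals <- pi_[!m]
  bg <- if (length(outVals)) stats::median(outVals) else 0
  bgMad <- if (length(outVals)) stats::mad(outVals) else 0

  thr <- switch(policy,
    otsu = {
      # Otsu is only meaningful when the in-mask histogram is genuinely
      # bimodal; on a unimodal field (all-negative or all-positive spheroid)
      # it would split the single mode in half. Require the class-mean
      # separation to exceed 3x the background noise, else fall back to the
      # background floor alone.
      t0 <- -Inf
      if (diff(range(inVals)) > 0) {
        tt <- otsuThreshold(inVals)
        sep <- mean(inVals[inVals >= tt]) - mean(inVals[inVals < tt])
        if (is.finite(sep) && sep >= 3 * bgMad) t0 <- tt
      }
      max(t0, bg + 3 * bgMad)
    },
    fixed = {
      if (is.null(value)) stop("policy 'fixed' requires a threshold value")
      value
    },
    quantile = {
      if (is.null(value)) stop("policy 'quantile' requires a probability")
      unname(stats::quantile(inVals, value))
    })

  px <- bfMask@pixelSize
  pxArea <- px[1] * px[2] / 1e6  # mm^2 per pixel
  piMask <- m & (pi_ >= thr)
  bfArea <- sum(m) * pxArea
  piArea <- sum(piMask) * pxArea
  piIntensity <- if (backgroundSubtract) sum(inVals - bg) else sum(inVals)
  new("DeathMetrics",
      bfArea = bfArea, piArea = piArea, piIntensity = piIntensity,
      piAreaRatio = piArea / bfArea,
      piIntensityRatio = piIntensity / bfArea,
      piThreshold = thr, background = bg)
}

#' Normalize a metric to the untreated-control mean
#'
#' @param x metric value(s) (numeric vector)
#' @param controlMean mean of the untreated condition (positive scalar)
#' @return `x / controlMean`, fold-of-control
#' @export
normalizeToControl <- function(x, controlMean) {
  if (length(controlMean) != 1L || !is.finite(controlMean) ||
      controlMean <= 0)
    stop("controlMean must be a single positive value")
  x / controlMean
}

#' Percent viability from live/dead counts
#'
#' `100 * live / (live + dead)`, the trypan-blue exclusion formula.
#'
#' @param live,dead non-negative cell counts (vectorized); `live + dead`
#'   must be positive
#' @return viability in percent, in `[0, 100]`
#' @export
viabilityPercent <- function(live, dead) {
  if (any(live < 0) || any(dead < 0)) stop("counts must be non-negative")
  if (any(live + dead == 0)) stop("live + dead must be positive")
  100 * live / (live + dead)
}
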