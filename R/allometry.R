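#' Allometric area-to-weight law
#'
#' Defines the power law `w = c * (area_mm2)^k * exp(eps)` linking projected
#' rosette area to fresh weight, with multiplicative log-normal noise
#' `eps ~ N(0, noise_sd^2)`. Projected area in pixels is converted to mm^2
#' through `mm_per_px`. The defaults are calibrated so that a rosette growing
#' from transplant (~28 px radius) to harvest (~170 px radius) spans roughly
#' 1--120 g, the range a butterhead lettuce covers between transplant and
#' harvest, and so that the linear correlation between projected area and
#' weight lands in the high range observed for real crops.
#'
#' Two morphological factors modulate the pure area law, mirroring how real
#' canopies deviate from a single allometry:
#' * a latent tissue-density factor `d` (standard-normal scale, one value
#'   per plant) multiplies the weight by `exp(density_gain * d)`; the
#'   renderer exposes the same factor as overall leaf brightness, so
#'   image-based models can exploit information that the four scalar shape
#'   features cannot -- the mechanism by which automatic feature extraction
#'   outperforms manual morphometrics on real crops;
#' * a lobedness factor `(L / lobedness_ref)^lobedness_gain`, where
#'   `L = P / (2 * sqrt(pi * A))` is the isoperimetric ratio of the
#'   silhouette: at equal projected area, a rosette with more or narrower
#'   leaves (longer perimeter) carries more tissue. This is what makes the
#'   perimeter an informative regressor beyond area.
#'
#' @param coefficient_c scale coefficient, g per mm^(2k); must be > 0
#' @param exponent_k allometric exponent (dimensionless); must be > 0
#' @param noise_sd standard deviation of the log-scale noise; >= 0
#' @param mm_per_px physical size of one pixel at the working resolution, mm
#' @param density_gain log-scale weight gain per unit of latent density
#' @param lobedness_gain exponent on the isoperimetric ratio
#' @param lobedness_ref reference isoperimetric ratio of a typical rosette
#' @return an object of class `fw_allometric_law`
#' @examples
#' law <- allometric_law()
#' allometric_weight(20000, law, noise_sd = 0)
#' @export
allometric_law <- function(coefficient_c = 3.3e-4, exponent_k = 1.2,
                           noise_sd = 0.10, mm_per_px = 0.8,
                           density_gain = 0.20, lobedness_gain = 0.8,
                           lobedness_ref = 1.75) {
  if (coefficient_c <= 0) fw_domain_error("coefficient_c must be > 0")
  if (exponent_k <= 0) fw_domain_error("exponent_k must be > 0")
  if (noise_sd < 0) fw_domain_error("noise_sd must be >= 0")
  if (mm_per_px <= 0) fw_domain_error("mm_per_px must be > 0")
  if (density_gain < 0) fw_domain_error("density_gain must be >= 0")
  if (lobedness_ref <= 0) fw_domain_error("lobedness_ref must be > 0")
  structure(list(coefficient_c = coefficient_c, exponent_k = exponent_k,
                 noise_sd = noise_sd, mm_per_px = mm_per_px,
                 density_gain = density_gain, lobedness_gain = lobedness_gain,
                 lobedness_ref = lobedness_ref),
            class = "fw_allometric_law")
}

#' @export
print.fw_allometric_law <- function(x, ...) {
  cat(sprintf("Allometric law: w[g] = %.3g * (A[mm^2])^%.3g * (L/%.3g)^%.3g * exp(%.3g*d + eps)\n",
              x$coefficient_c, x$exponent_k, x$lobedness_ref,
              x$lobedness_gain, x$density_gain))
  cat(sprintf("  eps ~ N(0, %.3g^2); pixel pitch %.3g mm/px\n",
              x$noise_sd, x$mm_per_px))
  invisible(x)
}

#' Draw a fresh weight for a given projected area
#'
#' @param area_px projected area in pixels^2 (vectorised); must be > 0
#' @param law an [allometric_law()]
#' @param noise_sd optional override of the law's noise level
#' @param density latent tissue-density value(s); 0 for a nominal plant
#' @param lobedness isoperimetric ratio `P / (2 sqrt(pi A))` of the
#'   silhouette; `NULL` uses the law's reference value (factor 1)
#' @return fresh weight(s) in grams
#' @export
allometric_weight <- function(area_px, law = allometric_law(), noise_sd = NULL,
                              density = 0, lobedness = NULL) {
  if (!inherits(law, "fw_allometric_law")) fw_domain_error("law must be an fw_allometric_law")
  if (any(!is.finite(area_px)) || any(area_px <= 0))
    fw_domain_error("area_px must be positive and finite")
  sdv <- noise_sd %||% law$noise_sd
  area_mm2 <- area_px * law$mm_per_px^2
  eps <- if (sdv > 0) rnorm(length(area_px), 0, sdv) else 0
  lob <- if (is.null(lobedness)) 1 else
    (lobedness / law$lobedness_ref)^(law$lobedness_gain %||% 0)
  law$coefficient_c * area_mm2^law$exponent_k * lob *
    exp((law$density_gain %||% 0) * density + eps)
}
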