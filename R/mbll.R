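#' Optical constants for the modified Beer-Lambert law
#'
#' Defaults: 760/850 nm wavelength pair; molar extinction coefficients for
#' HbO and HbR expressed per cm of path and per uM of concentration;
#' source-detector separation 30 mm; differential pathlength factor 6.0 at
#' both wavelengths. Every value is configuration, not hard-coded, so other
#' optode geometries or coefficient tables can be substituted.
#'
#' @param wavelengths_nm Two wavelengths in nm (metadata).
#' @param extinction 2 x 2 matrix, rows = wavelengths, columns = (HbO, HbR),
#'   in 1/(cm * uM).
#' @param distance_mm Source-detector distance in mm.
#' @param dpf Differential pathlength factor per wavelength (length 2).
#' @return An `mbll_config` list.
#' @export
default_mbll_config <- function(wavelengths_nm = c(760, 850),
                                extinction = matrix(
                                  c(5.86e-4, 1.54852e-3,
                                    1.058e-3, 6.9132e-4),
                                  nrow = 2, byrow = TRUE,
                                  dimnames = list(c("760", "850"),
                                                  c("HbO", "HbR"))),
                                distance_mm = 30,
                                dpf = c(6, 6)) {
  if (!is.matrix(extinction) || !all(dim(extinction) == c(2, 2))) {
    stop("`extinction` must be a 2 x 2 matrix (wavelength x chromophore)")
  }
  stop_if_not_positive(distance_mm, "distance_mm")
  if (length(dpf) == 1) dpf <- rep(dpf, 2)
  if (any(dpf <= 0)) stop("`dpf` must be positive")
  if (abs(det(extinction)) < 1e-12 * max(abs(extinction))^2) {
    stop("extinction matrix is singular; cannot separate HbO/HbR")
  }
  structure(list(wavelengths_nm = wavelengths_nm,
                 extinction = extinction,
                 distance_mm = distance_mm,
                 dpf = dpf),
            class = "mbll_config")
}

#' Path-length scaling (cm) per wavelength
#' @noRd
mbll_pathlength <- function(mbll) {
  (mbll$distance_mm / 10) * mbll$dpf
}

#' Forward modified Beer-Lambert law
#'
#' Maps haemoglobin concentration changes to dual-wavelength optical-density
#' changes: `dOD(l) = [e_HbO(l) dHbO + e_HbR(l) dHbR] * d * DPF(l)`, applied
#' exactly (a linear map) per channel and sample.
#'
#' @param hemo A `hemo_recording` (channels x chromophores x samples, uM).
#' @param mbll Optical constants, see [default_mbll_config()].
#' @return An `optical_recording`: `data` is channels x wavelengths(2) x
#'   samples of dimensionless optical-density change, with geometry metadata.
#' @export
mbll_forward <- function(hemo, mbll = default_mbll_config()) {
  stopifnot(inherits(hemo, "hemo_recording"))
  pl <- mbll_pathlength(mbll)
  d <- dim(hemo$data)
  A <- mbll$extinction * pl   # rowwise scaling: row l multiplied by pl[l]
  od <- array(0, dim = c(d[1], 2, d[3]))
  hbo <- matrix(hemo$data[, 1, ], d[1], d[3])
  hbr <- matrix(hemo$data[, 2, ], d[1], d[3])
  for (l in 1:2) {
    od[, l, ] <- A[l, 1] * hbo + A[l, 2] * hbr
  }
  out <- list(data = od,
              sampling_rate = hemo$sampling_rate,
              wavelengths_nm = mbll$wavelengths_nm,
              distance_mm = mbll$distance_mm,
              dpf = mbll$dpf,
              subject_id = hemo$subject_id,
              schedule = hemo$schedule)
  class(out) <- "optical_recording"
  out
}

#' Invert the modified Beer-Lambert law
#'
#' Recovers HbO/HbR concentration changes from dual-wavelength optical
#' density by solving, per channel and sample, the 2 x 2 linear system
#' `dOD(l) / (d * DPF(l)) = E . dc`.
#'
#' @param optical An `optical_recording` with exactly two wavelengths.
#' @param mbll Optical constants used for the inversion (must match the
#'   acquisition geometry).
#' @return A `hemo_recording` with chromophore axis ordered (HbO, HbR).
#' @export
mbll_invert <- function(optical, mbll = default_mbll_config()) {
  stopifnot(inherits(optical, "optical_recording"))
  d <- dim(optical$data)
  if (d[2] != 2) stop("recording must have exactly 2 wavelengths")
  pl <- mbll_pathlength(mbll)
  Einv <- solve(mbll$extinction)  # singularity checked at config time
  conc <- array(0, dim = c(d[1], 2, d[3]),
                dimnames = list(NULL, c("HbO", "HbR"), NULL))
  y1 <- matrix(optical$data[, 1, ], d[1], d[3]) / pl[1]
  y2 <- matrix(optical$data[, 2, ], d[1], d[3]) / pl[2]
  conc[, 1, ] <- Einv[1, 1] * y1 + Einv[1, 2] * y2
  conc[, 2, ] <- Einv[2, 1] * y1 + Einv[2, 2] * y2
  out <- list(data = conc,
              sampling_rate = optical$sampling_rate,
              subject_id = optical$subject_id,
              filtered = FALSE,
              schedule = optical$schedule)
  class(out) <- "hemo_recording"
  out
}
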