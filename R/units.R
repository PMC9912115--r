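# Internal unit system: mm / mg / s / MPa (so 1 g/cm^3 == 1 mg/mm^3 and
# MPa * mm^2 == N). Conversion happens only at the user-facing boundary,
# where the conventional plant units (kN, kg/h, rpm, min, % w/w) are used.

.unit_table <- list(
  # dimension = c(unit = factor-to-base)
  mass     = c(mg = 1, g = 1e3, kg = 1e6),
  force    = c(N = 1, kN = 1e3),
  time     = c(s = 1, min = 60, h = 3600),
  length   = c(mm = 1, cm = 10, m = 1e3),
  pressure = c(MPa = 1, kPa = 1e-3),
  density  = c(mg_mm3 = 1, g_cm3 = 1),
  massrate = c(mg_s = 1, kg_h = 1e6 / 3600)
)

#' Convert between the unit systems used at the package boundary
#'
#' The model works in a single consistent mm/mg/s/MPa system; measured and
#' reported quantities use the conventional tablet-press units (kN, kg/h,
#' g/cm^3, minutes). `unit_convert()` converts within one physical dimension.
#'
#' @param x numeric vector.
#' @param from,to unit names; both must belong to the same dimension. One of
#'   `"mg"`, `"g"`, `"kg"`, `"N"`, `"kN"`, `"s"`, `"min"`, `"h"`, `"mm"`,
#'   `"cm"`, `"m"`, `"MPa"`, `"kPa"`, `"mg_mm3"`, `"g_cm3"`, `"mg_s"`,
#'   `"kg_h"`.
#' @return numeric vector in the target unit.
#' @examples
#' unit_convert(6.9, "kg_h", "mg_s")
#' unit_convert(1343, "N", "kN")
#' @export
unit_convert <- function(x, from, to) {
  for (dim in .unit_table) {
    if (from %in% names(dim) && to %in% names(dim)) {
      return(x * unname(dim[from]) / unname(dim[to]))
    }
  }
  rlang::abort(sprintf("no conversion from '%s' to '%s' within one dimension", from, to))
}
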