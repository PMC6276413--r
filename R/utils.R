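#' Round half away from zero
#'
#' Base [round()] rounds half to even; clinical prevalence tables round
#' half away from zero (65.5 -> 66, -0.5 -> -1). Used for all integer
#' percentages reported by the package.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5), 0)  # 1 2 3
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

## internal: stop with a formatted message, no call in output
.fail <- function(...) stop(sprintf(...), call. = FALSE)

.assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .fail("'%s' must be a single finite number", name)
  invisible(x)
}

## internal: genotype frequencies for MAF q and inbreeding coefficient F.
## P(0) = (1-q)^2 + F q (1-q); P(1) = 2 q (1-q) (1-F); P(2) = q^2 + F q (1-q)
genotype_freqs <- function(q, f = 0) {
  p <- c(
    (1 - q)^2 + f * q * (1 - q),
    2 * q * (1 - q) * (1 - f),
    q^2 + f * q * (1 - q)
  )
  names(p) <- c("0", "1", "2")
  p
}

## mg/dl <-> mmol/l helpers (cholesterol 38.67, triglycerides 88.57 mg/dl
## per mmol/l)

#' Convert cholesterol between mg/dl and mmol/l
#' @param x numeric vector of concentrations.
#' @param to target unit, `"mmol"` or `"mgdl"`.
#' @return converted numeric vector.
#' @export
convert_cholesterol <- function(x, to = c("mmol", "mgdl")) {
  to <- match.arg(to)
  if (to == "mmol") x / 38.67 else x * 38.67
}

#' Convert triglycerides between mg/dl and mmol/l
#' @inheritParams convert_cholesterol
#' @return converted numeric vector.
#' @export
convert_triglycerides <- function(x, to = c("mmol", "mgdl")) {
  to <- match.arg(to)
  if (to == "mmol") x / 88.57 else x * 88.57
}

## lipid metadata used across the package: direction of the adverse
## ("risk") phenotype shift for each trait
LIPIDS <- c("tc", "ldl", "hdl", "tg")
ADVERSE_DIRECTION <- c(tc = 1, ldl = 1, hdl = -1, tg = 1)
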