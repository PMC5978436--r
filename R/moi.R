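#' Poisson multiplicity-of-infection statistics
#'
#' In a pooled lentiviral screen the number of viral integrations per cell
#' is modelled as Poisson with mean equal to the multiplicity of infection
#' (MOI). Screens are run at low MOI so that almost every infected cell
#' carries a single shRNA: at MOI 0.1 the probability that an infected cell
#' received two or more particles is about 4.9%, i.e. below 5%.
#'
#' @param moi Non-negative mean number of particles per cell.
#' @return A list of class `moi_stats` with `moi`, `p_infected`
#'   (`1 - e^-moi`), `p_multiple` (`1 - e^-moi (1 + moi)`) and
#'   `p_multiple_given_infected` (`p_multiple / p_infected`; 0 at MOI 0).
#' @export
#' @examples
#' poisson_moi_stats(0.1)$p_multiple_given_infected  # ~0.0492
poisson_moi_stats <- function(moi) {
  stopifnot(is.numeric(moi), length(moi) == 1L, is.finite(moi))
  if (moi < 0) stop("moi must be non-negative")
  p_infected <- -expm1(-moi)
  p_multiple <- 1 - exp(-moi) * (1 + moi)
  structure(list(
    moi = moi,
    p_infected = p_infected,
    p_multiple = p_multiple,
    p_multiple_given_infected =
      if (p_infected > 0) p_multiple / p_infected else 0
  ), class = "moi_stats")
}

#' @export
print.moi_stats <- function(x, ...) {
  cat(sprintf(paste0("MOI %.4g: P(infected) = %.4f, P(>=2 particles) = %.4f,",
                     " P(>=2 | infected) = %.4f\n"),
              x$moi, x$p_infected, x$p_multiple,
              x$p_multiple_given_infected))
  invisible(x)
}

#' MOI achieving a target infection fraction
#'
#' Inverts `p_infected = 1 - e^-moi`: the MOI at which a given fraction of
#' cells is infected. A dilution infecting close to 10% of cells corresponds
#' to an MOI of `-ln(0.9) ~ 0.105`, conventionally rounded to 0.1.
#'
#' @param p_infected Target infected fraction in `[0, 1)`.
#' @return The corresponding MOI.
#' @export
#' @examples
#' round(moi_for_infection_prob(0.10), 1)  # 0.1
moi_for_infection_prob <- function(p_infected) {
  stopifnot(is.numeric(p_infected), all(p_infected >= 0), all(p_infected < 1))
  -log1p(-p_infected)
}
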