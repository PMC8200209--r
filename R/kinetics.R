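# Desorption-kinetics model: Arrhenius isomer rate ratios, Maxwell-Boltzmann
# high-energy fractions, enhancement factors across a temperature change, and
# isomer-resolved desorption partitioning.
#
# Sign convention: delta_eps is stored nonnegative as the binding-strength
# excess of the trans isomer (trans minus cis physisorption potential), so the
# cis:trans desorption rate ratio is exp(+delta_eps / (kB * T)) > 1 -- the
# more weakly bound cis isomer desorbs faster, and the ratio shrinks as the
# temperature rises.

.KB_CODATA <- 1.987204e-3  # Boltzmann (gas) constant, kcal mol^-1 K^-1

#' Named Boltzmann-constant profile
#'
#' The kinetics engine runs under a named constants profile. `"codata"` is
#' the standard value, 1.987204e-3 kcal/(mol K). `"paper_effective"` is the
#' effective constant calibrated with [fit_effective_kB()] on the
#' `delta_eps = 8` row of the bundled reference rate table (about 5% below
#' the standard value); the reference table is internally consistent with
#' that constant but not with the standard one, so both behaviors are
#' available and every replica output states which profile produced it.
#'
#' @param name `"codata"` or `"paper_effective"`.
#' @return An object of class `constants_profile` with fields `name` and
#'   `kB` (kcal/(mol K)).
#' @export
constants_profile <- function(name = c("codata", "paper_effective")) {
  name <- match.arg(name)
  if (name == "codata")
    return(structure(list(name = "codata", kB = .KB_CODATA),
                     class = "constants_profile"))
  tab <- reference_rate_table()
  row8 <- tab[tab$delta_eps == 8.0, ]
  fit_effective_kB(data.frame(delta_eps = row8$delta_eps,
                              T = celsius_to_kelvin(row8$temp_c),
                              ratio = row8$ratio))
}

#' @export
print.constants_profile <- function(x, ...) {
  cat(sprintf("<constants_profile> %s: kB = %.6e kcal/(mol K)\n", x$name, x$kB))
  invisible(x)
}

#' Convert Celsius to Kelvin
#' @param temp_c Temperature(s) in degrees Celsius.
#' @return Temperature(s) in kelvin (`temp_c + 273.15`).
#' @export
celsius_to_kelvin <- function(temp_c) temp_c + 273.15

#' Literature reference table of relative desorption rates
#'
#' The published cis:trans relative desorption rates of MCHM from amorphous
#' carbon, tabulated over binding-difference values
#' `delta_eps` in \{1.3, 2.4, 4.0, 8.0\} kcal/mol and temperatures 0-30
#' degrees C. Used as calibration input for the `"paper_effective"` constants
#' profile and as the replica comparison reference.
#'
#' @return Data frame with columns `delta_eps` (kcal/mol), `temp_c` (deg C),
#'   `ratio` (dimensionless).
#' @export
reference_rate_table <- function() {
  path <- system.file("extdata", "reference_rate_table.csv",
                      package = "carbsorb", mustWork = TRUE)
  utils::read.csv(path)
}

#' Arrhenius cis:trans desorption rate ratio
#'
#' `exp(delta_eps / (kB * T))`: the ratio of the desorption rate of the more
#' weakly bound (cis) isomer to that of the more strongly bound (trans)
#' isomer whose activation energy is larger by `delta_eps`.
#'
#' @param delta_eps Binding difference (trans minus cis), kcal/mol.
#' @param T Temperature, kelvin.
#' @param profile A [constants_profile()].
#' @return Dimensionless rate ratio (vectorized).
#' @export
rate_ratio <- function(delta_eps, T, profile = constants_profile("codata")) {
  stopifnot(inherits(profile, "constants_profile"), all(T > 0))
  exp(delta_eps / (profile$kB * T))
}

#' Calibrate an effective Boltzmann constant from rate-ratio cells
#'
#' Least-squares fit of `kB` minimizing `sum((ln r - delta_eps/(kB*T))^2)`
#' over the supplied cells; linear in `1/kB`, so the fit is closed-form. A
#' single cell reduces to exact inversion `kB = delta_eps / (T * ln r)`.
#'
#' @param cells Data frame with columns `delta_eps` (kcal/mol), `T` (kelvin),
#'   `ratio` (> 1).
#' @return A `constants_profile` named `"paper_effective"`, with the fitted
#'   cells kept in the `"cells"` attribute.
#' @export
fit_effective_kB <- function(cells) {
  stopifnot(is.data.frame(cells), nrow(cells) >= 1,
            all(c("delta_eps", "T", "ratio") %in% names(cells)))
  if (any(cells$delta_eps == 0))
    stop("degenerate cells with delta_eps = 0 cannot constrain kB")
  if (any(cells$ratio <= 1)) stop("ratios must exceed 1")
  x <- cells$delta_eps / cells$T
  y <- log(cells$ratio)
  a <- sum(x * y) / sum(x^2)     # ln r = (1/kB) * (delta_eps / T)
  out <- structure(list(name = "paper_effective", kB = 1 / a),
                   class = "constants_profile")
  attr(out, "cells") <- cells
  out
}

#' Maxwell-Boltzmann high-energy fraction
#'
#' The fraction of the Maxwell-Boltzmann energy distribution lying above the
#' desorption barrier `Ea`: the regularized upper incomplete gamma function
#' `Q(3/2, x)` with `x = Ea/(kB*T)`, evaluated in closed form as
#' `erfc(sqrt(x)) + (2/sqrt(pi)) * sqrt(x) * exp(-x)`.
#'
#' @param Ea Desorption activation energy (physisorption potential), kcal/mol,
#'   nonnegative.
#' @param T Temperature, kelvin.
#' @param profile A [constants_profile()].
#' @return Fraction in (0, 1] (vectorized).
#' @export
high_energy_fraction <- function(Ea, T, profile = constants_profile("codata")) {
  stopifnot(all(Ea >= 0), all(T > 0), inherits(profile, "constants_profile"))
  x <- Ea / (profile$kB * T)
  # erfc(z) = 2 * pnorm(z * sqrt(2), lower.tail = FALSE)
  2 * stats::pnorm(sqrt(2 * x), lower.tail = FALSE) +
    (2 / sqrt(pi)) * sqrt(x) * exp(-x)
}

#' Total desorption-rate enhancement factor
#'
#' Ratio of the Maxwell-Boltzmann high-energy fractions above the barrier at
#' two temperatures: how much the total desorption rate grows when the
#' temperature rises from `T1` to `T2`.
#'
#' @param Ea Desorption barrier, kcal/mol.
#' @param T1,T2 Temperatures, kelvin.
#' @param profile A [constants_profile()].
#' @return Dimensionless enhancement factor; 1 when `T1 == T2`.
#' @export
enhancement_factor <- function(Ea, T1, T2,
                               profile = constants_profile("codata")) {
  high_energy_fraction(Ea, T2, profile) / high_energy_fraction(Ea, T1, profile)
}

#' Partition desorbing molecules between isomers
#'
#' Assuming equal adsorbed populations of the two isomers, a cis:trans rate
#' ratio `r` splits `total` desorbing molecules as `n_cis = total*r/(1+r)`
#' and `n_trans = total/(1+r)`, optionally rounded to the nearest integer.
#'
#' @param total Total number of desorbing molecules, nonnegative.
#' @param ratio cis:trans rate ratio, positive.
#' @param rounding `"none"` (exact, counts sum to `total` exactly) or
#'   `"nearest"` (integer counts; the sum may differ from `total` by 1).
#' @return An object of class `partition_result` with `total`, `n_cis`,
#'   `n_trans`, `rounding`.
#' @export
partition_desorbed <- function(total, ratio, rounding = c("none", "nearest")) {
  rounding <- match.arg(rounding)
  stopifnot(total >= 0, ratio > 0)
  n_cis <- total * ratio / (1 + ratio)
  n_trans <- total / (1 + ratio)
  if (rounding == "nearest") {
    n_cis <- round(n_cis); n_trans <- round(n_trans)
  }
  structure(list(total = total, n_cis = n_cis, n_trans = n_trans,
                 rounding = rounding),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> total %s -> cis %s / trans %s (%s rounding)\n",
              format(x$total), format(x$n_cis), format(x$n_trans), x$rounding))
  invisible(x)
}

#' Isomer-specific enhancement factors from two partitions
#'
#' Given the isomer split of the desorbing population at a reference
#' temperature and at an elevated temperature, the isomer-specific
#' enhancement factors are the count ratios
#' `EF_cis = n_cis(T2)/n_cis(T1)` and `EF_trans = n_trans(T2)/n_trans(T1)`;
#' `EF_total` is the total-count ratio. When both partitions carry
#' nearest-integer rounding the ratios are taken over the rounded counts
#' (replica convention); exact counts are used otherwise.
#'
#' @param partition_T1,partition_T2 [partition_desorbed()] results sharing
#'   the same rounding mode.
#' @return An object of class `ef_result` with `EF_total`, `EF_cis`,
#'   `EF_trans`.
#' @export
isomer_specific_EF <- function(partition_T1, partition_T2) {
  stopifnot(inherits(partition_T1, "partition_result"),
            inherits(partition_T2, "partition_result"))
  if (!identical(partition_T1$rounding, partition_T2$rounding))
    stop("partitions must share the same rounding mode")
  if (partition_T1$n_trans == 0 || partition_T1$n_cis == 0)
    stop("zero denominator count at the reference temperature")
  structure(list(
    EF_total = (partition_T2$n_cis + partition_T2$n_trans) /
      (partition_T1$n_cis + partition_T1$n_trans),
    EF_cis = partition_T2$n_cis / partition_T1$n_cis,
    EF_trans = partition_T2$n_trans / partition_T1$n_trans
  ), class = "ef_result")
}

#' @export
print.ef_result <- function(x, ...) {
  cat(sprintf("<ef_result> EF_total = %.3f, EF_cis = %.3f, EF_trans = %.3f\n",
              x$EF_total, x$EF_cis, x$EF_trans))
  invisible(x)
}

#' Replica of the relative-desorption-rate table
#'
#' Evaluates [rate_ratio()] over the standard grid
#' `delta_eps` in \{1.3, 2.4, 4.0, 8.0\} kcal/mol by temperatures
#' \{0, 10, 20, 30\} degrees C under the given constants profile.
#'
#' @param profile A [constants_profile()].
#' @return Data frame with columns `delta_eps`, `temp_c`, `ratio`, `profile`.
#' @export
table2_replica <- function(profile = constants_profile("paper_effective")) {
  grid <- expand.grid(temp_c = c(0, 10, 20, 30),
                      delta_eps = c(1.3, 2.4, 4.0, 8.0))[, 2:1]
  grid$ratio <- rate_ratio(grid$delta_eps, celsius_to_kelvin(grid$temp_c),
                           profile)
  grid$profile <- profile$name
  rownames(grid) <- NULL
  grid
}

#' Enhancement-factor curves over a barrier grid
#'
#' Total and isomer-specific enhancement factors, relative to the rate at
#' `T1`, as a function of the (cis) desorption barrier, for one or more
#' elevated temperatures. Exact (unrounded) partition arithmetic is used.
#'
#' @param delta_eps Isomer binding difference, kcal/mol (default 2.4).
#' @param Ea_grid Positive barrier grid, kcal/mol.
#' @param T1 Reference temperature, kelvin (default 273.15).
#' @param T2_list Elevated temperatures, kelvin (default +10 K and +30 K).
#' @param profile A [constants_profile()].
#' @return Data frame with columns `Ea`, `T1`, `T2`, `EF_total`, `EF_cis`,
#'   `EF_trans`, `profile`.
#' @export
ef_curve <- function(delta_eps = 2.4, Ea_grid = seq(1, 20, by = 0.5),
                     T1 = 273.15, T2_list = c(283.15, 303.15),
                     profile = constants_profile("codata")) {
  stopifnot(all(Ea_grid > 0), T1 > 0, all(T2_list > 0))
  r1 <- rate_ratio(delta_eps, T1, profile)
  out <- do.call(rbind, lapply(T2_list, function(T2) {
    r2 <- rate_ratio(delta_eps, T2, profile)
    eft <- enhancement_factor(Ea_grid, T1, T2, profile)
    data.frame(Ea = Ea_grid, T1 = T1, T2 = T2,
               EF_total = eft,
               EF_cis = eft * (r2 / (1 + r2)) / (r1 / (1 + r1)),
               EF_trans = eft * (1 + r1) / (1 + r2),
               profile = profile$name)
  }))
  rownames(out) <- NULL
  out
}
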