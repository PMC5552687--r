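# Thermodynamic-cycle composition of solution-phase free energies and
# transition-state-theory rate constants.

#' Compose a solvation thermodynamic cycle
#'
#' Combines a gas-phase barrier and reaction energy with solvation free
#' energies of the reactant complex, transition state and product complex to
#' estimate the solution-phase profile:
#' `barrier_solution = barrier_gas + dG_solv(TS) - dG_solv(RC)` and
#' `reaction_solution = reaction_gas + dG_solv(PC) - dG_solv(RC)`. Exact
#' arithmetic; equal solvation free energies cancel and return the gas
#' values.
#'
#' @param gas_barrier Gas-phase barrier height (kcal/mol).
#' @param gas_reaction Gas-phase reaction energy (kcal/mol).
#' @param gsolv_reactant,gsolv_ts,gsolv_product Solvation free energies of
#'   the three states (kcal/mol).
#' @return A one-row tibble of class `solvation_cycle` with the inputs and
#'   the derived `solution_barrier` and `solution_reaction`.
#' @export
#' @examples
#' cycle_compose(19.2, 7.6, -25.2, -17.3, -17.3)
cycle_compose <- function(gas_barrier, gas_reaction, gsolv_reactant,
                          gsolv_ts, gsolv_product) {
  vals <- c(gas_barrier, gas_reaction, gsolv_reactant, gsolv_ts,
            gsolv_product)
  if (any(!is.finite(vals))) stop("all five cycle inputs must be finite")
  out <- tibble::tibble(
    gas_barrier = gas_barrier,
    gas_reaction = gas_reaction,
    gsolv_reactant = gsolv_reactant,
    gsolv_ts = gsolv_ts,
    gsolv_product = gsolv_product,
    solution_barrier = gas_barrier + gsolv_ts - gsolv_reactant,
    solution_reaction = gas_reaction + gsolv_product - gsolv_reactant
  )
  class(out) <- c("solvation_cycle", class(out))
  out
}

#' Transition-state-theory rate constant
#'
#' `k = A * exp(-dW / RT)` with the thermodynamic prefactor
#' `A = (k_B T / h) * (R T / P)` expressed per molecule, i.e. in
#' cm^3/molecule/s. The bimolecular standard-state volume factor is part of
#' the prefactor's definition here even for a unimolecular step, because the
#' reported reference rates carry those units; the nearest power of ten
#' (`round(log10 k)`) is the quantity used for order-of-magnitude
#' comparisons.
#'
#' @param barrier Free-energy barrier dW (kcal/mol).
#' @param temperature Temperature (K, default 298.15).
#' @param pressure Standard-state pressure (atm, default 1).
#' @return A one-row tibble of class `rate_result`: `barrier`, `temperature`,
#'   `prefactor`, `rate` (both cm^3/molecule/s), `log10_rate`,
#'   `order_of_magnitude`.
#' @export
#' @examples
#' tst_rate(19.2)$order_of_magnitude  # -21
#' tst_rate(31.6)$order_of_magnitude  # -30
tst_rate <- function(barrier, temperature = 298.15, pressure = 1) {
  if (temperature <= 0) stop("temperature must be positive")
  if (pressure <= 0) stop("pressure must be positive")
  kBT <- .consts$kB * temperature                  # J
  P <- pressure * .consts$atm                      # Pa
  # (kB T / h) [1/s] * (kB T / P) [m^3/molecule] -> cm^3/molecule/s
  A <- (kBT / .consts$h) * (kBT / P) * 1e6
  RT <- .consts$R_kcal * temperature               # kcal/mol
  k <- A * exp(-barrier / RT)
  out <- tibble::tibble(
    barrier = barrier, temperature = temperature, pressure = pressure,
    prefactor = A, rate = k, log10_rate = log10(k),
    order_of_magnitude = round(log10(k))
  )
  class(out) <- c("rate_result", class(out))
  out
}

#' Orders of magnitude between two barriers' rates
#'
#' `(barrier_b - barrier_a) / (RT ln 10)`: the base-10 log of the rate ratio
#' `k(barrier_a) / k(barrier_b)` at a common temperature. The prefactor
#' cancels analytically, so the result is independent of the standard-state
#' pressure.
#'
#' @param barrier_a,barrier_b Barriers (kcal/mol).
#' @param temperature Temperature (K).
#' @return A one-row tibble with `orders` and `orders_rounded`.
#' @export
#' @examples
#' rate_ratio_orders(19.2, 31.6)$orders_rounded  # 9
rate_ratio_orders <- function(barrier_a, barrier_b, temperature = 298.15) {
  if (temperature <= 0) stop("temperature must be positive")
  RT <- .consts$R_kcal * temperature
  orders <- (barrier_b - barrier_a) / (RT * log(10))
  tibble::tibble(orders = orders, orders_rounded = round(orders))
}
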