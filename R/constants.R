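#' Molar gas constant in kcal/(mol K)
#'
#' All energies in this package are molar (kcal/mol), so the Boltzmann
#' constant and the gas constant coincide: [kB_molar] is an alias of
#' `R_gas`. Heat capacities are kcal/(mol K) and free energies kcal/mol
#' throughout.
#'
#' @format A length-one numeric, 1.9872e-3 kcal/(mol K).
#' @export
R_gas <- 1.9872e-3

#' @rdname R_gas
#' @format NULL
#' @export
kB_molar <- R_gas
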