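# Physical constants (CODATA 2018) and isotope properties.

.const <- list(
  hbar = 1.054571817e-34,   # J s
  kB   = 1.380649e-23,      # J/K
  Rgas = 8.314462618        # J/(mol K)
)

# gyromagnetic ratios, rad s^-1 T^-1
.gyromagnetic <- c(
  "1H"  = 2.6752218744e8,
  "13C" = 6.728284e7,
  "15N" = -2.7116e7,
  "19F" = 2.518148e8,
  "31P" = 1.08394e8
)

#' Gyromagnetic ratio of an isotope
#'
#' @param isotope Isotope label, e.g. `"1H"` or `"13C"`.
#' @return Gyromagnetic ratio in rad s^-1 T^-1.
#' @examples
#' gyromagnetic_ratio("1H") / gyromagnetic_ratio("13C") # ~ 3.98
#' @export
gyromagnetic_ratio <- function(isotope) {
  if (!isotope %in% names(.gyromagnetic)) {
    stop("unknown isotope: ", isotope, call. = FALSE)
  }
  unname(.gyromagnetic[[isotope]])
}

# proton counts used for internal-standard referencing
.molecule_protons <- c(
  fumarate        = 2,   # two vinylic protons
  cp_star         = 15,  # pentamethylcyclopentadienyl ligand
  sodium_acetate  = 3,   # methyl group
  h2              = 2
)
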