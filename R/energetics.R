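#' Read a molecular-mechanics energetics table
#'
#' Reads a CSV of per-species MMFF94(aq) optimization outputs with
#' columns `species`, `final_energy_kJ_mol`, `solvation_energy_kJ_mol`,
#' `dipole_D`. The packaged table of published values for chondroitin
#' sulfate, the proteinoid (L-Glu:L-Asp:L-Phe) and their complex ships
#' at `system.file("extdata", "mmff94_energetics.csv",
#' package = "protospike")` and is the default.
#'
#' @param path CSV path; default the packaged table.
#' @return data.frame with one row per species.
#' @export
read_energetics_table <- function(path = system.file(
    "extdata", "mmff94_energetics.csv", package = "protospike")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("energetics table not found", call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "final_energy_kJ_mol", "solvation_energy_kJ_mol",
            "dipole_D")
  if (!all(need %in% names(df))) {
    stop(sprintf("energetics table must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  num <- need[-1L]
  if (!all(vapply(df[num], function(x) all(is.finite(x)), logical(1)))) {
    stop("non-finite values in energetics table", call. = FALSE)
  }
  df
}

#' Complexation deltas over molecular-mechanics energetics
#'
#' For each property (final energy, solvation energy, dipole moment),
#' sums the component values and reports the delta
#' `complex - sum(components)`. A negative final-energy delta indicates
#' a favorable complexation; the published chondroitin
#' sulfate + proteinoid example gives component sums of -64.23 kJ/mol
#' (final), -346.87 kJ/mol (solvation) and 13.402 D (dipole).
#'
#' @param complex single-row data.frame (or list) with the complex's
#'   `final_energy_kJ_mol`, `solvation_energy_kJ_mol`, `dipole_D`.
#' @param components data.frame of component rows, same columns, at
#'   least one row.
#' @return data.frame with columns `property`, `complex`,
#'   `component_sum`, `delta` (one row per property).
#' @examples
#' tab <- read_energetics_table()
#' complexation_deltas(tab[3, ], tab[1:2, ])
#' @export
complexation_deltas <- function(complex, components) {
  components <- as.data.frame(components)
  if (nrow(components) < 1L) stop("need at least one component",
                                  call. = FALSE)
  props <- c(final_energy = "final_energy_kJ_mol",
             solvation_energy = "solvation_energy_kJ_mol",
             dipole_moment = "dipole_D")
  stopifnot(all(props %in% names(components)))
  cx <- vapply(props, function(p) as.numeric(complex[[p]]), numeric(1))
  sums <- vapply(props, function(p) sum(components[[p]]), numeric(1))
  data.frame(property = names(props),
             complex = unname(cx),
             component_sum = unname(sums),
             delta = unname(cx - sums),
             row.names = NULL)
}
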