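#' Model assumptions controlling the species set
#'
#' The mass balances close at 18 molecular forms when free monomers are
#' allowed to partition into the nucleus (partition coefficients `Ktm_u`,
#' `Ktm_s`). Disabling monomer partitioning removes the two nuclear monomer
#' forms and closes the system at 16 forms; the equilibrium structure of all
#' other species is unchanged.
#'
#' @param monomer_partitioning logical; do free monomers equilibrate between
#'   cytoplasm and nucleus? Default `TRUE`.
#' @return An object of class `model_assumptions`.
#' @export
model_assumptions <- function(monomer_partitioning = TRUE) {
  stopifnot(is.logical(monomer_partitioning),
            length(monomer_partitioning) == 1, !is.na(monomer_partitioning))
  structure(list(monomer_partitioning = monomer_partitioning),
            class = "model_assumptions")
}

#' Enumerate the molecular forms of the model
#'
#' Returns the ordered table of distinct molecular species tracked by the
#' model: cytoplasmic monomers, the three dimer compositions (UU, US, SS) as
#' free cytoplasmic dimers, Cactus-bound dimers, nuclear dimers and
#' promoter-bound dimers, plus free Cactus, free promoter and (by default)
#' the two nuclear monomers. One steady-state mass balance is written per
#' form, so the default enumeration corresponds to 18 algebraic equations,
#' alongside the 4 conservation equations for the U, S, Cactus and promoter
#' pools.
#'
#' The ordering is stable: cytoplasmic monomers, nuclear monomers,
#' cytoplasmic free dimers, Cactus-bound dimers, nuclear dimers,
#' promoter-bound dimers (each in UU, US, SS order), free Cactus, free
#' promoter. Species names in this table are the names used for every
#' concentration vector in the package.
#'
#' @param assumptions a [model_assumptions()] object.
#' @return A data.frame with columns `name`, `role`, `n_u`, `n_s`
#'   (subunit composition) and `compartment`; 18 rows by default, 16 with
#'   monomer partitioning disabled.
#' @examples
#' nrow(enumerate_species())                                   # 18
#' nrow(enumerate_species(model_assumptions(FALSE)))           # 16
#' @export
enumerate_species <- function(assumptions = model_assumptions()) {
  stopifnot(inherits(assumptions, "model_assumptions"))
  sp <- function(name, role, n_u, n_s, compartment)
    data.frame(name = name, role = role, n_u = n_u, n_s = n_s,
               compartment = compartment, stringsAsFactors = FALSE)
  dimers <- function(prefix, role, compartment)
    rbind(sp(paste0(prefix, "UU"), role, 2L, 0L, compartment),
          sp(paste0(prefix, "US"), role, 1L, 1L, compartment),
          sp(paste0(prefix, "SS"), role, 0L, 2L, compartment))
  out <- rbind(
    sp("U_cyt", "monomer", 1L, 0L, "cytoplasm"),
    sp("S_cyt", "monomer", 0L, 1L, "cytoplasm"),
    if (assumptions$monomer_partitioning)
      rbind(sp("U_nuc", "monomer", 1L, 0L, "nucleus"),
            sp("S_nuc", "monomer", 0L, 1L, "nucleus")),
    dimers("", "free dimer", "cytoplasm"),
    dimers("Cact_", "Cactus-bound dimer", "cytoplasm"),
    dimers("nuc_", "nuclear dimer", "nucleus"),
    dimers("P_", "promoter-bound dimer", "nucleus"),
    sp("Cact_free", "free Cactus", 0L, 0L, "cytoplasm"),
    sp("P_free", "free promoter", 0L, 0L, "nucleus"))
  rownames(out) <- NULL
  out
}

# canonical species name order for the default (18-form) closure
species_names <- function(assumptions = model_assumptions()) {
  enumerate_species(assumptions)$name
}
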