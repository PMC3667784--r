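#' @include RcppExports.R
NULL

#' Species table of a network or trajectory
#'
#' @param x a \linkS4class{ReactionNetwork} or \linkS4class{Trajectory}.
#' @return A \code{data.frame} with one row per molecular species: canonical
#'   name, monomer composition (\code{m14}, \code{t2}, \code{m2},
#'   \code{m2act}, \code{ecm}), localization and M14a activity weight.
#' @export
setGeneric("speciesTable", function(x) standardGeneric("speciesTable"))

#' Reaction table of a network
#'
#' @param x a \linkS4class{ReactionNetwork}.
#' @return A \code{data.frame} with one row per reaction (reactants,
#'   products, rate constant, tag).
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' Number of species
#' @param x a \linkS4class{ReactionNetwork}.
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))

#' Number of reactions
#' @param x a \linkS4class{ReactionNetwork}.
#' @export
setGeneric("nReactions", function(x) standardGeneric("nReactions"))

#' Species names
#' @param x a \linkS4class{ReactionNetwork} or \linkS4class{Trajectory}.
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' Time grid of a trajectory
#' @param x a \linkS4class{Trajectory}.
#' @export
setGeneric("trajTimes", function(x) standardGeneric("trajTimes"))

#' Concentration series
#'
#' @param x a \linkS4class{Trajectory}.
#' @param species character vector of species names; all species if missing.
#' @return Numeric matrix (time by species), in nM.
#' @export
setGeneric("concentrations", function(x, species) standardGeneric("concentrations"))
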