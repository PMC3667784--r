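#' @include AllGenerics.R
NULL

#' Mass-action reaction network of the MT1-MMP / TIMP-2 / MMP-2 system
#'
#' Container for the enumerated molecular species and the mass-action
#' reactions connecting them.  Species carry their monomer composition
#' (counts of MT1-MMP, TIMP-2, proMMP-2, active MMP-2 and bound ECM units),
#' their localization (membrane pool or solution) and their contribution per
#' molecule to the M14a activity measure (the dimer counts twice; the free
#' monomer and the two half-inhibited dimer forms count once; everything
#' else is inactive).
#'
#' @slot species \code{data.frame} with columns \code{name}, \code{m14},
#'   \code{t2}, \code{m2}, \code{m2act}, \code{ecm}, \code{location}
#'   (one of \code{"membrane"}, \code{"membrane_X"}, \code{"membrane_D"},
#'   \code{"solution"}), \code{pool} (\code{NA}, \code{"X"} or \code{"D"})
#'   and \code{activity_weight}.
#' @slot reactions \code{data.frame} with columns \code{r1}, \code{r2}
#'   (reactant names, \code{NA} if absent; each reactant occurrence
#'   consumes one copy), \code{p1}, \code{p2}, \code{p3} (product names),
#'   \code{n1}..\code{n3} (product stoichiometries), \code{k} (rate
#'   constant, 1/s or 1/(nM s)), \code{tag}, \code{type}
#'   (\code{"mass_action"} or \code{"insertion"}), \code{pool}, \code{mf0}
#'   and \code{dist} (named delta vector overriding the product columns;
#'   carries distributed insertion and ECM-releasing internalization).
#' @slot metadata list recording the variant (options, deletions applied,
#'   shedding, pools) and the parameter set used.
#' @export
setClass("ReactionNetwork",
  representation(species = "data.frame", reactions = "data.frame",
                 metadata = "list"))

setValidity("ReactionNetwork", function(object) {
  sp <- object@species
  rx <- object@reactions
  msg <- character()
  if (anyDuplicated(sp$name)) msg <- c(msg, "species names must be unique")
  refd <- unique(stats::na.omit(unlist(rx[, c("r1", "r2", "p1", "p2", "p3")],
                                       use.names = FALSE)))
  missing_sp <- setdiff(refd, sp$name)
  if (length(missing_sp))
    msg <- c(msg, paste0("reactions reference unknown species: ",
                         paste(missing_sp, collapse = ", ")))
  if (any(rx$k < 0, na.rm = TRUE)) msg <- c(msg, "rate constants must be >= 0")
  # composition bookkeeping: mass-action reactions conserve monomer
  # equivalents, except proMMP-2 activation (M2 -> M2act) and ECM cleavage
  # (one ECM unit removed)
  if (nrow(rx) && length(missing_sp) == 0) {
    comp <- as.matrix(sp[, c("m14", "t2", "m2", "m2act", "ecm")])
    rownames(comp) <- sp$name
    for (i in seq_len(nrow(rx))) {
      if (rx$type[i] != "mass_action") next
      if (rx$tag[i] %in% c("internalization", "insertion")) next
      bal <- numeric(5)
      for (side in c("r1", "r2")) {
        nm <- rx[[side]][i]
        if (!is.na(nm)) bal <- bal - comp[nm, ]
      }
      for (p in 1:3) {
        nm <- rx[[paste0("p", p)]][i]
        if (!is.na(nm)) bal <- bal + as.numeric(rx[[paste0("n", p)]][i]) * comp[nm, ]
      }
      ok <- switch(rx$tag[i],
        activation   = all(bal[c(1, 2, 5)] == 0) && bal[3] == -1 && bal[4] == 1,
        ecm_cleavage = all(bal[1:4] == 0) && bal[5] == -1,
        all(bal == 0))
      if (!ok)
        msg <- c(msg, paste0("reaction ", i, " (", rx$tag[i],
                             ") violates composition bookkeeping"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Concentration time courses from the RK4 integrator
#'
#' @slot times numeric, strictly increasing time grid (s).
#' @slot states numeric matrix (time by species), concentrations in nM.
#' @slot species species table (as in \linkS4class{ReactionNetwork}).
#' @slot events \code{data.frame} of applied pulses: \code{time},
#'   \code{pool}, \code{requested}, \code{applied} (nM).
#' @slot metadata list (dt, variant, seed, ...).
#' @export
setClass("Trajectory",
  representation(times = "numeric", states = "matrix", species = "data.frame",
                 events = "data.frame", metadata = "list"))

setValidity("Trajectory", function(object) {
  msg <- character()
  if (length(object@times) != nrow(object@states))
    msg <- c(msg, "states row count must equal times length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Membrane docking pool for MT1-MMP turnover
#'
#' The invadopodial membrane carries two kinetically distinct docking pools
#' for MT1-MMP, X (slow, FRAP time constant 259 s) and D (fast, 26.0 s),
#' with maximum docking-site concentrations of 3 nM and 7 nM.
#'
#' @slot pool_id \code{"X"} or \code{"D"}.
#' @slot M_F0 maximum docking-site concentration (nM).
#' @slot k_ins continuous insertion rate constant (1/s).
#' @slot k_int internalization rate constant (1/s).
#' @export
setClass("PoolConfig",
  representation(pool_id = "character", M_F0 = "numeric", k_ins = "numeric",
                 k_int = "numeric"))

setValidity("PoolConfig", function(object) {
  msg <- character()
  if (!object@pool_id %in% c("X", "D")) msg <- c(msg, "pool_id must be 'X' or 'D'")
  if (!is.finite(object@M_F0) || object@M_F0 <= 0) msg <- c(msg, "M_F0 must be > 0")
  if (object@k_ins < 0 || object@k_int < 0) msg <- c(msg, "rates must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Description of MT1-MMP delivery to a membrane pool
#'
#' @slot mode \code{"continuous"} or \code{"pulsatile"}.
#' @slot interval_mode \code{"regular"} or \code{"random"} (exponential
#'   waiting times with the regular mean).
#' @slot amount_mode \code{"regular"} or \code{"random"} (uniform on
#'   \code{[0, 2 PH]}, mean PH).
#' @slot PH single-insertion amount per pool, named numeric (nM).
#' @slot freq_fold,conc_fold fold changes of frequency and single-insertion
#'   amount against the control regimen; their product is 1 when the
#'   time-averaged delivery is to be conserved.
#' @slot seed integer RNG seed (used when any mode is random).
#' @export
setClass("InsertionSchedule",
  representation(mode = "character", interval_mode = "character",
                 amount_mode = "character", PH = "numeric",
                 freq_fold = "numeric", conc_fold = "numeric",
                 seed = "integer"))

setValidity("InsertionSchedule", function(object) {
  msg <- character()
  if (!object@mode %in% c("continuous", "pulsatile"))
    msg <- c(msg, "mode must be continuous or pulsatile")
  if (!object@interval_mode %in% c("regular", "random"))
    msg <- c(msg, "interval_mode must be regular or random")
  if (!object@amount_mode %in% c("regular", "random"))
    msg <- c(msg, "amount_mode must be regular or random")
  if (any(object@PH < 0)) msg <- c(msg, "PH must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Compartment lattice for the reaction-diffusion model
#'
#' @slot extent physical extent in metres, length 3 (default 5 x 5 x 3 um).
#' @slot divisions integer divisions, length 3 (default 51 x 51 x 1).
#' @slot mask integer indices (1-based, x-fastest) of invadopodium
#'   compartments.
#' @slot diffusing character names of diffusing species.
#' @slot D diffusion coefficients (m^2/s), named after \code{diffusing}.
#' @export
setClass("SpatialGrid",
  representation(extent = "numeric", divisions = "integer", mask = "integer",
                 diffusing = "character", D = "numeric"))

setValidity("SpatialGrid", function(object) {
  msg <- character()
  if (length(object@extent) != 3 || any(object@extent <= 0))
    msg <- c(msg, "extent must be 3 positive lengths (m)")
  if (length(object@divisions) != 3 || any(object@divisions < 1))
    msg <- c(msg, "divisions must be 3 positive integers")
  nc <- prod(object@divisions[1:2])
  if (length(object@mask) && (min(object@mask) < 1 || max(object@mask) > nc))
    msg <- c(msg, "mask indices outside the lattice")
  if (length(object@D) != length(object@diffusing) || any(object@D < 0))
    msg <- c(msg, "one non-negative D per diffusing species required")
  if (length(msg)) msg else TRUE
})

## ---- show methods ----

setMethod("show", "ReactionNetwork", function(object) {
  md <- object@metadata
  cat("ReactionNetwork:", nrow(object@species), "species,",
      nrow(object@reactions), "reactions\n")
  opts <- md$options
  if (!is.null(opts))
    cat("  variant: pools=", opts$pools, ", ecm=", opts$include_ecm,
        ", shedding=", opts$include_shedding, "\n", sep = "")
  if (length(md$deletions))
    cat("  path deletions applied:", paste(md$deletions, collapse = ","), "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@times), "time points over [",
      object@times[1], ",", object@times[length(object@times)], "] s,",
      ncol(object@states), "species\n")
  if (nrow(object@events))
    cat("  ", nrow(object@events), "insertion events applied\n")
})

setMethod("show", "PoolConfig", function(object) {
  cat("PoolConfig ", object@pool_id, ": M_F0 = ", object@M_F0,
      " nM, k_ins = ", signif(object@k_ins, 4), " /s, k_int = ",
      signif(object@k_int, 4), " /s (tau = ", signif(1 / object@k_ins, 4),
      " s)\n", sep = "")
})

setMethod("show", "InsertionSchedule", function(object) {
  cat("InsertionSchedule:", object@mode)
  if (object@mode == "pulsatile")
    cat(" (intervals ", object@interval_mode, ", amounts ",
        object@amount_mode, ", folds ", object@freq_fold, "/",
        object@conc_fold, ")", sep = "")
  cat("\n")
})

setMethod("show", "SpatialGrid", function(object) {
  cat("SpatialGrid: ", paste(object@divisions, collapse = " x "),
      " compartments over ", paste(signif(object@extent * 1e6, 3),
                                   collapse = " x "),
      " um; |mask| = ", length(object@mask), "; diffusing: ",
      paste(object@diffusing, collapse = ", "), "\n", sep = "")
})

## ---- accessors ----

#' @rdname speciesTable
#' @export
setMethod("speciesTable", "ReactionNetwork", function(x) x@species)

#' @rdname speciesTable
#' @export
setMethod("speciesTable", "Trajectory", function(x) x@species)

#' @rdname reactions
#' @export
setMethod("reactions", "ReactionNetwork", function(x) x@reactions)

#' @rdname nSpecies
#' @export
setMethod("nSpecies", "ReactionNetwork", function(x) nrow(x@species))

#' @rdname nReactions
#' @export
setMethod("nReactions", "ReactionNetwork", function(x) nrow(x@reactions))

#' @rdname speciesNames
#' @export
setMethod("speciesNames", "ReactionNetwork", function(x) x@species$name)

#' @rdname speciesNames
#' @export
setMethod("speciesNames", "Trajectory", function(x) colnames(x@states))

#' @rdname trajTimes
#' @export
setMethod("trajTimes", "Trajectory", function(x) x@times)

#' @rdname concentrations
#' @export
setMethod("concentrations", "Trajectory", function(x, species) {
  if (missing(species)) return(x@states)
  bad <- setdiff(species, colnames(x@states))
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  x@states[, species, drop = FALSE]
})

#' Applied insertion events of a trajectory
#' @param traj a \linkS4class{Trajectory}.
#' @return \code{data.frame} with \code{time}, \code{pool},
#'   \code{requested} and \code{applied} amounts (nM).
#' @export
trajEvents <- function(traj) traj@events
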