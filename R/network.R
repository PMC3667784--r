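#' @include parameters.R
NULL

## Dimer bookkeeping: a membrane MT1-MMP unit ("arm") is in state 0 (free),
## 1 (TIMP-2 bound) or 2 (TIMP-2.proMMP-2 bound).  Dimer names concatenate
## the two arm names in ascending state order, which reproduces the
## canonical names (e.g. arms {0,2} -> "M14.M14.T2.M2").
.arm_names <- c("M14", "M14.T2", "M14.T2.M2")

.dimer_name <- function(a, b) {
  s <- sort(c(a, b))
  paste(.arm_names[s + 1], collapse = ".")
}

.sp_row <- function(name, m14 = 0, t2 = 0, m2 = 0, m2act = 0, ecm = 0,
                    location = "solution", pool = NA_character_, w = 0) {
  data.frame(name = name, m14 = m14, t2 = t2, m2 = m2, m2act = m2act,
             ecm = ecm, location = location, pool = pool,
             activity_weight = w, stringsAsFactors = FALSE)
}

.membrane_base_species <- function() {
  rbind(
    .sp_row("M14",       1, 0, 0, location = "membrane", w = 1),
    .sp_row("M14.T2",    1, 1, 0, location = "membrane", w = 0),
    .sp_row("M14.T2.M2", 1, 1, 1, location = "membrane", w = 0),
    .sp_row(.dimer_name(0, 0), 2, 0, 0, location = "membrane", w = 2),
    .sp_row(.dimer_name(0, 1), 2, 1, 0, location = "membrane", w = 1),
    .sp_row(.dimer_name(0, 2), 2, 1, 1, location = "membrane", w = 1),
    .sp_row(.dimer_name(1, 1), 2, 2, 0, location = "membrane", w = 0),
    .sp_row(.dimer_name(1, 2), 2, 2, 1, location = "membrane", w = 0),
    .sp_row(.dimer_name(2, 2), 2, 2, 2, location = "membrane", w = 0))
}

.membrane_ecm_species <- function() {
  rbind(
    .sp_row("M14.ECM",            1, 0, 0, ecm = 1, location = "membrane"),
    .sp_row("M14.M14.ECM",        2, 0, 0, ecm = 1, location = "membrane"),
    .sp_row("M14.M14.T2.ECM",     2, 1, 0, ecm = 1, location = "membrane"),
    .sp_row("M14.M14.T2.M2.ECM",  2, 1, 1, ecm = 1, location = "membrane"))
}

.poolify <- function(sp, pool) {
  sp$name <- gsub("M14", paste0("M14", pool), sp$name, fixed = TRUE)
  sp$location <- paste0("membrane_", pool)
  sp$pool <- pool
  sp
}

#' Enumerate the molecular species of the MT1-MMP network
#'
#' Returns the closed species list of the complex-formation network:
#' monomers M14, T2, M2 and active MMP-2 (M2act); the solution complexes
#' T2.M2 and T2.M2act; the nine membrane forms (monomer, TIMP-2-bound
#' monomer, ternary complex, and the six dimer states reachable by
#' hemopexin-domain dimerization of arms carrying nothing, T2, or T2.M2);
#' optionally the ECM species (free ECM, the four M14a.ECM complexes,
#' M2act.ECM) and the shed-ectodomain fragment species.  With
#' \code{pools = "XD"} every membrane species is duplicated for the two
#' invadopodial docking pools (suffix on each M14 token, e.g.
#' \code{M14X.M14X}).
#'
#' @param include_ecm include ECM and enzyme-ECM complex species.
#' @param include_shedding include the shed fragment M14f and M14f.T2.
#' @param pools \code{"single"} or \code{"XD"}.
#' @return \code{data.frame} of species (see \linkS4class{ReactionNetwork}).
#' @examples
#' sp <- enumerateSpecies()
#' stopifnot("M14.T2.M2.M14.T2.M2" %in% sp$name)
#' @export
enumerateSpecies <- function(include_ecm = FALSE, include_shedding = FALSE,
                             pools = c("single", "XD")) {
  pools <- match.arg(pools)
  sol <- rbind(
    .sp_row("T2",       t2 = 1),
    .sp_row("M2",       m2 = 1),
    .sp_row("M2act",    m2act = 1),
    .sp_row("T2.M2",    t2 = 1, m2 = 1),
    .sp_row("T2.M2act", t2 = 1, m2act = 1))
  mem <- .membrane_base_species()
  if (include_ecm) mem <- rbind(mem, .membrane_ecm_species())
  if (pools == "XD") mem <- rbind(.poolify(mem, "X"), .poolify(mem, "D"))
  out <- rbind(mem, sol)
  if (include_ecm)
    out <- rbind(out, .sp_row("ECM", ecm = 1),
                 .sp_row("M2act.ECM", m2act = 1, ecm = 1))
  if (include_shedding)
    out <- rbind(out,
                 .sp_row("M14f", m14 = 1),        # shed ectodomain fragment
                 .sp_row("M14f.T2", m14 = 1, t2 = 1))
  rownames(out) <- NULL
  out
}

## Mutable reaction-list builder (kept internal; avoids rbind-in-loop cost).
.rxn_builder <- function() {
  rows <- list()
  add <- function(r1, r2 = NA_character_, products, k, tag,
                  type = "mass_action", pool = NA_character_, mf0 = NA_real_,
                  dist = NULL) {
    p <- names(products)
    if (is.null(p)) p <- character(0)
    n <- unname(products)
    length(p) <- 3; length(n) <- 3
    rows[[length(rows) + 1]] <<- list(
      r1 = r1, r2 = r2, p1 = p[1], p2 = p[2], p3 = p[3],
      n1 = n[1], n2 = n[2], n3 = n[3], k = k, tag = tag, type = type,
      pool = pool, mf0 = mf0, dist = list(dist))
  }
  build <- function() {
    df <- do.call(rbind, lapply(rows, function(r) {
      data.frame(r[setdiff(names(r), "dist")], stringsAsFactors = FALSE)
    }))
    if (is.null(df)) {
      df <- data.frame(r1 = character(), r2 = character(), p1 = character(),
                       p2 = character(), p3 = character(), n1 = numeric(),
                       n2 = numeric(), n3 = numeric(), k = numeric(),
                       tag = character(), type = character(),
                       pool = character(), mf0 = numeric(),
                       stringsAsFactors = FALSE)
      df$dist <- list()
      return(df)
    }
    df$dist <- lapply(rows, function(r) r$dist[[1]])
    df
  }
  list(add = add, build = build)
}

## Chemistry for one membrane (pool suffix applied through `nm`).
## Site-counting convention ("distinct pair"): a rate constant is multiplied
## by the number of equivalent sites or ligands it can act on; dimerization
## of identical partners runs at k*[A]^2 with both copies consumed.
.add_membrane_chemistry <- function(b, nm, p, preassembled) {
  kon_t2 <- p$kon_t2; koff_t2 <- p$koff_t2
  kon_m2 <- p$kon_m2; koff_m2 <- p$koff_m2
  kon_d <- p$kon_dim; koff_d <- p$koff_dim
  d <- function(a, bb) nm(.dimer_name(a, bb))

  ## TIMP-2 binding to TIMP-free catalytic sites
  b$add(nm("M14"), "T2", c(stats::setNames(1, nm("M14.T2"))), kon_t2, "binding")
  b$add(nm("M14.T2"), products = c("T2" = 1, stats::setNames(1, nm("M14"))),
        k = koff_t2, tag = "dissociation")
  b$add(d(0, 0), "T2", stats::setNames(1, d(0, 1)), 2 * kon_t2, "binding")
  b$add(d(0, 1), products = c("T2" = 1, stats::setNames(1, d(0, 0))),
        k = koff_t2, tag = "dissociation")
  b$add(d(0, 1), "T2", stats::setNames(1, d(1, 1)), kon_t2, "binding")
  b$add(d(1, 1), products = c("T2" = 1, stats::setNames(1, d(0, 1))),
        k = 2 * koff_t2, tag = "dissociation")
  b$add(d(0, 2), "T2", stats::setNames(1, d(1, 2)), kon_t2, "binding")
  b$add(d(1, 2), products = c("T2" = 1, stats::setNames(1, d(0, 2))),
        k = koff_t2, tag = "dissociation")

  ## proMMP-2 docking onto membrane-bound TIMP-2
  b$add(nm("M14.T2"), "M2", stats::setNames(1, nm("M14.T2.M2")), kon_m2, "binding")
  b$add(nm("M14.T2.M2"), products = c("M2" = 1, stats::setNames(1, nm("M14.T2"))),
        k = koff_m2, tag = "dissociation")
  b$add(d(0, 1), "M2", stats::setNames(1, d(0, 2)), kon_m2, "binding")
  b$add(d(0, 2), products = c("M2" = 1, stats::setNames(1, d(0, 1))),
        k = koff_m2, tag = "dissociation")
  b$add(d(1, 1), "M2", stats::setNames(1, d(1, 2)), 2 * kon_m2, "binding")
  b$add(d(1, 2), products = c("M2" = 1, stats::setNames(1, d(1, 1))),
        k = koff_m2, tag = "dissociation")
  b$add(d(1, 2), "M2", stats::setNames(1, d(2, 2)), kon_m2, "binding")
  b$add(d(2, 2), products = c("M2" = 1, stats::setNames(1, d(1, 2))),
        k = 2 * koff_m2, tag = "dissociation")

  ## docking of the preassembled T2.M2 complex onto free MT1 sites
  if (preassembled) {
    b$add(nm("M14"), "T2.M2", stats::setNames(1, nm("M14.T2.M2")), kon_t2, "binding")
    b$add(nm("M14.T2.M2"), products = c("T2.M2" = 1, stats::setNames(1, nm("M14"))),
          k = koff_t2, tag = "dissociation")
    b$add(d(0, 0), "T2.M2", stats::setNames(1, d(0, 2)), 2 * kon_t2, "binding")
    b$add(d(0, 2), products = c("T2.M2" = 1, stats::setNames(1, d(0, 0))),
          k = koff_t2, tag = "dissociation")
    b$add(d(0, 1), "T2.M2", stats::setNames(1, d(1, 2)), kon_t2, "binding")
    b$add(d(1, 2), products = c("T2.M2" = 1, stats::setNames(1, d(0, 1))),
          k = koff_t2, tag = "dissociation")
    b$add(d(0, 2), "T2.M2", stats::setNames(1, d(2, 2)), kon_t2, "binding")
    b$add(d(2, 2), products = c("T2.M2" = 1, stats::setNames(1, d(0, 2))),
          k = 2 * koff_t2, tag = "dissociation")
  }

  ## hemopexin-domain dimerization (within one pool)
  for (a in 0:2) for (bb in a:2) {
    ra <- nm(.arm_names[a + 1]); rb <- nm(.arm_names[bb + 1])
    b$add(ra, rb, stats::setNames(1, d(a, bb)), kon_d, "binding")
    if (a == bb)
      b$add(d(a, bb), products = stats::setNames(2, ra), k = koff_d,
            tag = "dissociation")
    else
      b$add(d(a, bb), products = stats::setNames(c(1, 1), c(ra, rb)),
            k = koff_d, tag = "dissociation")
  }

  ## proMMP-2 processing by the TIMP-free arm of the quaternary complex
  b$add(d(0, 2), products = c(stats::setNames(1, d(0, 1)), "M2act" = 1),
        k = p$k_act, tag = "activation")
  invisible(b)
}

#' Build the core mass-action reaction network
#'
#' Assembles the reversible TIMP-2 binding, proMMP-2 docking (sequential
#' and, optionally, via the preassembled T2.M2 complex), hemopexin-domain
#' dimerization, irreversible proMMP-2 activation and MMP-2 inhibition
#' reactions over the species of \code{\link{enumerateSpecies}}.  ECM
#' degradation reactions are appended through
#' \code{\link{addEcmReactions}} when \code{include_ecm = TRUE};
#' ectodomain shedding through \code{\link{addEctodomainShedding}} when
#' \code{include_shedding = TRUE}.  Membrane turnover is added separately
#' (\code{\link{addContinuousTurnover}}).
#'
#' @param params named list of rate constants
#'   (\code{\link{defaultKineticParameters}}).
#' @param include_ecm include ECM degradation species and reactions.
#' @param include_shedding include ectodomain shedding.
#' @param pools \code{"single"} or \code{"XD"}.
#' @param preassembled allow the preassembled T2.M2 complex to form in
#'   solution and dock onto free MT1 sites (in addition to sequential
#'   binding).
#' @return A \linkS4class{ReactionNetwork}.
#' @examples
#' net <- buildCoreNetwork(defaultKineticParameters())
#' net
#' @export
buildCoreNetwork <- function(params = defaultKineticParameters(),
                             include_ecm = FALSE, include_shedding = FALSE,
                             pools = c("single", "XD"), preassembled = TRUE) {
  pools <- match.arg(pools)
  .check_params(params, c("kon_t2", "koff_t2", "kon_m2", "koff_m2",
                          "kon_dim", "koff_dim", "k_act", "kon_t2m2a",
                          "koff_t2m2a"))
  sp <- enumerateSpecies(include_ecm, include_shedding, pools)
  b <- .rxn_builder()
  if (preassembled)
    b$add("T2", "M2", c("T2.M2" = 1), params$kon_m2, "binding")
  if (preassembled)
    b$add("T2.M2", products = c("T2" = 1, "M2" = 1), k = params$koff_m2,
          tag = "dissociation")
  b$add("T2", "M2act", c("T2.M2act" = 1), params$kon_t2m2a, "inhibition")
  b$add("T2.M2act", products = c("T2" = 1, "M2act" = 1),
        k = params$koff_t2m2a, tag = "dissociation")
  if (pools == "single") {
    .add_membrane_chemistry(b, identity, params, preassembled)
  } else {
    for (pl in c("X", "D"))
      .add_membrane_chemistry(
        b, function(x) gsub("M14", paste0("M14", pl), x, fixed = TRUE),
        params, preassembled)
  }
  net <- methods::new("ReactionNetwork", species = sp, reactions = b$build(),
    metadata = list(options = list(pools = pools, include_ecm = include_ecm,
                                   include_shedding = include_shedding,
                                   preassembled = preassembled),
                    params = params, deletions = integer()))
  if (include_ecm) net <- addEcmReactions(net, params)
  if (include_shedding) net <- addEctodomainShedding(net, params$k_shed)
  net
}

## Deletion index -> inactive complex (base membrane name)
.deletion_map <- c("1" = "M14.T2.M2.M14.T2.M2", "2" = "M14.T2.M2",
                   "3" = "M14.T2.M14.T2.M2", "4" = "M14.T2.M14.T2",
                   "5" = "M14.T2")

#' Delete pathways through selected inactive complexes
#'
#' Removes the designated TIMP-2-inhibited complexes and every reaction
#' producing or consuming them, emulating the path-deletion analysis of the
#' transient peak: 1 = M14.T2.M2.M14.T2.M2 (highest-order inactive
#' complex), 2 = M14.T2.M2, 3 = M14.T2.M14.T2.M2, 4 = M14.T2.M14.T2,
#' 5 = M14.T2.  With pools X and D the deletion applies to both pools.
#' The operation is idempotent and commutative over deletion indices; the
#' input network is not modified.
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param deletions integer subset of 1..5.
#' @return A new \linkS4class{ReactionNetwork}.
#' @examples
#' net <- buildCoreNetwork()
#' nd <- applyPathDeletions(net, c(1, 2))
#' setdiff(speciesNames(net), speciesNames(nd))
#' @export
applyPathDeletions <- function(net, deletions) {
  deletions <- sort(unique(as.integer(deletions)))
  if (!length(deletions)) return(net)
  if (!all(deletions %in% 1:5)) stop("deletions must be a subset of 1..5")
  base <- .deletion_map[as.character(deletions)]
  pools <- net@metadata$options$pools
  targets <- if (identical(pools, "XD"))
    c(gsub("M14", "M14X", base, fixed = TRUE),
      gsub("M14", "M14D", base, fixed = TRUE))
  else base
  targets <- intersect(targets, net@species$name)
  sp <- net@species[!net@species$name %in% targets, , drop = FALSE]
  rx <- net@reactions
  touches <- rep(FALSE, nrow(rx))
  for (col in c("r1", "r2", "p1", "p2", "p3"))
    touches <- touches | (!is.na(rx[[col]]) & rx[[col]] %in% targets)
  ## distributed-insertion stoichiometries may also reference species
  if (length(rx$dist))
    touches <- touches | vapply(rx$dist, function(d)
      !is.null(d) && any(names(d) %in% targets), logical(1))
  rx <- rx[!touches, , drop = FALSE]
  refd <- unique(stats::na.omit(unlist(rx[, c("r1", "r2", "p1", "p2", "p3")],
                                       use.names = FALSE)))
  if (length(setdiff(refd, sp$name)))
    stop("internal consistency error: retained reactions reference deleted species")
  md <- net@metadata
  md$deletions <- sort(unique(c(md$deletions, deletions)))
  methods::new("ReactionNetwork", species = sp, reactions = rx, metadata = md)
}

#' Add ectodomain shedding of membrane MT1-MMP
#'
#' Adds irreversible shedding of the free membrane MT1-MMP monomer to a
#' diffusible ectodomain fragment, plus reversible fragment-TIMP-2 binding:
#' the shed fragment acts as a TIMP-2 scavenger.
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param k_shed shedding rate constant (1/s), >= 0.
#' @return A new \linkS4class{ReactionNetwork} including the fragment
#'   species and reactions.
#' @export
addEctodomainShedding <- function(net, k_shed) {
  if (!is.numeric(k_shed) || length(k_shed) != 1 || !is.finite(k_shed) ||
      k_shed < 0)
    stop("k_shed must be a single finite value >= 0")
  sp <- net@species
  if (!"M14f" %in% sp$name)
    sp <- rbind(sp, .sp_row("M14f", m14 = 1), .sp_row("M14f.T2", m14 = 1, t2 = 1))
  p <- net@metadata$params
  b <- .rxn_builder()
  m14s <- sp$name[sp$location != "solution" & sp$m14 == 1 & sp$t2 == 0 &
                  sp$ecm == 0]
  for (m in m14s)
    b$add(m, products = c("M14f" = 1), k = k_shed, tag = "shedding")
  b$add("M14f", "T2", c("M14f.T2" = 1), p$kon_t2, "binding")
  b$add("M14f.T2", products = c("M14f" = 1, "T2" = 1), k = p$koff_t2,
        tag = "dissociation")
  md <- net@metadata
  md$options$include_shedding <- TRUE
  md$params$k_shed <- k_shed
  methods::new("ReactionNetwork", species = sp,
               reactions = rbind(net@reactions, b$build()), metadata = md)
}
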