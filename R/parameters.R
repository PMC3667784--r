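#' @include AllClasses.R
NULL

#' Default kinetic parameters
#'
#' Rate constants and initial concentrations for the MT1-MMP (M14) /
#' TIMP-2 (T2) / proMMP-2 (M2) network.  Units: bimolecular rate constants
#' 1/(nM s), unimolecular 1/s, concentrations nM.  The values follow the
#' precursor-model lineage of invadopodial MT1-MMP kinetics (tight, fast
#' TIMP-2 binding; slower, weaker proMMP-2 docking through the TIMP-2
#' adaptor; hemopexin-domain dimerization; slow catalytic processing of the
#' proform); every constant can be overridden through this list or a config
#' file.
#'
#' Fields:
#' \describe{
#'   \item{kon_t2, koff_t2}{TIMP-2 binding to a free MT1-MMP catalytic site
#'     (also used for the MT1-MMP / T2.M2 preassembled-complex bond and for
#'     TIMP-2 capture by the shed ectodomain fragment).}
#'   \item{kon_m2, koff_m2}{proMMP-2 docking onto TIMP-2 (membrane-bound or
#'     in solution).}
#'   \item{kon_dim, koff_dim}{hemopexin-domain dimerization of membrane
#'     MT1-MMP units.}
#'   \item{k_act}{irreversible processing of proMMP-2 inside the quaternary
#'     complex M14.M14.T2.M2, releasing active MMP-2.}
#'   \item{kon_t2m2a, koff_t2m2a}{inhibition of active MMP-2 by TIMP-2.}
#'   \item{kon_ecm, koff_ecm, kcat_ecm}{ECM binding and cleavage by the four
#'     active MT1-MMP forms.}
#'   \item{kon_ecm_m2a, koff_ecm_m2a, kcat_ecm_m2a}{ECM binding and cleavage
#'     by active MMP-2.}
#'   \item{k_shed}{ectodomain shedding of membrane MT1-MMP (variant only).}
#'   \item{M14_0, T2_0, M2_0, ECM_0}{initial concentrations.}
#' }
#'
#' @return Named list of numeric values.
#' @examples
#' p <- defaultKineticParameters()
#' p$T2_0 <- 200
#' @export
defaultKineticParameters <- function() {
  list(
    kon_t2       = 2.74e-3, koff_t2      = 2e-4,
    kon_m2       = 1.4e-4,  koff_m2      = 4.7e-3,
    kon_dim      = 2e-3,    koff_dim     = 1e-2,
    k_act        = 2e-3,
    kon_t2m2a    = 5.9e-3,  koff_t2m2a   = 1e-4,
    kon_ecm      = 1e-3,    koff_ecm     = 0.1,  kcat_ecm     = 1,
    kon_ecm_m2a  = 1e-3,    koff_ecm_m2a = 0.1,  kcat_ecm_m2a = 1,
    k_shed       = 1e-4,
    M14_0 = 100, T2_0 = 100, M2_0 = 100, ECM_0 = 1000
  )
}

#' Construct a membrane pool configuration
#'
#' Defaults are the two invadopodial docking pools: X with maximum docking
#' concentration 3 nM and turnover time constant 259 s, D with 7 nM and
#' 26.0 s.  Insertion and internalization rate constants both default to
#' the reciprocal turnover time constant.
#'
#' @param pool_id \code{"X"} or \code{"D"}.
#' @param M_F0 maximum docking-site concentration (nM).
#' @param tau turnover time constant (s); sets \code{k_ins = k_int = 1/tau}
#'   unless given explicitly.
#' @param k_ins,k_int insertion / internalization rate constants (1/s).
#' @return A \linkS4class{PoolConfig}.
#' @examples
#' poolConfig("X")
#' poolConfig("D")
#' @export
poolConfig <- function(pool_id = c("X", "D"), M_F0 = NULL, tau = NULL,
                       k_ins = NULL, k_int = NULL) {
  pool_id <- match.arg(pool_id)
  if (is.null(M_F0)) M_F0 <- if (pool_id == "X") 3 else 7
  if (is.null(tau)) tau <- if (pool_id == "X") 259 else 26.0
  if (is.null(k_ins)) k_ins <- 1 / tau
  if (is.null(k_int)) k_int <- 1 / tau
  methods::new("PoolConfig", pool_id = pool_id, M_F0 = M_F0,
               k_ins = k_ins, k_int = k_int)
}

#' Turnover time constant of a pool
#' @param pool a \linkS4class{PoolConfig}.
#' @return 1/k_ins (s).
#' @export
turnoverTau <- function(pool) 1 / pool@k_ins

.check_params <- function(params, needed) {
  miss <- setdiff(needed, names(params))
  if (length(miss))
    stop("missing rate constant(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- needed[!vapply(params[needed],
                        function(v) is.numeric(v) && is.finite(v) && v >= 0,
                        logical(1))]
  if (length(bad))
    stop("rate constant(s) must be finite and >= 0: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
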