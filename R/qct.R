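# Electron-count and energy bookkeeping of the real-space partitioning.
#
# For an M-basin system the molecular electron count decomposes as
#   N = sum_A N_A,            q_A = Z_A - N_A,
#   lambda(A) = N_A - var_A,  delta(A,B) = -2 cov_AB,
#   N = sum_A lambda(A) + sum_{A<B} delta(A,B)     (sum rule)
# and the energy as
#   E_intra^A   = T^A + Vee^A + VNe^A,
#   E_inter^AB  = Vee^AB + VNN^AB + VNe^AB + VeN^AB,
#   E = sum_A E_intra^A + sum_{A<B} E_inter^AB.
# The residual of the N reconstruction doubles as a per-molecule
# uncertainty score for predicted electron metrics.

#' Conversion constant from atomic units to kcal/mol
#'
#' Applied only at reporting time; all stored energies are in a.u.
#' @export
AU_TO_KCALMOL <- 627.5

#' Atomic charge from an electron population
#'
#' @param Z_A atomic number(s) (>= 1).
#' @param N_A basin electron population(s) (>= 0), electrons.
#' @return q_A = Z_A - N_A, electrons; vectorized.
#' @export
atomic_charge <- function(Z_A, N_A) {
  if (any(Z_A < 1)) stop("atomic numbers must be >= 1")
  if (any(N_A < 0)) stop("electron populations must be >= 0")
  Z_A - N_A
}

#' Localization index from a basin population and its variance
#'
#' @param N_A basin electron population(s), electrons.
#' @param var_A population variance(s) (>= 0).
#' @return lambda = N_A - var_A, electrons.
#' @export
localization_index <- function(N_A, var_A) {
  if (any(var_A < 0)) stop("population variances must be >= 0")
  N_A - var_A
}

#' Delocalization index from an interbasin population covariance
#'
#' @param cov_AB covariance(s) of the two basin populations.
#' @return delta = -2 cov_AB, electrons.
#' @export
delocalization_index <- function(cov_AB) -2 * cov_AB

#' Reconstruct the molecular electron count from lambda and delta
#'
#' `N = sum_A lambda(A) + sum_{A<B} delta(A,B)` (the half double-sum over
#' ordered pairs equals the plain sum over unordered pairs).
#'
#' @param lam length-M vector of localization indices.
#' @param delta length-M(M-1)/2 vector of delocalization indices in
#'   canonical pair order.
#' @return reconstructed N, electrons.
#' @export
reconstruct_N <- function(lam, delta) {
  M <- length(lam)
  if (length(delta) != n_pairs(M)) {
    stop("delta has length ", length(delta), ", expected M(M-1)/2 = ",
         n_pairs(M), " for M = ", M)
  }
  sum(lam) + sum(delta)
}

#' Intra-atomic (self) IQA energy
#'
#' @param T_A atomic kinetic energy, a.u.
#' @param Vee_A intra-atomic electron-electron repulsion, a.u.
#' @param VNe_A intra-atomic electron-nucleus attraction, a.u.
#' @return E_intra = T + Vee + VNe, a.u.; vectorized.
#' @export
iqa_intra <- function(T_A, Vee_A, VNe_A) T_A + Vee_A + VNe_A

#' Interatomic IQA interaction energy
#'
#' The two electron-nucleus terms are distinct: density of A with nucleus
#' of B, and vice versa.
#'
#' @param Vee interbasin electron-electron repulsion, a.u.
#' @param VNN nucleus-nucleus repulsion, a.u.
#' @param VNe density-of-A/nucleus-of-B attraction, a.u.
#' @param VeN nucleus-of-A/density-of-B attraction, a.u.
#' @return E_inter = Vee + VNN + VNe + VeN, a.u.; vectorized.
#' @export
iqa_inter <- function(Vee, VNN, VNe, VeN) Vee + VNN + VNe + VeN

#' Reconstruct the total energy from IQA components
#'
#' @param E_intra length-M vector of self-energies, a.u.
#' @param E_inter length-M(M-1)/2 vector of pair interaction energies in
#'   canonical order, a.u.
#' @return E = sum E_intra + sum E_inter, a.u.
#' @export
reconstruct_E <- function(E_intra, E_inter) {
  M <- length(E_intra)
  if (length(E_inter) != n_pairs(M)) {
    stop("E_inter has length ", length(E_inter), ", expected M(M-1)/2 = ",
         n_pairs(M), " for M = ", M)
  }
  sum(E_intra) + sum(E_inter)
}

#' Sum-rule uncertainty score of a predicted electron-metric record
#'
#' The systems in scope are neutral, so the molecular electron count is
#' known exactly (sum of Z) and the error of its reconstruction from
#' predicted local values is a label-free reliability indicator:
#' * charge route: `|sum(Q_hat)|` (true molecular charge is 0),
#' * lambda/delta route: `|reconstruct_N(lam_hat, delta_hat) - sum(Z)|`.
#' By default the charge route is used when `Q` is present, else the
#' sum-rule route; both are reported when both property sets are present.
#'
#' @param record a `local_record` holding predicted properties (`Q`
#'   and/or `lambda` + `delta`).
#' @param route `"auto"` (default), `"charge"` or `"sumrule"`.
#' @return named numeric vector with elements `charge` and/or `sumrule`
#'   (electrons).
#' @export
uncertainty_from_reconstruction <- function(record, route = c("auto", "charge", "sumrule")) {
  route <- match.arg(route)
  stopifnot(inherits(record, "local_record"))
  Z <- record$molecule$Z
  has_q <- "Q" %in% names(record$props_1p)
  has_ld <- all(c("lambda") %in% names(record$props_1p)) &&
    "delta" %in% names(record$props_2p)
  out <- c()
  if (route %in% c("auto", "charge")) {
    if (has_q) {
      out["charge"] <- abs(sum(record$props_1p$Q))
    } else if (route == "charge") {
      stop("charge route requires a predicted 'Q' property")
    }
  }
  if (route %in% c("auto", "sumrule")) {
    if (has_ld) {
      out["sumrule"] <- abs(reconstruct_N(record$props_1p$lambda,
                                          record$props_2p$delta) - sum(Z))
    } else if (route == "sumrule") {
      stop("sum-rule route requires predicted 'lambda' and 'delta' properties")
    }
  }
  if (length(out) == 0L) {
    stop("record carries neither 'Q' nor 'lambda'+'delta'; cannot score")
  }
  out
}

#' Check the sum rules of a set of labeled records
#'
#' For each record reports the total-charge residual `|sum Q|`, the
#' electron-count reconstruction residual and the total-energy
#' reconstruction residual (each `NA` when the needed properties are
#' absent). The reference total energy is read from the record's
#' `extras$E_total`, which the surrogate generator stores before any
#' label noise is applied.
#'
#' @param records list of `local_record`s.
#' @param tol tolerance for the `ok` flag (default 1e-10).
#' @return data.frame with columns `id`, `sumQ`, `resid_N`, `resid_E`, `ok`.
#' @export
check_sum_rules <- function(records, tol = 1e-10) {
  if (inherits(records, "local_record")) records <- list(records)
  rows <- lapply(records, function(rec) {
    Z <- rec$molecule$Z
    sumQ <- if ("Q" %in% names(rec$props_1p)) abs(sum(rec$props_1p$Q)) else NA_real_
    resid_N <- if ("lambda" %in% names(rec$props_1p) &&
                   "delta" %in% names(rec$props_2p)) {
      abs(reconstruct_N(rec$props_1p$lambda, rec$props_2p$delta) - sum(Z))
    } else NA_real_
    resid_E <- if ("E_intra" %in% names(rec$props_1p) &&
                   "E_inter" %in% names(rec$props_2p) &&
                   !is.null(rec$extras$E_total)) {
      abs(reconstruct_E(rec$props_1p$E_intra, rec$props_2p$E_inter) -
            rec$extras$E_total)
    } else NA_real_
    data.frame(id = rec$molecule$id, sumQ = sumQ, resid_N = resid_N,
               resid_E = resid_E)
  })
  out <- do.call(rbind, rows)
  out$ok <- apply(out[, c("sumQ", "resid_N", "resid_E")], 1,
                  function(v) all(v[!is.na(v)] <= tol))
  out
}
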