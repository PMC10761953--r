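#' @include traj-metrics.R
NULL

#' Nonpolar solvation term from a surface-area change
#'
#' G_SA = gamma * dSASA + beta, the surface-tension model of the nonpolar
#' solvation contribution.
#'
#' @param deltaSasa change in solvent-accessible surface area (Angstrom^2).
#' @param gammaSurface surface tension coefficient, kJ/(mol Angstrom^2).
#' @param betaOffset constant offset, kJ/mol.
#' @return nonpolar solvation energy, kJ/mol
#' @export
nonpolarTerm <- function(deltaSasa, gammaSurface, betaOffset) {
  stopifnot(is.finite(deltaSasa), is.finite(gammaSurface), is.finite(betaOffset))
  gammaSurface * deltaSasa + betaOffset
}

#' Combine MM-PBSA binding-energy components
#'
#' Aggregation identities of the end-point binding free-energy estimate:
#' G_gas = E_ele + E_vdw; G_solv = G_pb + G_sa; G_total = G_gas + G_solv.
#' The entropy term of the full binding free energy may be supplied as an
#' optional scalar (it is never computed here); when given, the returned
#' gBind = gTotal - tDeltaS.
#'
#' All units kJ/mol, as conventionally reported.
#'
#' @param eEle electrostatic energy.
#' @param eVdw van der Waals energy.
#' @param gPb polar solvation term.
#' @param gSa nonpolar solvation term (default 0, so a pre-summed
#'   solvation value can be passed through gPb).
#' @param tDeltaS optional entropy term T*dS; NA to omit.
#' @return list(gGas, gSolv, gTotal[, gBind])
#' @export
combineComponents <- function(eEle, eVdw, gPb, gSa = 0, tDeltaS = NA) {
  stopifnot(is.finite(eEle), is.finite(eVdw), is.finite(gPb), is.finite(gSa))
  gGas <- eEle + eVdw
  gSolv <- gPb + gSa
  out <- list(gGas = gGas, gSolv = gSolv, gTotal = gGas + gSolv)
  if (!is.na(tDeltaS)) out$gBind <- out$gTotal - tDeltaS
  out
}

#' Audit printed MM-PBSA tables for internal consistency
#'
#' Checks the aggregation identities against independently printed
#' subtotals: |(eEle + eVdw) - gGas| and |(gGas + gSolv) - gTotal| must
#' each be within \code{tol}. Published component tables occasionally
#' fail this check; the audit flags the mismatch with its magnitude and
#' never "corrects" the printed values.
#'
#' @param eEle,eVdw printed gas-phase components, kJ/mol.
#' @param gGas printed gas-phase subtotal, kJ/mol.
#' @param gSolv printed solvation subtotal, kJ/mol (NA to skip the total check).
#' @param gTotal printed total, kJ/mol (NA to skip).
#' @param tol mismatch tolerance, kJ/mol (default 0.01).
#' @return list(consistent, gasDiscrepancy, totalDiscrepancy)
#' @export
auditComponents <- function(eEle, eVdw, gGas, gSolv = NA, gTotal = NA,
                            tol = 0.01) {
  gasDiff <- abs((eEle + eVdw) - gGas)
  totDiff <- if (!is.na(gSolv) && !is.na(gTotal)) abs((gGas + gSolv) - gTotal)
             else NA_real_
  list(consistent = gasDiff <= tol && (is.na(totDiff) || totDiff <= tol),
       gasDiscrepancy = gasDiff, totalDiscrepancy = totDiff)
}

#' Summarize a per-snapshot component table
#'
#' Averages snapshot-wise MM-PBSA components (TSV columns e_ele, e_vdw,
#' g_pb, g_sa) with standard errors, then combines the means. A
#' single-row table is returned as-is with zero standard errors.
#'
#' @param tbl data.frame with columns e_ele, e_vdw, g_pb, g_sa, or a path
#'   to a TSV with that header.
#' @return list(mean = combineComponents on column means,
#'   components = data.frame(term, mean, se), n = snapshot count)
#' @export
snapshotSummary <- function(tbl) {
  if (is.character(tbl))
    tbl <- utils::read.table(tbl, header = TRUE, sep = "\t")
  need <- c("e_ele", "e_vdw", "g_pb", "g_sa")
  if (!all(need %in% names(tbl)))
    stop("component table needs columns: ", paste(need, collapse = ", "))
  n <- nrow(tbl)
  if (n < 1) stop("empty component table")
  mu <- colMeans(tbl[need])
  se <- if (n > 1) vapply(tbl[need], stats::sd, numeric(1)) / sqrt(n)
        else stats::setNames(rep(0, 4), need)
  list(mean = combineComponents(mu[["e_ele"]], mu[["e_vdw"]],
                                mu[["g_pb"]], mu[["g_sa"]]),
       components = data.frame(term = need, mean = unname(mu),
                               se = unname(se)),
       n = n)
}
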