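## Semi-empirical pairwise binding free-energy model (AutoDock4 family):
## weighted 12-6 van der Waals, 12-10 hydrogen bond, screened Coulomb
## electrostatics with a sigmoidal distance-dependent dielectric, Gaussian
## pairwise desolvation, and a torsional entropy penalty proportional to
## the number of active rotatable bonds.
##
##   dG = W_vdw * sum(A/r^12 - B/r^6)
##      + W_hbond * sum(C/r^12 - D/r^10)          [donor-acceptor pairs]
##      + W_elec * sum(q_i q_j * 332.06 / (eps(r) r))
##      + W_desolv * sum((S_i V_j + S_j V_i) exp(-r^2 / 2 sigma^2))
##      + W_tor * N_tor
##
## Distances are clamped at 0.01 A and each pair term at +1e5 kcal/mol so
## clashed MD snapshots rescore finite.

ENERGY_CLAMP <- 1e5
R_MIN <- 0.01

#' Read a per-atom-type energy parameter table
#'
#' Plain text, one row per atom type with columns `type`, `r_eq`, `eps`,
#' `vol`, `solpar`, `hbond_class`, `hbond_r_eq`, `hbond_eps`.  Lines
#' beginning with `#` are comments.
#'
#' @param path parameter table file.
#' @return data frame keyed by atom type.
#' @export
read_parameter_table <- function(path) {
  # na.strings empty: "NA" is a real atom-type code (aromatic-ring N)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           na.strings = character(0))
  req <- c("type", "r_eq", "eps", "vol", "solpar", "hbond_class",
           "hbond_r_eq", "hbond_eps")
  if (!all(req %in% names(tab)))
    stopf("parameter table must have columns: %s", paste(req, collapse = ", "))
  if (anyDuplicated(tab$type)) stop("duplicate atom types in parameter table")
  bad <- setdiff(tab$hbond_class, c("none", "donor", "acceptor", "both"))
  if (length(bad)) stopf("unknown hbond_class: %s", paste(bad, collapse = ", "))
  rownames(tab) <- tab$type
  tab
}

#' Default energy-model parameters
#'
#' Bundles the shipped atom-type table with the semi-empirical term
#' weights, the desolvation width, the sigmoidal dielectric constants and
#' the thermodynamic constants used for the dG to Ki conversion.
#'
#' Defaults: `W_vdw = 0.1662`, `W_hbond = 0.1209`, `W_elec = 0.1406`,
#' `W_desolv = 0.1322`, `W_tor = 0.2983`, `sigma = 3.5` A, Coulomb
#' conversion 332.06 kcal A / (mol e^2), dielectric constants
#' `A_eps = -8.5525`, `eps0 = 78.4`, `k_eps = 7.7839`,
#' `lambda_eps = 0.003627`, `R = 1.9872e-3` kcal/(mol K), `T = 298.15` K.
#' All overridable via `...`.
#'
#' @param table_path optional alternative parameter table.
#' @param ... named overrides for any scalar parameter above.
#' @return An object of class `EnergyParameters`.
#' @export
default_energy_parameters <- function(table_path = NULL, ...) {
  if (is.null(table_path))
    table_path <- system.file("extdata", "energy_params_default.tsv",
                              package = "popshift", mustWork = TRUE)
  p <- list(
    type_table = read_parameter_table(table_path),
    W_vdw = 0.1662, W_hbond = 0.1209, W_elec = 0.1406,
    W_desolv = 0.1322, W_tor = 0.2983,
    sigma = 3.5, coulomb = 332.06,
    A_eps = -8.5525, eps0 = 78.4, k_eps = 7.7839, lambda_eps = 0.003627,
    R = 1.9872e-3, T = 298.15
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stopf("unknown parameter(s): %s", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  weights <- c(p$W_vdw, p$W_hbond, p$W_elec, p$W_desolv, p$W_tor)
  if (any(weights < 0)) stop("term weights must be non-negative")
  if (p$sigma <= 0) stop("desolvation width sigma must be positive")
  structure(p, class = "EnergyParameters")
}

#' @export
print.EnergyParameters <- function(x, ...) {
  cat(sprintf(paste0("EnergyParameters: %d atom types; weights vdw %.4f, ",
                     "hbond %.4f, elec %.4f, desolv %.4f, tor %.4f\n"),
              nrow(x$type_table), x$W_vdw, x$W_hbond, x$W_elec,
              x$W_desolv, x$W_tor))
  invisible(x)
}

#' Sigmoidal distance-dependent dielectric
#'
#' `eps(r) = A + (eps0 - A) / (1 + k exp(-lambda (eps0 - A) r))`, a
#' monotone nondecreasing screening function rising from ~1.35 at contact
#' to the bulk-water value 78.4 at long range.
#'
#' @param r distance(s) in Angstrom, `r >= 0`.
#' @param p an `EnergyParameters` object.
#' @return dimensionless permittivity, same length as `r`.
#' @export
dielectric <- function(r, p = default_energy_parameters()) {
  if (any(r < 0)) stop("dielectric is undefined for negative distances")
  B <- p$eps0 - p$A_eps
  p$A_eps + B / (1 + p$k_eps * exp(-p$lambda_eps * B * r))
}

type_index <- function(types, tab) {
  i <- match(types, tab$type)
  if (anyNA(i))
    stopf("atom type(s) not in parameter table: %s",
          paste(unique(types[is.na(i)]), collapse = ", "))
  i
}

# vectorized pair coefficients for type index vectors i, j
pair_coefficients <- function(i, j, tab) {
  req <- (tab$r_eq[i] + tab$r_eq[j]) / 2
  eps <- sqrt(tab$eps[i] * tab$eps[j])
  A <- eps * req^12
  B <- 2 * eps * req^6
  ci <- tab$hbond_class[i]; cj <- tab$hbond_class[j]
  don_i <- ci %in% c("donor", "both"); acc_i <- ci %in% c("acceptor", "both")
  don_j <- cj %in% c("donor", "both"); acc_j <- cj %in% c("acceptor", "both")
  is_hb <- (don_i & acc_j) | (don_j & acc_i)
  # 12-10 parameters come from the acceptor partner (AutoDock convention)
  acc_idx <- ifelse(don_i & acc_j, j, i)
  hreq <- tab$hbond_r_eq[acc_idx]; heps <- tab$hbond_eps[acc_idx]
  C <- ifelse(is_hb, 5 * heps * hreq^12, 0)
  D <- ifelse(is_hb, 6 * heps * hreq^10, 0)
  list(A = A, B = B, C = C, D = D, is_hb = is_hb, eps = eps, req = req,
       Si = tab$solpar[i], Vi = tab$vol[i],
       Sj = tab$solpar[j], Vj = tab$vol[j])
}

#' Pairwise interaction energies between two typed, charged atoms
#'
#' Vectorized over equal-length inputs.  The van der Waals 12-6 term uses
#' `A = eps r_eq^12`, `B = 2 eps r_eq^6` (arithmetic-mean pair `r_eq`,
#' geometric-mean well depth); donor-acceptor pairs additionally receive a
#' 12-10 hydrogen-bond term.  Each term is clamped at +1e5 kcal/mol and
#' distances below 0.01 A are treated as 0.01 A.
#'
#' @param type_i,type_j atom-type codes from the parameter table.
#' @param q_i,q_j partial charges (e).
#' @param r interatomic distance(s), Angstrom, `> 0`.
#' @param p an `EnergyParameters` object.
#' @return data frame with columns `vdw`, `hbond`, `elec`, `desolv`
#'   (kcal/mol).
#' @export
pair_energy <- function(type_i, type_j, q_i, q_j, r,
                        p = default_energy_parameters()) {
  if (any(r <= 0)) stop("pair_energy requires r > 0")
  tab <- p$type_table
  i <- type_index(type_i, tab); j <- type_index(type_j, tab)
  n <- max(length(i), length(j), length(r))
  i <- rep_len(i, n); j <- rep_len(j, n)
  q_i <- rep_len(q_i, n); q_j <- rep_len(q_j, n); r <- rep_len(r, n)
  co <- pair_coefficients(i, j, tab)
  r <- pmax(r, R_MIN)
  r2 <- r * r; r6 <- r2 * r2 * r2; r10 <- r6 * r2 * r2; r12 <- r6 * r6
  clamp <- function(x) pmin(x, ENERGY_CLAMP)
  vdw   <- clamp(p$W_vdw * (co$A / r12 - co$B / r6))
  hbond <- clamp(p$W_hbond * (co$C / r12 - co$D / r10))
  elec  <- clamp(p$W_elec * q_i * q_j * p$coulomb / (dielectric(r, p) * r))
  desolv <- clamp(p$W_desolv * (co$Si * co$Vj + co$Sj * co$Vi) *
                    exp(-r2 / (2 * p$sigma^2)))
  data.frame(vdw = vdw, hbond = hbond, elec = elec, desolv = desolv)
}

#' Construct a score breakdown
#' @param vdw,hbond,elec,desolv,torsional_penalty per-term energies
#'   (kcal/mol).
#' @param warnings character vector of scoring warnings (e.g. clashes).
#' @return A `ScoreBreakdown` whose `total_dg` is the exact sum of terms.
#' @export
new_score_breakdown <- function(vdw, hbond, elec, desolv, torsional_penalty,
                                warnings = character(0)) {
  structure(list(vdw = vdw, hbond = hbond, elec = elec, desolv = desolv,
                 torsional_penalty = torsional_penalty,
                 total_dg = vdw + hbond + elec + desolv + torsional_penalty,
                 warnings = warnings),
            class = "ScoreBreakdown")
}

#' @export
print.ScoreBreakdown <- function(x, ...) {
  cat(sprintf(paste0("dG = %.3f kcal/mol  (vdw %.3f, hbond %.3f, ",
                     "elec %.3f, desolv %.3f, torsional %.3f)\n"),
              x$total_dg, x$vdw, x$hbond, x$elec, x$desolv,
              x$torsional_penalty))
  if (length(x$warnings)) cat(" warnings:", length(x$warnings), "\n")
  invisible(x)
}

select_role_atoms <- function(s, roles) {
  which(s$atoms$role %in% roles)
}

#' Score a ligand pose against a rigid receptor
#'
#' Sums [pair_energy()] over every receptor-ligand atom pair (no distance
#' cutoff) and adds the torsional penalty `W_tor * n_tor`.  Waters are
#' always excluded; ions are excluded by default (both carried via role
#' labels).  Atom pairs closer than 0.01 A are scored with clamped
#' energies and flagged in the `warnings` element.
#'
#' @param receptor `Structure` providing the fixed environment.
#' @param ligand `Structure` whose atoms carry role `"ligand"`.
#' @param tree optional `TorsionTree`; its `n_tor` sets the torsional
#'   penalty (0 when `NULL`).
#' @param p an `EnergyParameters` object.
#' @param include_ions include receptor-side ions in the sum?
#' @return A `ScoreBreakdown`.
#' @export
score_pose <- function(receptor, ligand, tree = NULL,
                       p = default_energy_parameters(),
                       include_ions = FALSE) {
  stopifnot(inherits(receptor, "Structure"), inherits(ligand, "Structure"))
  rec_roles <- c("receptor", if (include_ions) "ion")
  ri <- select_role_atoms(receptor, rec_roles)
  li <- select_role_atoms(ligand, "ligand")
  if (!length(ri)) stop("no receptor-role atoms to score against")
  if (!length(li))
    stop("no ligand-role atoms found; check the structure's role labels")
  ra <- receptor$atoms[ri, ]; la <- ligand$atoms[li, ]
  if (anyNA(ra$atom_type) || anyNA(la$atom_type))
    stop("all scored atoms must carry an atom_type")
  rxyz <- as.matrix(ra[, c("x", "y", "z")])
  lxyz <- as.matrix(la[, c("x", "y", "z")])
  nr <- nrow(rxyz); nl <- nrow(lxyz)
  d2 <- outer(rowSums(rxyz^2), rowSums(lxyz^2), `+`) -
    2 * rxyz %*% t(lxyz)
  r <- sqrt(pmax(d2, 0))
  ii <- rep(seq_len(nr), times = nl)
  jj <- rep(seq_len(nl), each = nr)
  terms <- pair_energy(ra$atom_type[ii], la$atom_type[jj],
                       ra$charge[ii], la$charge[jj],
                       pmax(as.vector(r), R_MIN), p)
  n_clash <- sum(r < R_MIN)
  warnings <- if (n_clash)
    sprintf("%d atom pair(s) closer than %.2f A scored with clamped energies",
            n_clash, R_MIN) else character(0)
  n_tor <- if (is.null(tree)) 0L else tree$n_tor
  new_score_breakdown(sum(terms$vdw), sum(terms$hbond), sum(terms$elec),
                      sum(terms$desolv), p$W_tor * n_tor, warnings)
}

#' Convert a binding free energy to an inhibition constant
#'
#' `Ki = exp(dG / (R T))` with `R = 1.9872e-3` kcal/(mol K); the default
#' temperature is 298.15 K.  Strictly monotone increasing in `dG`.
#'
#' @param dg binding free energy, kcal/mol.
#' @param T temperature, K (`> 0`).
#' @param R gas constant, kcal/(mol K).
#' @return inhibition constant in molar units.
#' @export
delta_g_to_ki <- function(dg, T = 298.15, R = 1.9872e-3) {
  if (T <= 0) stop("temperature must be positive")
  exp(dg / (R * T))
}

#' Inverse of [delta_g_to_ki()]
#' @param ki inhibition constant, molar.
#' @param T temperature, K.
#' @param R gas constant, kcal/(mol K).
#' @return binding free energy, kcal/mol.
#' @export
ki_to_delta_g <- function(ki, T = 298.15, R = 1.9872e-3) {
  if (T <= 0) stop("temperature must be positive")
  R * T * log(ki)
}
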