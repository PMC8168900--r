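# Species naming shared across the package (profiles, states, CSV headers).
.cell_species <- c("C", "M1", "M2", "D", "T1", "T8", "Tr")
.mol_species  <- c("I2", "I10", "I12", "P", "Tb", "PD", "PL", "A1", "Ab")
.all_species  <- c(.cell_species, .mol_species)

#' Species names of the model
#'
#' @return Character vectors: `cell_species()` the seven advected cell
#'   densities, `molecular_species()` the nine diffusing concentrations.
#' @export
cell_species <- function() .cell_species

#' @rdname cell_species
#' @export
molecular_species <- function() .mol_species

.check_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0))
    stop(what, " must be finite and nonnegative", call. = FALSE)
  invisible(x)
}

#' Michaelis-Menten activation fraction
#'
#' `x / (K + x)`: the saturating fraction used wherever a cytokine activates a
#' cell through receptor binding with limited receptor recycling.
#'
#' @param x concentration(s), >= 0 (g/cm^3).
#' @param K half-saturation constant, > 0 (g/cm^3).
#' @return Dimensionless fraction in `[0, 1)`, nondecreasing in `x`.
#' @examples
#' mm_act(0, 1)    # 0
#' mm_act(1, 1)    # 0.5
#' @export
mm_act <- function(x, K) {
  .check_nonneg(x, "x")
  if (any(!is.finite(K)) || any(K <= 0)) stop("K must be positive", call. = FALSE)
  x / (K + x)
}

#' Inhibition fraction
#'
#' `1 / (1 + x/K)`: the factor by which a species at concentration `x`
#' inhibits a process. Complementary to [mm_act()]: `inhibit(x, K) ==
#' 1 - mm_act(x, K)`.
#'
#' @inheritParams mm_act
#' @return Dimensionless fraction in `(0, 1]`, nonincreasing in `x`.
#' @export
inhibit <- function(x, K) {
  .check_nonneg(x, "x")
  if (any(!is.finite(K)) || any(K <= 0)) stop("K must be positive", call. = FALSE)
  1 / (1 + x / K)
}

#' CD8-mediated cancer killing rate
#'
#' `mu_T8C * T8 * C / (1 + zeta_Tb * Tb)`: mass-action killing of cancer cells
#' by CD8+ T cells, inhibited by TGF-beta through the cancer-specific factor
#' `1/(1 + zeta_Tb * Tb)`.
#'
#' @param C,T8,Tb densities of cancer cells, CD8+ T cells and TGF-beta (g/cm^3).
#' @param mu_T8C killing rate constant (cm^3/(g*d)).
#' @param zeta_Tb TGF-beta inhibition strength (cm^3/g), cancer-specific.
#' @return Killing rate (g/(cm^3*d)).
#' @export
killing_term <- function(C, T8, Tb, mu_T8C, zeta_Tb) {
  .check_nonneg(c(C, T8, Tb, mu_T8C, zeta_Tb), "killing_term inputs")
  mu_T8C * T8 * C / (1 + zeta_Tb * Tb)
}

#' PD-1/PD-L1 complex concentration
#'
#' `Q = sigma * PD * PL`. The complex is derived, never independently stored.
#'
#' @param PD,PL PD-1 and PD-L1 concentrations (g/cm^3).
#' @param sigma complex formation scale (cm^3/g).
#' @return Complex concentration (g/cm^3), bilinear in `PD` and `PL`.
#' @export
complex_Q <- function(PD, PL, sigma) {
  .check_nonneg(c(PD, PL, sigma), "complex_Q inputs")
  sigma * PD * PL
}

#' Drug source rates at a given time
#'
#' The effective antibody sources are constant on the dosing window
#' `[t0, t1]` and zero outside it; the arm flag zeroes the inactive drug.
#'
#' @param t time (days).
#' @param schedule a [treatment_schedule()].
#' @return Named numeric vector `c(A1 = ..., Ab = ...)` (g/(cm^3*d)).
#' @export
dose_rate <- function(t, schedule) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  on <- as.numeric(t >= schedule$t0 & t <= schedule$t1)
  c(A1 = schedule$gamma_A1 * on, Ab = schedule$gamma_Ab * on)
}

#' Cell reaction terms
#'
#' Pointwise (space-free) right-hand sides for the seven cell species:
#' logistic growth minus TGF-beta-inhibited CD8 killing minus death for
#' cancer; CCL2-driven activation and IL-12 / TGF-beta phenotype switching
#' for the two macrophage phenotypes; tumor-signal activation for dendritic
#' cells; TGF-beta-augmented, IL-10/Treg/Q-inhibited IL-12 activation plus
#' IL-2 proliferation for Th1 and CD8, with the Q-induced Th1 -> Treg
#' conversion `lambda_T1Tr * T1 * Q/(K_Q + Q)` moved from Th1 to Treg
#' (mass-conserving); TGF-beta-driven Treg differentiation and IL-2
#' proliferation for Tregs. All inputs may be vectors over mesh nodes.
#'
#' @param cells named list/vector with elements `C, M1, M2, D, T1, T8, Tr`.
#' @param mols named list/vector with elements
#'   `I2, I10, I12, P, Tb, PD, PL, A1, Ab`.
#' @param p a `kinetic_params` object.
#' @return Named list of reaction rates (g/(cm^3*d)), one per cell species.
#' @export
cell_rhs <- function(cells, mols, p) {
  cells <- as.list(cells); mols <- as.list(mols)
  for (s in .cell_species) .check_nonneg(cells[[s]], s)
  for (s in .mol_species) .check_nonneg(mols[[s]], s)
  with(c(cells, mols, unclass(p)), {
    Q <- complex_Q(PD, PL, sigma)
    conv <- lambda_T1Tr * T1 * mm_act(Q, K_Q)
    act_T1 <- lambda_T1I12 * T10 * (1 + mm_act(Tb, K_Tb)) * mm_act(I12, K_I12) *
      inhibit(I10, Khat_TI10) * inhibit(Tr, Khat_TTr)
    act_T8 <- lambda_T8I12 * T80 * (1 + mm_act(Tb, K_Tb)) * mm_act(I12, K_I12) *
      inhibit(I10, Khat_TI10) * inhibit(Tr, Khat_TTr)
    list(
      C = lambda_C * C * (1 - C / C_M) -
        killing_term(C, T8, Tb, mu_T8C, zeta_Tb) - mu_C * C,
      M1 = lambda_M1 * M0 * mm_act(P, K_P) + lambda_M2M1 * M2 * mm_act(I12, K_I12) -
        lambda_M1M2 * M1 * mm_act(Tb, K_Tb) - mu_M1 * M1,
      M2 = lambda_M2 * M0 * mm_act(P, K_P) - lambda_M2M1 * M2 * mm_act(I12, K_I12) +
        lambda_M1M2 * M1 * mm_act(Tb, K_Tb) - mu_M2 * M2,
      D = lambda_D * D0 * mm_act(C, K_C) - mu_D * D,
      T1 = (act_T1 + lambda_T1I2 * T1 * mm_act(I2, K_I2)) * inhibit(Q, Khat_TQ) -
        conv - mu_T1 * T1,
      T8 = (act_T8 + lambda_T8I2 * T8 * mm_act(I2, K_I2)) * inhibit(Q, Khat_TQ) -
        mu_T8 * T8,
      Tr = lambda_TrTb * T10 * mm_act(Tb, K_Tb) + conv +
        lambda_TrI2 * Tr * mm_act(I2, K_I2) - mu_Tr * Tr
    )
  })
}

#' Molecular reaction terms
#'
#' Pointwise right-hand sides for the nine molecular species:
#' production by their cellular sources minus first-order degradation, with
#' bilinear blocking terms coupling each antibody to its target. The
#' anti-PD-1 blocking term `-mu_PDA1 * PD * A1` appears in both the PD-1 and
#' the antibody equation (mirrored depletion); TGF-beta is depleted at rate
#' `mu_AbTb * Tb * Ab` while the antibody is consumed at `mu_TbAb * Tb * Ab`.
#'
#' @inheritParams cell_rhs
#' @param dose length-2 numeric `c(A1, Ab)` source rates (g/(cm^3*d)),
#'   usually from [dose_rate()].
#' @return Named list of reaction rates (g/(cm^3*d)), one per molecular species.
#' @export
molecular_rhs <- function(cells, mols, p, dose = c(A1 = 0, Ab = 0)) {
  cells <- as.list(cells); mols <- as.list(mols)
  for (s in .cell_species) .check_nonneg(cells[[s]], s)
  for (s in .mol_species) .check_nonneg(mols[[s]], s)
  with(c(cells, mols, unclass(p)), {
    Tsum <- T1 + T8 + Tr
    list(
      I2  = lambda_I2T1 * T1 - mu_I2 * I2,
      I10 = lambda_I10M2 * M2 + lambda_I10C * C - mu_I10 * I10,
      I12 = lambda_I12D * D - mu_I12 * I12,
      P   = lambda_PC * C - mu_P * P,
      Tb  = lambda_TbC * C + lambda_TbM2 * M2 + lambda_TbTr * Tr -
        mu_Tb * Tb - mu_AbTb * Tb * Ab,
      PD  = lambda_PD * Tsum - mu_PD * PD - mu_PDA1 * PD * A1,
      PL  = lambda_PL1 * (Tsum + M1 + M2) + lambda_PLC * C - mu_PL * PL,
      A1  = dose[[1]] - mu_PDA1 * PD * A1 - mu_A1 * A1,
      Ab  = dose[[2]] - mu_TbAb * Tb * Ab - mu_Ab * Ab
    )
  })
}
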