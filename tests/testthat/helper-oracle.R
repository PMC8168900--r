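# Independent brute-force evaluator of the printed reaction equations, written
# term by term (deliberately separate from the package implementation) and used
# as the oracle for the kinetics and solver modules.

hill_up <- function(x, K) x / (K + x)
hill_down <- function(x, K) K / (K + x)   # algebraically 1/(1 + x/K)

oracle_rhs <- function(y, p, doseA1 = 0, doseAb = 0) {
  g <- function(nm) y[[nm]]
  Q <- p$sigma * g("PD") * g("PL")
  terms <- list()
  # cancer: logistic growth - CD8 killing (TGF-beta inhibited) - death
  terms$C <- sum(
    p$lambda_C * g("C") * (1 - g("C") / p$C_M),
    -(p$mu_T8C * g("T8") * g("C")) * (1 / (1 + p$zeta_Tb * g("Tb"))),
    -p$mu_C * g("C"))
  # M1: CCL2 activation + M2->M1 (IL-12) - M1->M2 (TGF-beta) - death
  terms$M1 <- sum(
    p$lambda_M1 * p$M0 * hill_up(g("P"), p$K_P),
    p$lambda_M2M1 * g("M2") * hill_up(g("I12"), p$K_I12),
    -p$lambda_M1M2 * g("M1") * hill_up(g("Tb"), p$K_Tb),
    -p$mu_M1 * g("M1"))
  # M2: mirror image of the transition terms
  terms$M2 <- sum(
    p$lambda_M2 * p$M0 * hill_up(g("P"), p$K_P),
    -p$lambda_M2M1 * g("M2") * hill_up(g("I12"), p$K_I12),
    p$lambda_M1M2 * g("M1") * hill_up(g("Tb"), p$K_Tb),
    -p$mu_M2 * g("M2"))
  terms$D <- p$lambda_D * p$D0 * hill_up(g("C"), p$K_C) - p$mu_D * g("D")
  aug <- 1 + hill_up(g("Tb"), p$K_Tb)
  block <- hill_up(g("I12"), p$K_I12) *
    hill_down(g("I10"), p$Khat_TI10) * hill_down(g("Tr"), p$Khat_TTr)
  conversion <- p$lambda_T1Tr * g("T1") * hill_up(Q, p$K_Q)
  terms$T1 <- sum(
    (p$lambda_T1I12 * p$T10 * aug * block +
       p$lambda_T1I2 * g("T1") * hill_up(g("I2"), p$K_I2)) * hill_down(Q, p$Khat_TQ),
    -conversion, -p$mu_T1 * g("T1"))
  terms$T8 <- sum(
    (p$lambda_T8I12 * p$T80 * aug * block +
       p$lambda_T8I2 * g("T8") * hill_up(g("I2"), p$K_I2)) * hill_down(Q, p$Khat_TQ),
    -p$mu_T8 * g("T8"))
  terms$Tr <- sum(
    p$lambda_TrTb * p$T10 * hill_up(g("Tb"), p$K_Tb),
    conversion,
    p$lambda_TrI2 * g("Tr") * hill_up(g("I2"), p$K_I2),
    -p$mu_Tr * g("Tr"))
  terms$I2  <- p$lambda_I2T1 * g("T1") - p$mu_I2 * g("I2")
  terms$I10 <- p$lambda_I10M2 * g("M2") + p$lambda_I10C * g("C") - p$mu_I10 * g("I10")
  terms$I12 <- p$lambda_I12D * g("D") - p$mu_I12 * g("I12")
  terms$P   <- p$lambda_PC * g("C") - p$mu_P * g("P")
  terms$Tb  <- sum(p$lambda_TbC * g("C"), p$lambda_TbM2 * g("M2"),
                   p$lambda_TbTr * g("Tr"),
                   -p$mu_Tb * g("Tb"), -p$mu_AbTb * g("Tb") * g("Ab"))
  terms$PD  <- sum(p$lambda_PD * (g("T1") + g("T8") + g("Tr")),
                   -p$mu_PD * g("PD"), -p$mu_PDA1 * g("PD") * g("A1"))
  terms$PL  <- sum(p$lambda_PL1 * (g("T1") + g("T8") + g("Tr") + g("M1") + g("M2")),
                   p$lambda_PLC * g("C"), -p$mu_PL * g("PL"))
  terms$A1  <- doseA1 - p$mu_PDA1 * g("PD") * g("A1") - p$mu_A1 * g("A1")
  terms$Ab  <- doseAb - p$mu_TbAb * g("Tb") * g("Ab") - p$mu_Ab * g("Ab")
  unlist(terms)
}

# random admissible pointwise states, seeded
random_states <- function(n, seed = 7) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    y <- c(
      C = runif(1, 0, 0.5), M1 = runif(1, 0, 0.1), M2 = runif(1, 0, 0.1),
      D = runif(1, 0, 0.02), T1 = runif(1, 0, 0.02), T8 = runif(1, 0, 0.02),
      Tr = runif(1, 0, 0.02),
      I2 = 10^runif(1, -12, -9), I10 = 10^runif(1, -12, -9),
      I12 = 10^runif(1, -11, -9), P = 10^runif(1, -11, -9),
      Tb = 10^runif(1, -8, -5), PD = 10^runif(1, -12, -9),
      PL = 10^runif(1, -11, -9), A1 = 10^runif(1, -10, -7),
      Ab = 10^runif(1, -8, -5))
    as.list(y)
  })
}

pkg_rhs <- function(y, p, doseA1 = 0, doseAb = 0) {
  cells <- y[cell_species()]
  mols <- y[molecular_species()]
  c(unlist(cell_rhs(cells, mols, p)),
    unlist(molecular_rhs(cells, mols, p, c(doseA1, doseAb))))
}

# coarse but accurate-enough solver settings used throughout the tests
test_cfg <- function(N = 33, dt = 2e-3) solver_config(N = N, dt = dt)

final_volume <- function(traj) traj$volume_cm3[nrow(traj)]
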