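#' @useDynLib tumorpde, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Single source of truth for parameter symbols, units, defaults and provenance.
# "printed" marks values fixed by the published description of the model;
# everything else is a documented placeholder calibrated against the published
# qualitative behaviour (see the methods vignette).
.param_registry <- function() {
  E <- function(default, unit, desc, printed = FALSE)
    list(default = default, unit = unit, desc = desc, printed = printed)
  list(
    # environment -----------------------------------------------------------
    theta   = E(0.5,   "g/cm^3", "constant combined density of all cells in the tumor"),
    C_M     = E(1.2,   "g/cm^3", "cancer-cell logistic carrying capacity"),
    M0      = E(0.1,   "g/cm^3", "naive monocyte/macrophage pool (constant)"),
    D0      = E(0.01,  "g/cm^3", "naive dendritic-cell pool (constant)"),
    T10     = E(6e-3,  "g/cm^3", "naive CD4+ T-cell pool (constant)"),
    T80     = E(2e-3,  "g/cm^3", "inactive CD8+ T-cell pool (constant)"),
    # cancer growth and killing --------------------------------------------
    lambda_C  = E(0.35, "1/d",          "cancer-cell logistic growth rate"),
    mu_C      = E(0.17, "1/d",          "cancer-cell death rate"),
    mu_T8C    = E(17,   "cm^3/(g*d)",   "killing rate of cancer cells by CD8+ T cells"),
    zeta_Tb   = E(4e5,  "cm^3/g",       "TGF-beta inhibition of CD8 killing (cancer-specific)"),
    # transitions and activation -------------------------------------------
    lambda_T1Tr = E(6,     "1/d", "Q-induced Th1 -> Treg conversion scale (cancer-specific)"),
    lambda_M2M1 = E(5e-2,  "1/d", "M2 -> M1 phenotype switch induced by IL-12"),
    lambda_M1M2 = E(5e-2,  "1/d", "M1 -> M2 phenotype switch induced by TGF-beta"),
    lambda_M1   = E(8e-3,  "1/d", "M1 activation from naive pool by CCL2"),
    lambda_M2   = E(2.4e-2,"1/d", "M2/MDSC activation from naive pool by CCL2"),
    lambda_D    = E(8e-2,  "1/d", "dendritic-cell activation by tumor signal"),
    lambda_T1I12 = E(2.2, "1/d", "Th1 activation from naive pool by IL-12"),
    lambda_T8I12 = E(1.2, "1/d", "CD8 activation from inactive pool by IL-12"),
    lambda_TrTb  = E(0.15,"1/d", "TGF-beta-driven Treg differentiation from naive CD4 pool"),
    lambda_T1I2  = E(0.05,"1/d", "IL-2-induced Th1 proliferation"),
    lambda_T8I2  = E(0.1, "1/d", "IL-2-induced CD8 proliferation"),
    lambda_TrI2  = E(0.02,"1/d", "IL-2-induced Treg proliferation"),
    # cell death ------------------------------------------------------------
    mu_M1 = E(0.02,  "1/d", "M1 macrophage death rate"),
    mu_M2 = E(0.02,  "1/d", "M2/MDSC death rate"),
    mu_D  = E(0.1,   "1/d", "dendritic-cell death rate"),
    mu_T1 = E(0.197, "1/d", "Th1 death rate"),
    mu_T8 = E(0.18,  "1/d", "CD8 death rate"),
    mu_Tr = E(0.2,   "1/d", "Treg death rate"),
    # cytokine / receptor production ----------------------------------------
    lambda_I2T1  = E(1.6e-8,  "1/d", "IL-2 production by Th1 cells"),
    lambda_I10M2 = E(2e-9,    "1/d", "IL-10 production by M2/MDSC"),
    lambda_I10C  = E(1e-10,   "1/d", "IL-10 production by cancer cells"),
    lambda_I12D  = E(3.45e-8, "1/d", "IL-12 production by dendritic cells"),
    lambda_PC    = E(2.16e-9, "1/d", "CCL2 production by cancer cells"),
    lambda_TbC   = E(1.5e-3,  "1/d", "TGF-beta production by cancer cells"),
    lambda_TbM2  = E(6e-3,    "1/d", "TGF-beta production by M2/MDSC"),
    lambda_TbTr  = E(0.5,     "1/d", "TGF-beta production by Tregs"),
    lambda_PD    = E(6.25e-9, "1/d", "PD-1 expression by T cells (T1, T8, Tr)"),
    lambda_PL1   = E(5e-9,    "1/d", "PD-L1 expression by T cells and macrophages"),
    lambda_PLC   = E(5e-10,   "1/d", "PD-L1 expression by cancer cells"),
    # molecular degradation --------------------------------------------------
    mu_I2  = E(2.376, "1/d", "IL-2 degradation rate"),
    mu_I10 = E(8,     "1/d", "IL-10 degradation rate"),
    mu_I12 = E(1.38,  "1/d", "IL-12 degradation rate"),
    mu_P   = E(1.73,  "1/d", "CCL2 degradation rate"),
    mu_Tb  = E(499,   "1/d", "TGF-beta degradation rate"),
    mu_PD  = E(1,     "1/d", "PD-1 turnover rate"),
    mu_PL  = E(1,     "1/d", "PD-L1 turnover rate"),
    mu_A1  = E(0.2,   "1/d", "anti-PD-1 antibody degradation rate"),
    mu_Ab  = E(0.2,   "1/d", "anti-TGF-beta antibody degradation rate"),
    # saturation / inhibition constants --------------------------------------
    K_P    = E(5e-10, "g/cm^3", "CCL2 half-saturation for macrophage activation"),
    K_I12  = E(1e-10, "g/cm^3", "IL-12 half-saturation for activation"),
    K_Tb   = E(2e-6,  "g/cm^3", "TGF-beta half-saturation"),
    K_I2   = E(4e-11, "g/cm^3", "IL-2 half-saturation for proliferation"),
    K_Q    = E(1.5e-8,"g/cm^3", "PD-1/PD-L1 complex half-saturation for Th1->Treg conversion"),
    K_C    = E(0.4,   "g/cm^3", "tumor-signal half-saturation for DC activation"),
    Khat_TI10 = E(2e-11, "g/cm^3", "IL-10 inhibition constant on T-cell activation"),
    Khat_TTr  = E(2e-3,  "g/cm^3", "Treg inhibition constant on T-cell activation"),
    Khat_TQ   = E(1e-10, "g/cm^3", "PD-1/PD-L1 complex inhibition constant on T cells"),
    # complex and drug blocking ---------------------------------------------
    sigma   = E(1e10, "cm^3/g",     "PD-1/PD-L1 complex formation scale, Q = sigma*PD*PL"),
    mu_PDA1 = E(1e8,  "cm^3/(g*d)", "PD-1 blocking rate by anti-PD-1 (mirrored depletion)"),
    mu_AbTb = E(2e9,  "cm^3/(g*d)", "TGF-beta depletion rate by anti-TGF-beta"),
    mu_TbAb = E(8e5,  "cm^3/(g*d)", "anti-TGF-beta consumption rate while blocking"),
    # transport ---------------------------------------------------------------
    delta_C  = E(8.64e-7, "cm^2/d", "cancer-cell diffusivity"),
    delta_M  = E(8.64e-7, "cm^2/d", "macrophage diffusivity"),
    delta_T  = E(8.64e-7, "cm^2/d", "T-cell diffusivity"),
    delta_D  = E(8.64e-7, "cm^2/d", "dendritic-cell diffusivity"),
    delta_I2  = E(8.64e-2, "cm^2/d", "IL-2 diffusivity"),
    delta_I10 = E(8.64e-2, "cm^2/d", "IL-10 diffusivity"),
    delta_I12 = E(8.64e-2, "cm^2/d", "IL-12 diffusivity"),
    delta_P   = E(8.64e-2, "cm^2/d", "CCL2 diffusivity"),
    delta_Tb  = E(8.64e-2, "cm^2/d", "TGF-beta diffusivity"),
    delta_PD  = E(8.64e-7, "cm^2/d", "PD-1 diffusivity (membrane-bound, cell-like)"),
    delta_PL  = E(8.64e-7, "cm^2/d", "PD-L1 diffusivity (membrane-bound, cell-like)"),
    delta_A1  = E(3.6e-2,  "cm^2/d", "anti-PD-1 antibody diffusivity"),
    delta_Ab  = E(3.6e-2,  "cm^2/d", "anti-TGF-beta antibody diffusivity"),
    chi_P     = E(10,      "cm^5/(g*d)", "chemotactic coefficient toward CCL2 (M1, M2, Tr)")
  )
}

.param_names <- function() names(.param_registry())

#' Default kinetic parameters
#'
#' Returns the full set of rate, saturation, transport and environment
#' constants of the model as a named list of class `kinetic_params`. Values
#' printed in the source model description (dose rates, cancer-specific
#' presets) are used as printed; the remaining constants are documented
#' placeholders calibrated so that the default model reproduces the published
#' qualitative behaviour (see the methods vignette). Units: days, g/cm^3, cm.
#'
#' @param ... named overrides of individual parameters, e.g.
#'   `default_params(zeta_Tb = 4e6, lambda_T1Tr = 1e3)`.
#' @return A validated `kinetic_params` object (named list).
#' @examples
#' p <- default_params()
#' p$theta
#' @export
default_params <- function(...) {
  reg <- .param_registry()
  p <- lapply(reg, `[[`, "default")
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    p[names(over)] <- over
  }
  validate_params(structure(p, class = "kinetic_params"))
}

#' Validate kinetic parameters
#'
#' Checks nonnegativity of all rates, strict positivity of the total cell
#' density, carrying capacity and every saturation constant, and that no
#' symbol is missing or unknown. Each failure names the offending symbol.
#'
#' @param p a `kinetic_params` object or named list covering all symbols.
#' @return `p`, unchanged, invisibly classed as `kinetic_params`.
#' @export
validate_params <- function(p) {
  nm <- .param_names()
  missing <- setdiff(nm, names(p))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(p), nm)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  for (k in nm) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("parameter ", k, " must be a finite numeric scalar", call. = FALSE)
    if (v < 0) stop("parameter ", k, " must be nonnegative (got ", v, ")", call. = FALSE)
  }
  strict <- c("theta", "C_M", grep("^K_|^Khat_", nm, value = TRUE))
  for (k in strict) if (p[[k]] <= 0)
    stop("parameter ", k, " must be strictly positive (got ", p[[k]], ")", call. = FALSE)
  structure(p[nm], class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  reg <- .param_registry()
  cat("Kinetic parameters (", length(x), " symbols)\n", sep = "")
  df <- data.frame(
    value = vapply(names(x), function(k) format(x[[k]], digits = 4), ""),
    unit = vapply(names(x), function(k) reg[[k]]$unit, ""),
    row.names = names(x)
  )
  print(df, right = FALSE)
  invisible(x)
}

#' Treatment schedule
#'
#' Constant-rate dosing of the two antibodies on a window `[t0, t1]`. The arm
#' flag masks the corresponding source: the control arm receives neither drug,
#' monotherapy arms receive one.
#'
#' @param arm one of `"control"`, `"antiPD1"`, `"antiTGFb"`, `"combination"`.
#' @param t0,t1 start and end of the dosing window (days), `0 <= t0 <= t1`.
#' @param gamma_A1 anti-PD-1 source rate (g/(cm^3*d)); default as printed.
#' @param gamma_Ab anti-TGF-beta source rate (g/(cm^3*d)); default as printed.
#' @return A `treatment_schedule` object.
#' @examples
#' treatment_schedule("combination", t0 = 6, t1 = 45)
#' @export
treatment_schedule <- function(arm = c("control", "antiPD1", "antiTGFb", "combination"),
                               t0 = 0, t1 = 45,
                               gamma_A1 = 1e-8, gamma_Ab = 2e-6) {
  arm <- match.arg(arm)
  if (!is.numeric(t0) || !is.numeric(t1) || t0 < 0 || t1 < t0)
    stop("need 0 <= t0 <= t1", call. = FALSE)
  if (gamma_A1 < 0 || gamma_Ab < 0) stop("dose rates must be nonnegative", call. = FALSE)
  structure(list(arm = arm, t0 = t0, t1 = t1,
                 gamma_A1 = if (arm %in% c("antiPD1", "combination")) gamma_A1 else 0,
                 gamma_Ab = if (arm %in% c("antiTGFb", "combination")) gamma_Ab else 0),
            class = "treatment_schedule")
}

#' Cancer-scenario presets
#'
#' The five cancer scenarios studied with the model. Each preset fixes the two
#' cancer-specific parameters (`lambda_T1Tr`, `zeta_Tb`), the treatment start
#' day and the simulation horizon. Only the gastric pair is printed explicitly
#' in the source; the others follow its stated relations between scenarios.
#'
#' @param cancer preset name, or `NULL` to get the table of all presets.
#' @return A `scenario_preset` (list) or, with `cancer = NULL`, a data.frame.
#' @examples
#' scenario_preset("gastric")
#' scenario_preset()
#' @export
scenario_preset <- function(cancer = NULL) {
  tab <- data.frame(
    cancer   = c("colon", "melanoma", "breast", "bladder", "gastric"),
    lambda_T1Tr = c(6, 6, 6, 6, 1e3),
    zeta_Tb  = c(4e5, 4e6, 4e6, 4e6, 4e6),
    t0       = c(6, 14, 14, 14, 15),
    horizon  = c(45, 45, 56, 32, 45),
    stringsAsFactors = FALSE
  )
  if (is.null(cancer)) return(tab)
  i <- match(cancer, tab$cancer)
  if (is.na(i)) stop("unknown preset: ", cancer, "; available: ",
                     paste(tab$cancer, collapse = ", "), call. = FALSE)
  pr <- as.list(tab[i, ])
  if (pr$horizon <= pr$t0) stop("preset horizon must exceed t0", call. = FALSE)
  structure(pr, class = "scenario_preset")
}

#' Write parameters to a YAML file
#'
#' Keys are exactly the model symbol names; each line carries the unit and
#' description as a comment, and placeholder values are flagged.
#'
#' @param p a `kinetic_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  p <- validate_params(p)
  reg <- .param_registry()
  lines <- c("# Model kinetic parameters. Units: days, g/cm^3, cm.",
             "# Values not printed in the main model description are flagged PLACEHOLDER.")
  fmt <- function(v) {
    s <- sprintf("%.15g", v)
    # YAML floats need a decimal point in the mantissa ("1.0e+10", not "1e+10")
    if (grepl("[eE]", s) && !grepl("\\.", s)) s <- sub("([eE])", ".0\\1", s)
    # bare integers beyond 32-bit range overflow the YAML integer type
    if (!grepl("[.eE]", s) && abs(v) > .Machine$integer.max) s <- paste0(s, ".0")
    s
  }
  for (k in names(p)) {
    flag <- if (isTRUE(reg[[k]]$printed)) "" else "  # PLACEHOLDER"
    lines <- c(lines, sprintf("%s: %s  # [%s] %s%s",
                              k, fmt(p[[k]]), reg[[k]]$unit, reg[[k]]$desc, flag))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load parameters from a YAML file
#'
#' @param path parameter file (flat key -> value mapping, symbols as keys).
#' @param warn_placeholders if `TRUE`, emit one warning listing the symbols
#'   whose values equal the shipped placeholder defaults.
#' @return A validated `kinetic_params` object.
#' @export
load_params <- function(path, warn_placeholders = FALSE) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .param_names())
  if (length(unknown))
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  p <- lapply(.param_registry(), `[[`, "default")
  p[names(raw)] <- lapply(raw, as.numeric)
  p <- validate_params(structure(p, class = "kinetic_params"))
  if (warn_placeholders) {
    reg <- .param_registry()
    ph <- names(p)[!vapply(reg, `[[`, TRUE, "printed")]
    warning("placeholder-calibrated parameters in use: ",
            paste(ph, collapse = ", "), call. = FALSE)
  }
  p
}
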