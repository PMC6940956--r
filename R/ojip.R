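#' Extract JIP-test landmarks from a fluorescence transient
#'
#' Reads the canonical landmark intensities of the fast fluorescence rise:
#' F0 at 50 us (O step), F300 at 300 us (K step), FJ at 2 ms (J step) and FI
#' at 30 ms (I step), interpolating linearly in (ln t, F) when a landmark
#' time is not sampled exactly. FM is the global maximum of the trace (the P
#' step is defined as maximal fluorescence, which under stress need not fall
#' at the last sample). Derived quantities:
#' \deqn{V_J = (F_J - F_0)/(F_M - F_0), \quad V_I = (F_I - F_0)/(F_M - F_0),}
#' \deqn{M_0 = 4 (F_{300} - F_0)/(F_M - F_0).}
#'
#' @param transient A `FluorescenceTransient` (see [new_transient()]).
#' @return An object of class `JipLandmarks`: list with `F0`, `F300`, `FJ`,
#'   `FI`, `FM`, `VJ`, `VI`, `M0` and the trace `label`.
#' @examples
#' tr <- simulate_ojip_transient(transient_spec())$transient
#' extract_landmarks(tr)
#' @export
extract_landmarks <- function(transient) {
  stopifnot(inherits(transient, "FluorescenceTransient"))
  t <- transient$time
  f <- transient$fluorescence
  need <- c(F0 = .T_O, F300 = .T_K, FJ = .T_J, FI = .T_I)
  if (min(t) > min(need) || max(t) < max(need))
    .stopf("transient [%g, %g] s does not cover the landmark times [%g, %g] s",
           min(t), max(t), min(need), max(need))
  vals <- approx(log(t), f, xout = log(need), ties = "ordered")$y
  names(vals) <- names(need)
  fm <- max(f)
  if (fm <= vals[["F0"]])
    .stopf("degenerate transient: FM (%g) must exceed F0 (%g)", fm, vals[["F0"]])
  fv <- fm - vals[["F0"]]
  structure(list(
    F0 = vals[["F0"]], F300 = vals[["F300"]], FJ = vals[["FJ"]],
    FI = vals[["FI"]], FM = fm,
    VJ = (vals[["FJ"]] - vals[["F0"]]) / fv,
    VI = (vals[["FI"]] - vals[["F0"]]) / fv,
    M0 = 4 * (vals[["F300"]] - vals[["F0"]]) / fv,
    label = transient$label), class = "JipLandmarks")
}

#' Construct a landmark set directly from intensities
#'
#' Convenience constructor used when landmark intensities come from
#' instrument software rather than a full trace.
#'
#' @param F0,F300,FJ,FI,FM Fluorescence intensities (a.u.) at 50 us, 300 us,
#'   2 ms, 30 ms, and the trace maximum.
#' @param label Identifier.
#' @return A `JipLandmarks` object.
#' @export
jip_landmarks <- function(F0, F300, FJ, FI, FM, label = "landmarks") {
  if (FM <= F0) .stopf("degenerate landmarks: FM must exceed F0")
  fv <- FM - F0
  structure(list(F0 = F0, F300 = F300, FJ = FJ, FI = FI, FM = FM,
                 VJ = (FJ - F0) / fv, VI = (FI - F0) / fv,
                 M0 = 4 * (F300 - F0) / fv, label = label),
            class = "JipLandmarks")
}

#' @export
print.JipLandmarks <- function(x, ...) {
  cat(sprintf("JipLandmarks '%s': F0=%.4g F300=%.4g FJ=%.4g FI=%.4g FM=%.4g | VJ=%.4f VI=%.4f M0=%.4f\n",
              x$label, x$F0, x$F300, x$FJ, x$FI, x$FM, x$VJ, x$VI, x$M0))
  invisible(x)
}

#' Relative variable fluorescence curve
#'
#' Normalizes a transient between F0 (read at 50 us) and FM:
#' \deqn{V_t = (F_t - F_0)/(F_M - F_0)} so that the curve starts near 0 and
#' peaks at exactly 1 on the same time grid as the input.
#'
#' @param transient A `FluorescenceTransient`.
#' @return An object of class `VtCurve`: list with `time`, `vt`, `label`.
#' @export
relative_variable_fluorescence <- function(transient) {
  lm <- extract_landmarks(transient)
  structure(list(time = transient$time,
                 vt = (transient$fluorescence - lm$F0) / (lm$FM - lm$F0),
                 label = transient$label),
            class = "VtCurve")
}

#' Differential relative-variable-fluorescence curve and K/J/I bands
#'
#' Computes `delta_vt(t) = Vt_treated(t) - Vt_control(t)` on a shared
#' log-time grid (the curves are interpolated in (ln t, Vt) over the
#' overlapping time range). The sign convention is treated minus control, so
#' a stressed sample with an impaired oxygen-evolving complex shows a
#' positive K-band. Band amplitudes are the curve values at the K (300 us),
#' J (2 ms) and I (30 ms) times.
#'
#' @param treated_vt,control_vt `VtCurve` objects (see
#'   [relative_variable_fluorescence()]).
#' @param n_grid Number of points of the shared log-spaced grid.
#' @return An object of class `DifferentialCurve`: list with `time`,
#'   `delta_vt` and `bands` (named vector `dK`, `dJ`, `dI`).
#' @export
differential_curve <- function(treated_vt, control_vt, n_grid = 200) {
  stopifnot(inherits(treated_vt, "VtCurve"), inherits(control_vt, "VtCurve"))
  lo <- max(min(treated_vt$time), min(control_vt$time))
  hi <- min(max(treated_vt$time), max(control_vt$time))
  if (lo >= hi)
    .stopf("treated and control curves cover disjoint time ranges")
  grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  for (tk in c(.T_K, .T_J, .T_I)) {
    if (tk > lo && tk < hi) grid[which.min(abs(log(grid) - log(tk)))] <- tk
  }
  grid <- sort(grid)
  vt_t <- approx(log(treated_vt$time), treated_vt$vt, xout = log(grid),
                 ties = "ordered")$y
  vt_c <- approx(log(control_vt$time), control_vt$vt, xout = log(grid),
                 ties = "ordered")$y
  dv <- vt_t - vt_c
  band_at <- function(tk) {
    if (tk < lo || tk > hi) return(NA_real_)
    approx(log(grid), dv, xout = log(tk), ties = "ordered")$y
  }
  structure(list(time = grid, delta_vt = dv,
                 bands = c(dK = band_at(.T_K), dJ = band_at(.T_J),
                           dI = band_at(.T_I)),
                 treated = treated_vt$label, control = control_vt$label),
            class = "DifferentialCurve")
}

#' JIP-test parameters from a landmark set
#'
#' Applies the full JIP-test (Strasser framework) algebra to one landmark
#' set. Quantum yields and probabilities:
#' \deqn{\varphi_{P0} = 1 - F_0/F_M,\;\; \varphi_{D0} = F_0/F_M,\;\;
#'   \psi_{E0} = 1 - V_J,\;\; \varphi_{E0} = \varphi_{P0}\,\psi_{E0},}
#' \deqn{\delta_{R0} = (1 - V_I)/(1 - V_J),\;\;
#'   \varphi_{R0} = \varphi_{P0}(1 - V_I).}
#' Specific fluxes per active PSII reaction centre:
#' \deqn{TR_0/RC = M_0/V_J,\;\; ABS/RC = (M_0/V_J)/\varphi_{P0},\;\;
#'   DI_0/RC = ABS/RC - TR_0/RC,\;\; ET_0/RC = (M_0/V_J)\,\psi_{E0},}
#' reaction-centre density per cross section
#' \eqn{RC/CS_0 = F_0\,\varphi_{P0}\,V_J/M_0}, the antenna-partition
#' parameter \eqn{\gamma_{RC} = 1/(1 + ABS/RC)}, and the performance index
#' \deqn{PI_{ABS} = \frac{\varphi_{P0} V_J}{M_0}\cdot
#'   \frac{\varphi_{P0}}{1-\varphi_{P0}}\cdot\frac{1-V_J}{V_J}.}
#'
#' @param landmarks A `JipLandmarks` object (or anything [extract_landmarks()]
#'   returns).
#' @return An object of class `JipParameters` (named list); per-cross-section
#'   fluxes are filled by [cross_section_fluxes()].
#' @examples
#' jip_parameters(jip_landmarks(F0 = 500, F300 = 900, FJ = 1500,
#'                              FI = 2100, FM = 2500))
#' @export
jip_parameters <- function(landmarks) {
  stopifnot(inherits(landmarks, "JipLandmarks"))
  VJ <- landmarks$VJ; VI <- landmarks$VI; M0 <- landmarks$M0
  F0 <- landmarks$F0; FM <- landmarks$FM
  if (!(VJ > 0 && VJ < 1))
    .stopf("undefined parameters: VJ = %g must lie strictly in (0, 1)", VJ)
  if (!(VI > 0 && VI < 1))
    .stopf("undefined parameters: VI = %g must lie strictly in (0, 1)", VI)
  if (M0 <= 0) .stopf("undefined parameters: M0 = %g must be > 0", M0)
  if (F0 >= FM) .stopf("undefined parameters: F0 must be < FM")

  phiP0 <- 1 - F0 / FM
  phiD0 <- F0 / FM
  psiE0 <- 1 - VJ
  phiE0 <- phiP0 * psiE0
  deltaR0 <- (1 - VI) / (1 - VJ)
  phiR0 <- phiE0 * deltaR0
  TR0_RC <- M0 / VJ
  ABS_RC <- TR0_RC / phiP0
  DI0_RC <- ABS_RC - TR0_RC
  ET0_RC <- TR0_RC * psiE0
  RC_CS0 <- F0 * phiP0 * VJ / M0
  gammaRC <- 1 / (1 + ABS_RC)
  PI_ABS <- (phiP0 * VJ / M0) * (phiP0 / (1 - phiP0)) * ((1 - VJ) / VJ)

  structure(list(
    phiP0 = phiP0, phiE0 = phiE0, phiR0 = phiR0, phiD0 = phiD0,
    deltaR0 = deltaR0, psiE0 = psiE0,
    ABS_RC = ABS_RC, TR0_RC = TR0_RC, DI0_RC = DI0_RC, ET0_RC = ET0_RC,
    RC_CS0 = RC_CS0, gammaRC = gammaRC, PI_ABS = PI_ABS,
    ABS_CS = NA_real_, TR0_CS = NA_real_, ET0_CS = NA_real_,
    DI0_CS = NA_real_,
    label = landmarks$label), class = "JipParameters")
}

#' Fill the phenomenological per-cross-section energy fluxes
#'
#' The framework lists per-cross-section fluxes without printing a formula;
#' the standard proxy `ABS/CS0 ~ F0` is adopted (switchable to the FM-based
#' proxy), which makes `RC/CS0 * ABS/RC = F0` an exact internal identity.
#' Then `TR0/CS = phiP0 * ABS/CS`, `ET0/CS = phiE0 * ABS/CS`,
#' `DI0/CS = ABS/CS - TR0/CS`.
#'
#' @param params A `JipParameters` object from [jip_parameters()].
#' @param landmarks The matching `JipLandmarks`.
#' @param proxy `"F0"` (default) or `"FM"`: intensity used as the absorption
#'   flux proxy.
#' @return `params` with `ABS_CS`, `TR0_CS`, `ET0_CS`, `DI0_CS` filled.
#' @export
cross_section_fluxes <- function(params, landmarks, proxy = c("F0", "FM")) {
  stopifnot(inherits(params, "JipParameters"),
            inherits(landmarks, "JipLandmarks"))
  proxy <- match.arg(proxy)
  abs_cs <- if (proxy == "F0") landmarks$F0 else landmarks$FM
  params$ABS_CS <- abs_cs
  params$TR0_CS <- params$phiP0 * abs_cs
  params$ET0_CS <- params$phiE0 * abs_cs
  params$DI0_CS <- abs_cs - params$TR0_CS
  params
}

#' @export
print.JipParameters <- function(x, ...) {
  cat(sprintf("JipParameters '%s'\n", x$label))
  flds <- setdiff(names(x), "label")
  vals <- unlist(x[flds])
  print(round(vals, 4))
  invisible(x)
}

#' Full JIP-test analysis of one transient
#'
#' Convenience wrapper: landmarks, parameters and cross-section fluxes in a
#' single one-row data frame, suitable for binding across traces.
#'
#' @param transient A `FluorescenceTransient`.
#' @param proxy Absorption-flux proxy, see [cross_section_fluxes()].
#' @return A one-row data frame with landmark and parameter columns.
#' @export
jip_analyze <- function(transient, proxy = "F0") {
  lm <- extract_landmarks(transient)
  pp <- cross_section_fluxes(jip_parameters(lm), lm, proxy = proxy)
  cbind(data.frame(label = lm$label, stringsAsFactors = FALSE),
        as.data.frame(unclass(lm)[c("F0", "F300", "FJ", "FI", "FM",
                                    "VJ", "VI", "M0")]),
        as.data.frame(unclass(pp)[setdiff(names(pp), "label")]))
}

#' Group summaries of JIP parameters
#'
#' Mean, standard error, and percent-of-control for each numeric parameter
#' column of a per-trace table (one replicate = one trace).
#'
#' @param jip_table Data frame as returned by row-binding [jip_analyze()]
#'   outputs.
#' @param groups Character vector, one group label per row.
#' @param control_label Group considered the control (percent = 100).
#' @return A long data frame: group, parameter, mean, se, n,
#'   percent_of_control.
#' @export
jip_group_summary <- function(jip_table, groups, control_label) {
  if (length(groups) != nrow(jip_table))
    .stopf("groups must have one label per row")
  if (!control_label %in% groups)
    .stopf("control label '%s' absent from groups", control_label)
  num_cols <- names(jip_table)[vapply(jip_table, is.numeric, logical(1))]
  out <- do.call(rbind, lapply(num_cols, function(p) {
    v <- jip_table[[p]]
    agg_mean <- tapply(v, groups, mean)
    agg_se <- tapply(v, groups, function(x) sd(x) / sqrt(length(x)))
    agg_n <- tapply(v, groups, length)
    ctrl <- agg_mean[[control_label]]
    data.frame(group = names(agg_mean), parameter = p,
               mean = as.numeric(agg_mean), se = as.numeric(agg_se),
               n = as.integer(agg_n),
               percent_of_control = if (ctrl != 0)
                 100 * as.numeric(agg_mean) / ctrl else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
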