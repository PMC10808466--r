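#' Chip geometry
#'
#' Dimensions and volumes of the two-channel microfluidic chip that
#' govern the transport model.  Note three distinct heights: the flow
#' channel height entering the shear-stress formula, the capillary fluid
#' column height entering the hydrostatic pressure, and the membrane
#' thickness entering Darcy's law.
#'
#' @param channel_width_w_cm Flow channel width, cm.
#' @param channel_height_h_cm Flow channel height, cm.
#' @param capillary_height_cm Capillary fluid column height for the
#'   hydrostatic term, cm.
#' @param membrane_thickness_um Membrane thickness, micrometres
#'   (nominal 20 for the track-etched polycarbonate membrane).
#' @param exposed_area_A_cm2 Membrane area exposed to the channel, cm^2.
#' @param capillary_volume_Vc_ml,filtrate_volume_Vf_ml Channel volumes,
#'   mL.
#' @return An object of class `chip_geometry`.
#' @export
chip_geometry <- function(channel_width_w_cm, channel_height_h_cm,
                          capillary_height_cm, membrane_thickness_um = 20,
                          exposed_area_A_cm2, capillary_volume_Vc_ml,
                          filtrate_volume_Vf_ml) {
  vals <- c(channel_width_w_cm, channel_height_h_cm, capillary_height_cm,
            membrane_thickness_um, exposed_area_A_cm2,
            capillary_volume_Vc_ml, filtrate_volume_Vf_ml)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all chip geometry values must be strictly positive",
         call. = FALSE)
  }
  structure(list(channel_width_w_cm = channel_width_w_cm,
                 channel_height_h_cm = channel_height_h_cm,
                 capillary_height_cm = capillary_height_cm,
                 membrane_thickness_um = membrane_thickness_um,
                 exposed_area_A_cm2 = exposed_area_A_cm2,
                 capillary_volume_Vc_ml = capillary_volume_Vc_ml,
                 filtrate_volume_Vf_ml = filtrate_volume_Vf_ml),
            class = "chip_geometry")
}

#' Fluid properties
#'
#' The model mixes unit systems deliberately: shear stress and
#' hydrostatic pressure are computed in cgs (poise, dynes, barye with a
#' 0.1 factor to Pa), Darcy flux and osmotic pressure in SI/mixed units.
#' Both viscosity representations are therefore stored and must agree
#' (1 poise = 0.1 Pa s).
#'
#' @param viscosity_mu_poise Dynamic viscosity, poise; default is water
#'   at 37 degrees C (0.006913 poise).
#' @param viscosity_mu_pas Same viscosity in Pa s; derived when omitted.
#' @param density_rho_g_cm3 Fluid density, g/cm^3.
#' @param gravity_g_cm_s2 Gravitational acceleration, cm/s^2.
#' @param temperature_T_K Temperature, K (default 310.15 K = 37 C).
#' @param gas_constant_R Universal gas constant, atm L / (mol K).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(viscosity_mu_poise = 0.006913,
                             viscosity_mu_pas = NULL,
                             density_rho_g_cm3 = 0.9933,
                             gravity_g_cm_s2 = 981,
                             temperature_T_K = 310.15,
                             gas_constant_R = 0.08206) {
  if (is.null(viscosity_mu_pas)) {
    viscosity_mu_pas <- 0.1 * viscosity_mu_poise
  }
  if (abs(viscosity_mu_pas - 0.1 * viscosity_mu_poise) > 1e-12) {
    stop("viscosity fields disagree: 1 poise = 0.1 Pa s", call. = FALSE)
  }
  if (viscosity_mu_poise <= 0 || density_rho_g_cm3 <= 0 ||
      temperature_T_K <= 0) {
    stop("viscosity, density and temperature must be positive",
         call. = FALSE)
  }
  structure(list(viscosity_mu_poise = viscosity_mu_poise,
                 viscosity_mu_pas = viscosity_mu_pas,
                 density_rho_g_cm3 = density_rho_g_cm3,
                 gravity_g_cm_s2 = gravity_g_cm_s2,
                 temperature_T_K = temperature_T_K,
                 gas_constant_R = gas_constant_R),
            class = "fluid_properties")
}

#' Tracer molecule
#'
#' A dye-conjugated molecule tracked by the sensor.  The molecular
#' weight is a configuration field (free vs. conjugated molecule is the
#' caller's choice) and feeds the osmotic pressure; the membrane
#' permeability is a property of the molecule/membrane pair.
#'
#' @param name Tracer label, e.g. `"inulin-FITC"`.
#' @param molecular_weight_g_mol Molar mass, g/mol.
#' @param permeability_kappa_um2 Darcy permeability, square micrometres.
#' @param dye_channel LED channel that excites the conjugate.
#' @return An object of class `tracer`.
#' @export
tracer <- function(name, molecular_weight_g_mol, permeability_kappa_um2,
                   dye_channel = "cyan") {
  if (molecular_weight_g_mol <= 0) {
    stop("molecular weight must be > 0", call. = FALSE)
  }
  if (permeability_kappa_um2 < 0) {
    stop("permeability must be >= 0", call. = FALSE)
  }
  structure(list(name = name,
                 molecular_weight_g_mol = molecular_weight_g_mol,
                 permeability_kappa_um2 = permeability_kappa_um2,
                 dye_channel = dye_channel),
            class = "tracer")
}

#' Operating point of the perfusion system
#'
#' @param flowrate_Q_ml_s Volumetric flowrate, mL/s, `>= 0`.
#' @param capillary_concentration_C0_mg_ml Initial capillary tracer
#'   concentration, mg/mL, `>= 0`.
#' @return An object of class `operating_point`; the linear velocity
#'   `Q / (w h)` (cm/s) is derived on demand by the model.
#' @export
operating_point <- function(flowrate_Q_ml_s,
                            capillary_concentration_C0_mg_ml) {
  if (flowrate_Q_ml_s < 0) stop("flowrate must be >= 0", call. = FALSE)
  if (capillary_concentration_C0_mg_ml < 0) {
    stop("capillary concentration must be >= 0", call. = FALSE)
  }
  structure(list(flowrate_Q_ml_s = flowrate_Q_ml_s,
                 capillary_concentration_C0_mg_ml =
                   capillary_concentration_C0_mg_ml),
            class = "operating_point")
}

#' Wall shear stress in a rectangular channel
#'
#' Parallel-plate approximation `tau = 6 Q mu / (w h^2)` in cgs units:
#' Q in mL/s (= cm^3/s), mu in poise, w and h in cm, result in
#' dynes/cm^2.  Strictly linear in Q.
#'
#' @param Q_ml_s Flowrate, mL/s.
#' @param mu_poise Viscosity, poise.
#' @param w_cm Channel width, cm.
#' @param h_cm Channel height, cm.
#' @return Shear stress, dynes/cm^2.
#' @export
shear_stress <- function(Q_ml_s, mu_poise, w_cm, h_cm) {
  if (any(w_cm <= 0) || any(h_cm <= 0) || any(mu_poise <= 0)) {
    stop("viscosity and channel dimensions must be > 0", call. = FALSE)
  }
  if (any(Q_ml_s < 0)) stop("flowrate must be >= 0", call. = FALSE)
  6 * Q_ml_s * mu_poise / (w_cm * h_cm^2)
}

#' Hydrostatic pressure from Bernoulli's law
#'
#' `0.1 * (rho g h - rho v^2 / 2)` with the cgs inputs (g/cm^3, cm/s^2,
#' cm, cm/s) giving barye, and the 0.1 converting barye to Pa.  At high
#' linear velocity the dynamic term can make the result negative; it is
#' reported as-is.
#'
#' @param rho_g_cm3 Density, g/cm^3.
#' @param g_cm_s2 Gravitational acceleration, cm/s^2.
#' @param h_cap_cm Capillary fluid column height, cm.
#' @param v_cm_s Linear flow velocity, cm/s.
#' @return Pressure, Pa.
#' @export
hydrostatic_pressure <- function(rho_g_cm3, g_cm_s2, h_cap_cm, v_cm_s) {
  if (any(rho_g_cm3 < 0) || any(g_cm_s2 < 0) || any(h_cap_cm < 0)) {
    stop("density, gravity and height must be >= 0", call. = FALSE)
  }
  0.1 * (rho_g_cm3 * g_cm_s2 * h_cap_cm - 0.5 * rho_g_cm3 * v_cm_s^2)
}

#' Osmotic pressure (van 't Hoff)
#'
#' `pi = M R T` in atm, converted to Pa (x 101325) so all pressures enter
#' Darcy's law on the same scale.
#'
#' @param M_mol_l Molarity of the capillary solution, mol/L.
#' @param T_K Temperature, K.
#' @param R_atm_l Gas constant, atm L / (mol K).
#' @return Pressure, Pa.
#' @export
osmotic_pressure <- function(M_mol_l, T_K, R_atm_l = 0.08206) {
  if (any(M_mol_l < 0)) stop("molarity must be >= 0", call. = FALSE)
  if (any(T_K <= 0)) stop("temperature must be > 0", call. = FALSE)
  M_mol_l * R_atm_l * T_K * 101325
}

#' Trans-membrane pressure differential
#'
#' The driving pressure for Darcy flux: the sum of the hydrostatic and
#' osmotic contributions (both in Pa).
#'
#' @param hydrostatic_pa,osmotic_pa Pressures, Pa.
#' @return Pressure differential, Pa.
#' @export
pressure_differential <- function(hydrostatic_pa, osmotic_pa) {
  hydrostatic_pa + osmotic_pa
}

#' Darcy flux per unit membrane area
#'
#' `j = kappa / (mu h) * dP` with kappa in um^2, mu in Pa s, membrane
#' thickness h in um and dP in Pa; the units contract to um/s
#' (equivalently um^3 per um^2 per second).
#'
#' @param kappa_um2 Membrane permeability for the molecule, um^2.
#' @param mu_pas Fluid viscosity, Pa s.
#' @param h_membrane_um Membrane thickness, um.
#' @param dP_pa Pressure differential, Pa.
#' @return Flux per unit area, um/s.
#' @export
darcy_flux_per_area <- function(kappa_um2, mu_pas, h_membrane_um, dP_pa) {
  if (any(kappa_um2 < 0)) stop("permeability must be >= 0", call. = FALSE)
  if (any(mu_pas <= 0) || any(h_membrane_um <= 0)) {
    stop("viscosity and membrane thickness must be > 0", call. = FALSE)
  }
  kappa_um2 / (mu_pas * h_membrane_um) * dP_pa
}

#' Total volumetric flux through the exposed membrane
#'
#' Multiplies the per-area flux (um/s) by the exposed membrane area.
#' Dimensional consistency requires the area in um^2 before the
#' um^3 -> mL factor of 1e-12 is applied, so with A in cm^2
#' (1 cm^2 = 1e8 um^2) the net conversion is `J = j * A * 1e-4` mL/s.
#'
#' @param j_um_s Flux per unit area, um/s.
#' @param A_cm2 Exposed membrane area, cm^2.
#' @return Volumetric flux, mL/s.
#' @export
total_flux <- function(j_um_s, A_cm2) {
  if (any(A_cm2 <= 0)) stop("exposed area must be > 0", call. = FALSE)
  j_um_s * (A_cm2 * 1e8) * 1e-12
}

#' Tracer mass flux through the membrane
#'
#' @param J_ml_s Volumetric flux, mL/s.
#' @param C0_mg_ml Capillary tracer concentration, mg/mL.
#' @return Mass flux, mg/s.
#' @export
mass_flux <- function(J_ml_s, C0_mg_ml) {
  if (any(J_ml_s < 0) || any(C0_mg_ml < 0)) {
    stop("flux and concentration must be >= 0", call. = FALSE)
  }
  J_ml_s * C0_mg_ml
}

#' Membrane exposure time of the perfused fluid
#'
#' `V_c / Q`: how long a parcel of capillary fluid spends over the
#' membrane.
#'
#' @param Vc_ml Capillary channel volume, mL.
#' @param Q_ml_s Flowrate, mL/s, `> 0`.
#' @return Exposure time, seconds.
#' @export
exposure_time <- function(Vc_ml, Q_ml_s) {
  if (any(Vc_ml <= 0)) stop("capillary volume must be > 0", call. = FALSE)
  if (any(Q_ml_s <= 0)) {
    stop("static (no-flow) regime: exposure time is undefined at Q = 0",
         call. = FALSE)
  }
  Vc_ml / Q_ml_s
}

#' Full steady-state transport prediction
#'
#' Composes the pressure, Darcy and residence-time steps into the
#' predicted steady-state filtrate concentration
#' `C_f = J C0 (V_c / Q) / V_f`, returning every intermediate quantity.
#' Because the osmotic pressure grows with C0, the prediction is
#' super-linear (and the diffusion fraction monotone increasing) in C0;
#' it is exactly zero for an impermeable membrane (kappa = 0).
#'
#' @param geom A [chip_geometry()].
#' @param fluid A [fluid_properties()].
#' @param trc A [tracer()].
#' @param op An [operating_point()] with `Q > 0`.
#' @param tau_s Transient time constant stored on the prediction
#'   (default 120 s, from prior literature on comparable lumped systems).
#' @return An object of class `transport_prediction` with fields
#'   `linear_velocity_v_cm_s`, `hydrostatic_pa`, `osmotic_pa`,
#'   `pressure_dP_pa`, `flux_per_area_j_um_s`, `total_flux_J_ml_s`,
#'   `mass_flux_mg_s`, `exposure_time_s`,
#'   `filtrate_eq_concentration_mg_ml`, `transient_a_mg_ml`,
#'   `transient_b_mg_ml`, `time_constant_tau_s`.
#' @export
steady_state_prediction <- function(geom, fluid, trc, op, tau_s = 120) {
  if (op$flowrate_Q_ml_s <= 0) {
    stop("steady-state prediction requires Q > 0", call. = FALSE)
  }
  v <- op$flowrate_Q_ml_s /
    (geom$channel_width_w_cm * geom$channel_height_h_cm)
  hs <- hydrostatic_pressure(fluid$density_rho_g_cm3, fluid$gravity_g_cm_s2,
                             geom$capillary_height_cm, v)
  M <- op$capillary_concentration_C0_mg_ml / trc$molecular_weight_g_mol
  os <- osmotic_pressure(M, fluid$temperature_T_K, fluid$gas_constant_R)
  dP <- pressure_differential(hs, os)
  j <- darcy_flux_per_area(trc$permeability_kappa_um2, fluid$viscosity_mu_pas,
                           geom$membrane_thickness_um, dP)
  J <- total_flux(j, geom$exposed_area_A_cm2)
  mdot <- mass_flux(J, op$capillary_concentration_C0_mg_ml)
  texp <- exposure_time(geom$capillary_volume_Vc_ml, op$flowrate_Q_ml_s)
  cf <- mdot * texp / geom$filtrate_volume_Vf_ml
  structure(list(linear_velocity_v_cm_s = v,
                 hydrostatic_pa = hs,
                 osmotic_pa = os,
                 pressure_dP_pa = dP,
                 flux_per_area_j_um_s = j,
                 total_flux_J_ml_s = J,
                 mass_flux_mg_s = mdot,
                 exposure_time_s = texp,
                 filtrate_eq_concentration_mg_ml = cf,
                 transient_a_mg_ml = NA_real_,
                 transient_b_mg_ml = NA_real_,
                 time_constant_tau_s = tau_s),
            class = "transport_prediction")
}

#' Steady-state filtrate concentration
#'
#' Convenience scalar wrapper around [steady_state_prediction()].
#'
#' @inheritParams steady_state_prediction
#' @return Predicted filtrate concentration at equilibrium, mg/mL.
#' @export
steady_state_filtrate_concentration <- function(geom, fluid, trc, op) {
  steady_state_prediction(geom, fluid, trc, op)$
    filtrate_eq_concentration_mg_ml
}

#' Estimate membrane permeability from a measured filtrate concentration
#'
#' Inverts the Darcy/steady-state chain for kappa.  The chain is linear
#' in kappa at fixed pressure differential, so
#' `kappa = measured_cf / C_f(kappa = 1)`; the round trip with
#' [steady_state_filtrate_concentration()] is the identity.
#'
#' If `perfusion_time_s` is supplied and is short relative to the time
#' constant, the measured concentration is first de-attenuated by the
#' first-order factor `1 - exp(-t/tau)` so that a reading taken before
#' equilibrium still yields the equilibrium-consistent permeability.
#' Left `NULL` (default) the measurement is taken as the steady state,
#' matching the reference protocol of a 30-minute perfusion (15 tau).
#'
#' @param measured_cf_mg_ml Filtrate concentration observed after the
#'   perfusion, mg/mL.
#' @param geom,fluid,op See [steady_state_prediction()].
#' @param tracer_mw_g_mol Tracer molar mass, g/mol (the permeability is
#'   the unknown, so a full [tracer()] is not required).
#' @param perfusion_time_s Optional perfusion duration, s.
#' @param tau_s Time constant used for the optional de-attenuation.
#' @return Permeability kappa, um^2 (0, flagged with attribute
#'   `boundary = TRUE`, when the measured concentration is 0).
#' @export
estimate_permeability <- function(measured_cf_mg_ml, geom, fluid,
                                  tracer_mw_g_mol, op,
                                  perfusion_time_s = NULL, tau_s = 120) {
  if (measured_cf_mg_ml < 0) {
    stop("invalid measurement: filtrate concentration must be >= 0",
         call. = FALSE)
  }
  if (measured_cf_mg_ml == 0) {
    return(structure(0, boundary = TRUE))
  }
  cf <- measured_cf_mg_ml
  if (!is.null(perfusion_time_s)) {
    if (perfusion_time_s <= 0) {
      stop("perfusion time must be > 0", call. = FALSE)
    }
    cf <- cf / (1 - exp(-perfusion_time_s / tau_s))
  }
  unit <- tracer("unit", tracer_mw_g_mol, 1, dye_channel = "none")
  per_unit_kappa <- steady_state_filtrate_concentration(geom, fluid, unit, op)
  if (per_unit_kappa <= 0) {
    stop("invalid measurement: configuration admits no positive permeability",
         call. = FALSE)
  }
  structure(cf / per_unit_kappa, boundary = FALSE)
}

#' First-order transient response of the filtrate concentration
#'
#' The lumped-parameter (resistor-capacitor analog) step response
#' `c_f(t) = a + b (1 - exp(-t / tau))`: `a` is the starting equilibrium
#' concentration, `a + b` the new equilibrium, and `tau` the time
#' constant of the molecule moving through the system (default 120 s).
#'
#' @param a_mg_ml Starting concentration, mg/mL.
#' @param b_mg_ml Equilibrium shift, mg/mL (may be negative for a
#'   falling step).
#' @param tau_s Time constant, s, `> 0`.
#' @param t_s Time(s) since the step, s, `>= 0`.
#' @return Filtrate concentration(s), mg/mL.
#' @export
transient_response <- function(a_mg_ml, b_mg_ml, tau_s, t_s) {
  if (tau_s <= 0) stop("time constant must be > 0", call. = FALSE)
  if (any(t_s < 0)) stop("time must be >= 0", call. = FALSE)
  a_mg_ml + b_mg_ml * (1 - exp(-t_s / tau_s))
}

#' Predicted equilibrium diffusion percentage across flowrates
#'
#' For each flowrate, predicts the steady-state filtrate concentration
#' and converts it to a diffusion percentage of the capillary
#' concentration.  In a cell-free chip the model output is strictly
#' decreasing in flowrate: residence time scales as 1/Q while the
#' pressure differential barely changes.
#'
#' @param flowrates_ml_s Positive, distinct flowrates, mL/s.
#' @param geom,fluid,trc See [steady_state_prediction()].
#' @param C0_mg_ml Capillary concentration, mg/mL.
#' @return A `data.frame` with columns `flowrate_ml_s`,
#'   `filtrate_eq_mg_ml`, `diffusion_percent`, ordered as given.
#' @export
predict_equilibrium_diffusion_vs_flowrate <- function(flowrates_ml_s, geom,
                                                      fluid, trc, C0_mg_ml) {
  if (any(flowrates_ml_s <= 0)) {
    stop("flowrates must be strictly positive", call. = FALSE)
  }
  if (anyDuplicated(flowrates_ml_s)) {
    stop("flowrates must be distinct", call. = FALSE)
  }
  cf <- vapply(flowrates_ml_s, function(q) {
    steady_state_filtrate_concentration(
      geom, fluid, trc, operating_point(q, C0_mg_ml))
  }, numeric(1))
  data.frame(flowrate_ml_s = flowrates_ml_s,
             filtrate_eq_mg_ml = cf,
             diffusion_percent = diffusion_percentage(cf, C0_mg_ml))
}
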