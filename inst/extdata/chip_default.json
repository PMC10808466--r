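{
  "_comment": "Default two-channel chip configuration. SYNTHETIC STAND-IN geometry: membrane thickness (20 um) and layer heights (1/16 inch capillary, 3 mm filtrate) follow the reference device description; the channel width is back-calculated from the device's reported wall shear stress of 30.7e-3 dynes/cm^2 at 100 uL/min; area and volumes assume a 4 cm exposed channel length. Replace with measured values for a real chip.",
  "geometry": {
    "channel_width_w_cm": 0.08935,
    "channel_height_h_cm": 0.15875,
    "capillary_height_cm": 0.15875,
    "membrane_thickness_um": 20,
    "exposed_area_A_cm2": 0.3574,
    "capillary_volume_Vc_ml": 0.056737,
    "filtrate_volume_Vf_ml": 0.10722
  },
  "fluid": {
    "viscosity_mu_poise": 0.006913,
    "density_rho_g_cm3": 0.9933,
    "gravity_g_cm_s2": 981,
    "temperature_T_K": 310.15,
    "gas_constant_R": 0.08206
  },
  "tracers": {
    "inulin-FITC": {
      "molecular_weight_g_mol": 5000,
      "permeability_kappa_um2": 2.01e-4,
      "dye_channel": "cyan"
    },
    "HSA-TexasRed": {
      "molecular_weight_g_mol": 68000,
      "permeability_kappa_um2": 9.67e-4,
      "dye_channel": "amber"
    }
  },
  "rois": {
    "capillary": {"row_start": 40, "row_end": 340, "col_start": 90, "col_end": 190},
    "filtrate": {"row_start": 40, "row_end": 340, "col_start": 310, "col_end": 410}
  },
  "schedule": {
    "channels": ["cyan", "amber"],
    "period_s": 120,
    "min_period_s": 7
  },
  "operating": {
    "flowrate": "8 uL/min",
    "capillary_concentration_C0_mg_ml": 0.1
  },
  "seed": 1
}
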