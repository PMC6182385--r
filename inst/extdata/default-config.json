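{
  "design": "nonsequential_rlc",
  "steps": {
    "par": [34, 74, 114, 300, 470, 300, 470, 540, 74],
    "duration_s": [30, 30, 30, 30, 30, 30, 30, 30, 30]
  },
  "dark_adapt_s": 120,
  "step_offset_s": 30,
  "meas_interval_s": 60,
  "train": {
    "n_flashlets": 40,
    "flashlet_duration": 1.2,
    "gap_duration": 1,
    "dose_per_flashlet": null,
    "wavelength_nm": 455
  },
  "generator": {
    "F0_dark": 0.2,
    "FM_dark": 0.5,
    "sigma_dark": 400,
    "rho_dark": 0.3,
    "tau1_base": 500,
    "tau1_max": 1800,
    "tau2": 5000,
    "alpha1": 0.7,
    "npq_par_threshold": 305,
    "npq_rate": 0.003,
    "npq_relax_rate": 0.0005,
    "sigma_slope": -0.65,
    "upregulation": true,
    "upreg_factor": 0.5,
    "upreg_exposure_s": 35,
    "growth_par": 74,
    "dtt_mode": false,
    "noise_cv": 0.01
  },
  "fit": {
    "rel_tol": 1e-10,
    "max_iter": 500,
    "rho_max": 0.8,
    "sigma_factor": 10
  },
  "treatment": "control",
  "seed": 1
}
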