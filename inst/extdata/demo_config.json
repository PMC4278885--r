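{
  "seed": 20261,
  "out_dir": "mfa_demo_run",
  "ramp": {"retraction_speed": 1.0, "effective_stiffness": 100, "kT": 4.11},
  "dx": 1.0,
  "references": {
    "shear40": {"length_bp": 40, "geometry": "shear"},
    "shear40_propynyl": {"length_bp": 40, "geometry": "shear", "propynyl_count": 22},
    "shear20_P1": {"length_bp": 20, "geometry": "shear", "ligand": "P1"},
    "shear20_P2": {"length_bp": 20, "geometry": "shear", "ligand": "P2"},
    "shear20_P3": {"length_bp": 20, "geometry": "shear", "ligand": "P3"}
  },
  "conditions": {
    "Enh_eGFP":  {"protein_force": 73.1, "reference": "shear20_P1", "ce": 0.8},
    "Enh_wtGFP": {"protein_force": 73.0, "reference": "shear20_P1", "ce": 0.8},
    "Enh_sfGFP": {"protein_force": 75.0, "reference": "shear20_P1", "ce": 0.8},
    "sweep_40bp":     {"protein_force": 75.0, "reference": "shear40", "ce": 0.8},
    "sweep_propynyl": {"protein_force": 75.0, "reference": "shear40_propynyl", "ce": 0.8},
    "sweep_P3":       {"protein_force": 75.0, "reference": "shear20_P3", "ce": 0.8},
    "sweep_P2":       {"protein_force": 75.0, "reference": "shear20_P2", "ce": 0.8}
  },
  "layout": [
    ["Enh_eGFP",  "Enh_eGFP",  "Enh_eGFP",  "Enh_eGFP"],
    ["Enh_wtGFP", "Enh_wtGFP", "Enh_wtGFP", "Enh_wtGFP"],
    ["Enh_sfGFP", "Enh_sfGFP", "Enh_sfGFP", "Enh_sfGFP"],
    ["sweep_40bp", "sweep_propynyl", "sweep_P3", "sweep_P2"]
  ],
  "image": {"shape": [128, 128], "mask_radius": 48, "probe_density": 50},
  "optical": {"gain_red": 120, "gain_fret": 100, "fret_factor": 0.8,
              "illumination": "gaussian", "illum_amplitude": 1},
  "noise": {"background_offset": 100, "read_noise_sd": 2, "shot_noise": true},
  "analysis": {"min_start_counts": 10, "fret_ratio_max": 0.995,
               "nf_window": [-0.25, 1.25], "bins": 100,
               "min_pixels": 100, "ce_floor": 0.05}
}
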