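{
  "comment": "Condition presets emulating svFCS and FRAP measurements on HEL erythroid cells. 'law' blocks carry the published ground-truth diffusion-law parameters used by law-level round trips (t0 in ms, d_eff in um^2/s, SEMs as printed); 'frap' blocks the published half-time (s) and mobile fraction (%). 'sim' blocks are the calibrated particle-level parameters (lengths um, times s, D um^2/s), chosen once so that the particle pipeline reproduces the ordering and approximate magnitude of the published confinement intercepts: domain occupancy ~1 - D_eff/d_out and mean residence ~ (t0 / occupancy) set (p_enter, p_escape) via the measured scalings tau_res ~ 0.5 ms / p_escape (at d_in = 0.1) and K = (p_enter/p_escape) * sqrt(d_out/d_in).",
  "version": 1,
  "detection": { "bin_time_s": 1e-4, "brightness": 3.0, "background": 0.1 },
  "waists_um": [0.20, 0.25, 0.30, 0.35],
  "conditions": {
    "SM_control": {
      "law": { "t0_ms": 10.25, "t0_sem_ms": 1.43, "d_eff": 1.18, "d_eff_sem": 0.09, "cell_cv": 0.15 },
      "sim": { "box_size": 2.0, "n_particles": 64, "dt": 2e-5, "d_out": 1.8, "d_in": 0.1,
               "p_enter": 0.02, "p_escape": 0.018, "radius": 0.04, "area_fraction": 0.10 }
    },
    "SM_KnD": {
      "law": { "t0_ms": 3.71, "t0_sem_ms": 2.44, "d_eff": 0.68, "d_eff_sem": 0.06, "cell_cv": 0.15 },
      "sim": { "box_size": 2.0, "n_particles": 64, "dt": 2e-5, "d_out": 1.0, "d_in": 0.1,
               "p_enter": 0.05, "p_escape": 0.04, "radius": 0.04, "area_fraction": 0.10 }
    },
    "SM_ZA_Myr": {
      "law": { "t0_ms": 4.77, "t0_sem_ms": 1.08, "d_eff": 0.81, "d_eff_sem": 0.04, "cell_cv": 0.15 },
      "sim": { "box_size": 2.0, "n_particles": 64, "dt": 2e-5, "d_out": 1.15, "d_in": 0.1,
               "p_enter": 0.035, "p_escape": 0.03, "radius": 0.04, "area_fraction": 0.10 }
    },
    "SM_rescue": {
      "law": { "t0_ms": 8.28, "t0_sem_ms": 1.46, "d_eff": 1.01, "d_eff_sem": 0.07, "cell_cv": 0.15 },
      "sim": { "box_size": 2.0, "n_particles": 64, "dt": 2e-5, "d_out": 1.55, "d_in": 0.1,
               "p_enter": 0.028, "p_escape": 0.023, "radius": 0.04, "area_fraction": 0.10 }
    },
    "PC_control": {
      "law": { "t0_ms": 1.04, "t0_sem_ms": 2.49, "d_eff": 1.09, "d_eff_sem": 0.12, "cell_cv": 0.15 },
      "sim": { "box_size": 3.0, "n_particles": 144, "dt": 5e-5, "d_out": 1.09, "d_in": 1.09,
               "p_enter": 0.0, "p_escape": 1.0, "radius": 0.04, "area_fraction": 0.0 }
    },
    "PC_KnD": {
      "law": { "t0_ms": 2.18, "t0_sem_ms": 2.04, "d_eff": 1.15, "d_eff_sem": 0.15, "cell_cv": 0.15 },
      "sim": { "box_size": 3.0, "n_particles": 144, "dt": 5e-5, "d_out": 1.15, "d_in": 1.15,
               "p_enter": 0.0, "p_escape": 1.0, "radius": 0.04, "area_fraction": 0.0 }
    },
    "Thy1_control": {
      "law": { "t0_ms": 22.26, "t0_sem_ms": 2.37, "d_eff": 1.42, "d_eff_sem": 0.26, "cell_cv": 0.15 },
      "sim": { "box_size": 2.0, "n_particles": 64, "dt": 2e-5, "d_out": 2.18, "d_in": 0.1,
               "p_enter": 0.008, "p_escape": 0.008, "radius": 0.04, "area_fraction": 0.10 }
    },
    "Thy1_KnD": {
      "law": { "t0_ms": 13.21, "t0_sem_ms": 1.85, "d_eff": 0.79, "d_eff_sem": 0.06, "cell_cv": 0.15 },
      "sim": { "box_size": 2.0, "n_particles": 64, "dt": 2e-5, "d_out": 1.22, "d_in": 0.1,
               "p_enter": 0.018, "p_escape": 0.013, "radius": 0.04, "area_fraction": 0.10 }
    },
    "Flot2_control": {
      "frap": { "t_half_s": 13.7, "t_half_sd_s": 4.51, "mobile_pct": 42.13, "mobile_sd_pct": 4.01 },
      "sim": { "box_size": 2.0, "n_particles": 64, "dt": 5e-4, "d_out": 0.05, "d_in": 0.01,
               "p_enter": 0.05, "p_escape": 0.02, "radius": 0.04, "area_fraction": 0.10 }
    },
    "Flot2_KnD": {
      "frap": { "t_half_s": 11.26, "t_half_sd_s": 3.55, "mobile_pct": 41.74, "mobile_sd_pct": 4.15 },
      "sim": { "box_size": 2.0, "n_particles": 64, "dt": 5e-4, "d_out": 0.06, "d_in": 0.015,
               "p_enter": 0.05, "p_escape": 0.05, "radius": 0.04, "area_fraction": 0.10 }
    },
    "Flot2_MbCD": {
      "frap": { "t_half_s": 10.9, "t_half_sd_s": 3.49, "mobile_pct": 42.0, "mobile_sd_pct": 3.97 },
      "sim": { "box_size": 2.0, "n_particles": 64, "dt": 5e-4, "d_out": 0.065, "d_in": 0.02,
               "p_enter": 0.05, "p_escape": 0.08, "radius": 0.04, "area_fraction": 0.10 }
    }
  }
}
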