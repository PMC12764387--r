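{
  "seed": 1,
  "analysis": {
    "grid": [
      4,
      4
    ],
    "min_prominence_dff": 0.2,
    "min_separation_ms": 250,
    "hs_alpha": 1,
    "hs_n_iter": 200,
    "hs_tol": 0.0001,
    "mask_threshold": 0.2
  },
  "conditions": [
    {
      "name": "no_stim",
      "movie": {
        "pattern": "source",
        "h": 48,
        "w": 48,
        "nframes": 60,
        "speed": 120,
        "period_ms": 2000,
        "noise_sd": 0.02,
        "kernel": {
          "rise_ms": 400,
          "tau_ms": 480
        }
      },
      "motion": {
        "h": 48,
        "w": 48,
        "nframes": 80,
        "beat_period_ms": 1000,
        "peak_displacement_px": 3,
        "contraction_fraction": 0.45
      }
    },
    {
      "name": "static_1hz_4ms",
      "regimen": {
        "shape": "biphasic",
        "voltage_V": 4,
        "phase_duration_ms": 4,
        "frequency_Hz": 1
      },
      "movie": {
        "pattern": "source",
        "h": 48,
        "w": 48,
        "nframes": 60,
        "speed": 100,
        "period_ms": 2000,
        "noise_sd": 0.02,
        "kernel": {
          "rise_ms": 500,
          "tau_ms": 600
        }
      },
      "motion": {
        "h": 48,
        "w": 48,
        "nframes": 80,
        "beat_period_ms": 1000,
        "peak_displacement_px": 2,
        "contraction_fraction": 0.45
      }
    },
    {
      "name": "static_2hz_4ms",
      "regimen": {
        "shape": "biphasic",
        "voltage_V": 4,
        "phase_duration_ms": 4,
        "frequency_Hz": 2
      },
      "movie": {
        "pattern": "source",
        "h": 48,
        "w": 48,
        "nframes": 60,
        "speed": 110,
        "period_ms": 2000,
        "noise_sd": 0.02,
        "kernel": {
          "rise_ms": 600,
          "tau_ms": 570
        }
      },
      "motion": {
        "h": 48,
        "w": 48,
        "nframes": 80,
        "beat_period_ms": 1000,
        "peak_displacement_px": 2.5,
        "contraction_fraction": 0.45
      }
    },
    {
      "name": "static_1hz_8ms",
      "regimen": {
        "shape": "biphasic",
        "voltage_V": 4,
        "phase_duration_ms": 8,
        "frequency_Hz": 1
      },
      "movie": {
        "pattern": "plane_wave",
        "h": 48,
        "w": 48,
        "nframes": 60,
        "speed": 150,
        "period_ms": 2000,
        "noise_sd": 0.02,
        "kernel": {
          "rise_ms": 550,
          "tau_ms": 490
        }
      },
      "motion": {
        "h": 48,
        "w": 48,
        "nframes": 80,
        "beat_period_ms": 1000,
        "peak_displacement_px": 2,
        "contraction_fraction": 0.45
      }
    },
    {
      "name": "ramped_frequency",
      "regimen": {
        "shape": "biphasic",
        "voltage_V": 4,
        "phase_duration_ms": 4,
        "frequency_Hz": 1,
        "ramp": {
          "field": "frequency_Hz",
          "end_value": 2,
          "duration_days": 10
        }
      },
      "movie": {
        "pattern": "plane_wave",
        "h": 48,
        "w": 48,
        "nframes": 60,
        "speed": 200,
        "period_ms": 2000,
        "noise_sd": 0.02,
        "kernel": {
          "rise_ms": 530,
          "tau_ms": 520
        }
      },
      "motion": {
        "h": 48,
        "w": 48,
        "nframes": 80,
        "beat_period_ms": 1000,
        "peak_displacement_px": 1.7,
        "contraction_fraction": 0.45
      }
    },
    {
      "name": "ramped_duration",
      "regimen": {
        "shape": "biphasic",
        "voltage_V": 4,
        "phase_duration_ms": 4,
        "frequency_Hz": 1,
        "ramp": {
          "field": "phase_duration_ms",
          "end_value": 8,
          "duration_days": 10
        }
      },
      "movie": {
        "pattern": "plane_wave",
        "h": 48,
        "w": 48,
        "nframes": 60,
        "speed": 260,
        "period_ms": 2000,
        "noise_sd": 0.02,
        "kernel": {
          "rise_ms": 500,
          "tau_ms": 360
        }
      },
      "motion": {
        "h": 48,
        "w": 48,
        "nframes": 80,
        "beat_period_ms": 1000,
        "peak_displacement_px": 1.7,
        "contraction_fraction": 0.45
      }
    }
  ]
}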