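# Central defaults for vessel hemodynamics runs.
# Units are stated per field; all internal computation is SI.
rheology:
  density: 1060          # kg/m^3, whole blood
  mu_inf: 0.0035         # Pa s, infinite-shear viscosity
  mu_zero: 0.056         # Pa s, zero-shear viscosity
  lambda_time: 3.313     # s, Carreau-Yasuda time constant
  power_n: 0.3568        # dimensionless power-law exponent
waveform:
  period: 1.0            # s, cardiac cycle
  peak_time: 0.14        # s, systolic peak
  systolic_mmHg: 140     # mmHg (hypertensive/aneurysmal setting)
  diastolic_mmHg: 80     # mmHg
  harmonic_count: 8
solver:
  residual_tolerance: 1.0e-5
  cycles: 3              # washout cycles; final cycle reported
validation:
  equivalent_diameter_mm: 25.2   # descending-aorta equivalent diameter
indices:
  snapshot_times_s: [0.01, 0.14, 0.35, 0.59]
  rrt_ceiling: 1000.0    # 1/Pa, cap at singular points
geometry:
  pre_ad:
    ascending_diameter_mm: 52.79
    descending_diameter_mm: 28.44
  post_ad:
    true_lumen_mm: [23.17, 20.18]    # ascending, descending
    false_lumen_mm: [44.55, 19.11]
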