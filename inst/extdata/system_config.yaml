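# Instrument registry: cantilever sensing beams, laser displacement sensor,
# finite-element and experimental calibration coefficients, and the microwire
# stock used in the insertion study. All values are printed instrument
# constants; FEM coefficients are consumed as-is (no FEM is run here).
laser:
  height_mm: 171        # laser spot height c above the beam base
  range_mm: 2           # sensor measurement range
  resolution_um: 0.01   # sensor repeatability / quantization step
clamp_height_mm: 15     # fixed (clamped) portion at the beam base
beams:
  - name: beam1
    material: Al-2024
    elastic_modulus_gpa: 73.1
    length_mm: 375
    thickness_mm: 0.5
    width_mm: 20
  - name: beam2
    material: Al-2024
    elastic_modulus_gpa: 73.1
    length_mm: 375
    thickness_mm: 0.625
    width_mm: 20
  - name: beam3
    material: Al-2024
    elastic_modulus_gpa: 73.1
    length_mm: 380
    thickness_mm: 0.8
    width_mm: 40
  - name: beam4
    material: Al-6061
    elastic_modulus_gpa: 68.9
    length_mm: 380
    thickness_mm: 1.5
    width_mm: 20
calibration:
  # force_per_laser_deflection F_i/d_c in mN/mm; loadpoint_per_laser_deflection
  # d_l/d_c dimensionless. FEM includes component gravity; experiment is the
  # stage push-calibration.
  fem:
    beam1: {force_per_laser_deflection: 3.238,  loadpoint_per_laser_deflection: 4.1789}
    beam2: {force_per_laser_deflection: 15.648, loadpoint_per_laser_deflection: 4.1754}
    beam3: {force_per_laser_deflection: 31.226, loadpoint_per_laser_deflection: 4.3124}
    beam4: {force_per_laser_deflection: 109.36, loadpoint_per_laser_deflection: 4.2812}
  ideal:
    # Published ideal-cantilever force ratios (the beam2 entry is inconsistent
    # with Euler-Bernoulli theory for its geometry; see package vignette).
    beam1: {force_per_laser_deflection: 4.058}
    beam2: {force_per_laser_deflection: 16.62}
    beam3: {force_per_laser_deflection: 32.712}
    beam4: {force_per_laser_deflection: 101.76}
  experiment:
    beam1: {loadpoint_per_laser_deflection: 4.2816}
    beam2: {loadpoint_per_laser_deflection: 4.2544}
    beam3: {loadpoint_per_laser_deflection: 4.3999}
    beam4: {loadpoint_per_laser_deflection: 4.3775}
wire_materials:
  tungsten: {elastic_modulus_gpa: 410}
  stainless_steel: {elastic_modulus_gpa: 200}
wire_overhang_mm:
  # unsupported length out of the capillary tube, by wire diameter (um)
  "12": 1.5
  "25": 1.5
  "50": 3.0
  "100": 3.0
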