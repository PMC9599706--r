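# Versioned band table and condition presets for the synthetic-spectrum
# generator and the default deconvolution models. Heights are arbitrary
# absorbance units before area normalization; centers/FWHMs in cm-1.
version: 1
grid:
  max: 4000.0
  min: 1000.0
  n_points: 6224
windows:
  lipid:    [2750.0, 3100.0]
  ester:    [1700.0, 1780.0]
  amide_i:  [1600.0, 1700.0]
  amide_ii: [1510.0, 1580.0]
# Region over which the baseline (rubberband hull) is estimated before the
# fit window is cut out. Chosen so both edges sit in quiet gaps between band
# groups; a hull anchored on the flank of a band subtracts part of the band.
baseline_support:
  lipid:    [2750.0, 3100.0]
  ester:    [1600.0, 1780.0]
  amide_i:  [1600.0, 1780.0]
  amide_ii: [1480.0, 1600.0]
fit_defaults:
  center_bound_halfwidth: 6.0
  fwhm_bounds: [8.0, 50.0]
variability:
  height_cv: 0.03
  center_jitter_sd: 0.5
  noise_sd: 0.004
baseline:
  # absorbance = intercept + slope * (wavenumber - 1000)
  intercept: 0.02
  slope: 5.0e-6
bands:
  olefinic:     {center: 3010.0, fwhm: 14.0, group: lipid,    assignment: "olefinic =CH stretch (unsaturation)"}
  vas_ch3:      {center: 2960.0, fwhm: 24.0, group: lipid,    assignment: "asymmetric CH3 stretch"}
  vas_ch2:      {center: 2920.0, fwhm: 28.0, group: lipid,    assignment: "asymmetric CH2 stretch"}
  vs_ch3:       {center: 2870.0, fwhm: 22.0, group: lipid,    assignment: "symmetric CH3 stretch"}
  vs_ch2:       {center: 2850.0, fwhm: 20.0, group: lipid,    assignment: "symmetric CH2 stretch"}
  ester_co:     {center: 1740.0, fwhm: 26.0, group: ester,    assignment: "ester C=O stretch (triglyceride/phospholipid)"}
  antiparallel: {center: 1692.0, fwhm: 16.0, group: amide_i,  assignment: "antiparallel beta-sheet"}
  beta_turn:    {center: 1680.0, fwhm: 18.0, group: amide_i,  assignment: "beta-turn"}
  alpha_helix:  {center: 1655.0, fwhm: 22.0, group: amide_i,  assignment: "alpha-helix"}
  random_coil:  {center: 1640.0, fwhm: 20.0, group: amide_i,  assignment: "random coil"}
  beta_sheet:   {center: 1625.0, fwhm: 18.0, group: amide_i,  assignment: "beta-sheet"}
  amide_ii:     {center: 1545.0, fwhm: 40.0, group: amide_ii, assignment: "amide II (N-H bend / C-N stretch)"}
conditions:
  untreated:
    band_heights:
      olefinic: 0.060
      vas_ch3: 0.400
      vas_ch2: 0.660
      vs_ch3: 0.400
      vs_ch2: 0.540
      ester_co: 0.120
      amide_ii: 0.30
    amide_area_total: 12.0
    amide_area_fractions:
      alpha_helix: 0.55
      random_coil: 0.28
      beta_sheet: 0.09
      beta_turn: 0.05
      antiparallel: 0.03
  steatotic:
    band_heights:
      olefinic: 0.045
      vas_ch3: 0.400
      vas_ch2: 0.612
      vs_ch3: 0.400
      vs_ch2: 0.388
      ester_co: 0.200
      amide_ii: 0.40
    amide_area_total: 16.0
    amide_area_fractions:
      alpha_helix: 0.68
      random_coil: 0.16
      beta_sheet: 0.10
      beta_turn: 0.04
      antiparallel: 0.02
  ex4:
    band_heights:
      olefinic: 0.046
      vas_ch3: 0.400
      vas_ch2: 0.652
      vs_ch3: 0.400
      vs_ch2: 0.456
      ester_co: 0.150
      amide_ii: 0.33
    amide_area_total: 13.5
    amide_area_fractions:
      alpha_helix: 0.60
      random_coil: 0.22
      beta_sheet: 0.10
      beta_turn: 0.05
      antiparallel: 0.03
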