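# Four-layer skin model: healthy-baseline optical specification.
# Thicknesses, hemoglobin concentrations, water/lipid fractions, g and n are
# the standard multilayer-skin values used for the simulation study; the
# reduced-scattering power laws are a bundled approximate parameterization
# (the dermal law is calibrated so that the dermal transport mean free path
# 1/(mua + musp) equals 0.35 mm at 691 nm and 0.46 mm at 851 nm).
# Per-wavelength musp_mm1 / mua_mm1 maps may be given instead of the power
# law to enter tabulated optical properties verbatim.
name: four_layer_skin
ambient_n: 1.0
layers:
  - name: epidermis
    thickness_um: 50
    blood_volume_fraction: 0.0
    conc_hbo_uM: 0.0
    conc_hbr_uM: 0.0
    conc_hb_total_uM: 0.0
    water_fraction: 0.17
    lipid_fraction: 0.10
    melanin_fraction: 0.0
    g: 0.80
    "n": 1.37
    musp_power_law: {a_mm1: 3.30, b: 1.40, reference_nm: 691}
  - name: papillary_dermis
    thickness_um: 200
    blood_volume_fraction: 0.02
    conc_hbo_uM: 37.21
    conc_hbr_uM: 9.302
    conc_hb_total_uM: 46.51
    water_fraction: 0.70
    lipid_fraction: 0.05
    melanin_fraction: 0.0
    g: 0.80
    "n": 1.40
    musp_power_law: {a_mm1: 2.8501, b: 1.3305, reference_nm: 691}
  - name: reticular_dermis
    thickness_um: 1100
    blood_volume_fraction: 0.02
    conc_hbo_uM: 37.21
    conc_hbr_uM: 9.302
    conc_hb_total_uM: 46.51
    water_fraction: 0.70
    lipid_fraction: 0.05
    melanin_fraction: 0.0
    g: 0.80
    "n": 1.40
    musp_power_law: {a_mm1: 2.8501, b: 1.3305, reference_nm: 691}
  - name: subcutaneous
    thickness_um: 6150
    blood_volume_fraction: 0.07
    conc_hbo_uM: 130.2
    conc_hbr_uM: 32.56
    conc_hb_total_uM: 162.8
    water_fraction: 0.70
    lipid_fraction: 0.23
    melanin_fraction: 0.0
    g: 0.75
    "n": 1.40
    musp_power_law: {a_mm1: 1.90, b: 0.70, reference_nm: 691}
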